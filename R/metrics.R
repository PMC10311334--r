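# Unsupervised generated-data quality indicators.
#
# The package scores a generated set against the true training set with:
# the Frechet distance between Gaussian approximations of classifier
# embeddings (FD-binary / FD-tissue), manifold precision/recall/F1 via
# k-NN balls in the original feature space, adversarial accuracy (an
# implicit 1-NN real-vs-generated classifier: ~0 flags memorization, ~1
# easy separability, ~0.5 the desired regime), the cosine similarity of
# the gene-gene correlation matrices, and the PCA cumulative-variance
# spectrum.

as_values <- function(x) {
  if (inherits(x, "expression_dataset")) x$values else as.matrix(x)
}

# squared Euclidean cross-distance matrix, rows of a vs rows of b
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Frechet distance between two embedded sample sets
#'
#' Approximates each side by a Gaussian (mean and unbiased covariance) and
#' returns the squared Wasserstein-2 distance
#' `||mu_t - mu_g||^2 + Tr(S_t + S_g - 2 (S_t S_g)^{1/2})`.  The matrix
#' square root is taken by eigendecomposition of the symmetrized product
#' `S_t^{1/2} S_g S_t^{1/2}`; small negative eigenvalues arising from
#' numerical error are truncated at 0.
#'
#' @param true_embeddings,gen_embeddings numeric matrices with one row per
#'   sample and identical column dimension; at least 2 rows per side.
#' @return Non-negative scalar distance.
#' @export
frechet_distance <- function(true_embeddings, gen_embeddings) {
  a <- as_values(true_embeddings); b <- as_values(gen_embeddings)
  if (ncol(a) != ncol(b)) stop("embedding dimension mismatch: ",
                               ncol(a), " vs ", ncol(b))
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 samples per side")
  mu_t <- colMeans(a); mu_g <- colMeans(b)
  S_t <- stats::cov(a); S_g <- stats::cov(b)
  if (!all(is.finite(S_t)) || !all(is.finite(S_g)))
    stop("non-finite covariance")
  et <- eigen(S_t, symmetric = TRUE)
  half <- et$vectors %*% (sqrt(pmax(et$values, 0)) * t(et$vectors))
  M <- half %*% S_g %*% half
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  fd <- sum((mu_t - mu_g)^2) + sum(diag(S_t)) + sum(diag(S_g)) - 2 * tr_sqrt
  max(fd, 0)
}

#' Manifold precision, recall and F1 via k-NN balls
#'
#' Each sample x gets a ball of radius `r_k(x)`, its distance to its k-th
#' nearest neighbor *within its own set* (self excluded).  Precision is
#' the fraction of generated samples lying within the ball of at least one
#' true sample; recall swaps the roles; F1 is their harmonic mean (0 when
#' both are 0).  Distances are Euclidean in the original feature space.
#'
#' @param true_x,gen_x matrices (or `expression_dataset`s) over the same
#'   features; each side must have more than `k` samples.
#' @param k number of neighbors defining the ball radius (default 50).
#' @return List with `precision`, `recall`, `f1`.
#' @export
precision_recall <- function(true_x, gen_x, k = 50L) {
  a <- as_values(true_x); b <- as_values(gen_x)
  if (nrow(a) <= k) stop("true side has <= k samples (", nrow(a), " <= ",
                         k, ")")
  if (nrow(b) <= k) stop("generated side has <= k samples (", nrow(b),
                         " <= ", k, ")")
  rk <- function(x) {
    d2 <- cross_dist2(x, x)
    diag(d2) <- Inf
    sqrt(apply(d2, 1, function(r) sort(r, partial = k)[k]))
  }
  r_t <- rk(a); r_g <- rk(b)
  dcross <- sqrt(cross_dist2(a, b))          # n_t x n_g
  precision <- mean(apply(dcross <= r_t, 2, any))
  recall <- mean(apply(t(dcross) <= r_g, 2, any))
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Adversarial accuracy (1-NN real-vs-generated discrimination)
#'
#' For each true sample, compares its distance to the nearest generated
#' sample against the distance to the nearest *other* true sample (and
#' symmetrically for generated samples):
#' `AA = (mean(d_tg > d_tt) + mean(d_gt > d_gg)) / 2` with strict
#' inequality, so exact-duplicate ties count as "not farther" (exact
#' copies give AA = 0).  Following common practice on large cohorts the
#' true side can be subsampled (`subset_size`, seeded).
#'
#' @param true_x,gen_x matrices (or datasets) with >= 2 samples per side.
#' @param subset_size maximum number of true samples used (default 2000).
#' @param seed seed for the subsample draw.
#' @return Scalar in \[0,1\].
#' @export
adversarial_accuracy <- function(true_x, gen_x, subset_size = 2000L,
                                 seed = 0L) {
  a <- as_values(true_x); b <- as_values(gen_x)
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 samples per side")
  if (nrow(a) > subset_size) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    a <- a[sample.int(nrow(a), subset_size), , drop = FALSE]
  }
  dtt2 <- cross_dist2(a, a); diag(dtt2) <- Inf
  dgg2 <- cross_dist2(b, b); diag(dgg2) <- Inf
  dtg2 <- cross_dist2(a, b)
  d_tt <- apply(dtt2, 1, min); d_tg <- apply(dtg2, 1, min)
  d_gg <- apply(dgg2, 1, min); d_gt <- apply(dtg2, 2, min)
  (mean(d_tg > d_tt) + mean(d_gt > d_gg)) / 2
}

#' Correlation score between true and generated gene-gene structure
#'
#' Cosine similarity between the strictly-upper-triangular entries of the
#' two gene-gene Pearson correlation matrices.  Constant genes contribute
#' zero correlations; all-constant data has no correlation structure and
#' is an error.
#'
#' @param true_x,gen_x matrices (or datasets) over the same gene set with
#'   >= 3 samples per side.
#' @return Scalar in \[-1, 1\].
#' @export
correlation_score <- function(true_x, gen_x) {
  a <- as_values(true_x); b <- as_values(gen_x)
  if (ncol(a) != ncol(b)) stop("gene sets differ")
  if (nrow(a) < 3 || nrow(b) < 3) stop("need >= 3 samples per side")
  M_t <- suppressWarnings(stats::cor(a)); M_t[is.na(M_t)] <- 0
  M_g <- suppressWarnings(stats::cor(b)); M_g[is.na(M_g)] <- 0
  ut <- upper.tri(M_t)
  u_t <- M_t[ut]; u_g <- M_g[ut]
  n_t <- sqrt(sum(u_t^2)); n_g <- sqrt(sum(u_g^2))
  if (n_t == 0 || n_g == 0)
    stop("undefined correlation score: a side has no correlation structure")
  sum(u_t * u_g) / (n_t * n_g)
}

#' PCA cumulative explained-variance spectrum
#'
#' Returns CV(i), the fraction of total variance explained by the top i
#' principal components, for i = 1..min(n-1, d); the curve is
#' nondecreasing and ends at 1.  Used to compare the intrinsic
#' dimensionality of generated versus true data (mode-collapsed
#' generators concentrate variance on few components).
#'
#' @param x matrix or `expression_dataset` with n >= 2 samples.
#' @return Numeric vector of cumulative explained-variance fractions.
#' @export
pca_spectrum <- function(x) {
  v <- as_values(x)
  if (nrow(v) < 2) stop("need >= 2 samples")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  if (sum(vars) == 0) return(rep(1, length(vars)))
  cumsum(vars) / sum(vars)
}

# ---------------------------------------------------------------------------
# Embeddings

#' Fit a classifier embedding for Frechet-distance computation
#'
#' Trains the task classifier (binary cancer / tissue multiclass MLP, see
#' [classifier_spec()]) and exposes its last hidden layer as the embedding
#' map.  The embedding dimension equals the classifier's hidden size (256
#' for the binary task, 64 for tissues by default).
#'
#' @param train labelled `expression_dataset`.
#' @param task `"binary"` or `"tissue"`.
#' @param spec optional [classifier_spec()] override.
#' @param seed training seed.
#' @return An `embedding_space` object with fields `classifier`, `task`,
#'   `dimension`.
#' @export
fit_embedding <- function(train, task = c("binary", "tissue"), spec = NULL,
                          seed = 0L) {
  task <- match.arg(task)
  if (is.null(spec)) spec <- classifier_spec(task)
  clf <- train_classifier(train, spec, seed = seed)
  structure(list(classifier = clf, task = task,
                 dimension = spec$hidden_size),
            class = "embedding_space")
}

#' Embed samples into a fitted embedding space
#'
#' @param space an `embedding_space` from [fit_embedding()].
#' @param x matrix or `expression_dataset`; one row per sample.
#' @return Matrix of last-hidden-layer activations, one row per input.
#' @export
embed_samples <- function(space, x) {
  stopifnot(inherits(space, "embedding_space"))
  classifier_hidden(space$classifier, as_values(x))
}

# ---------------------------------------------------------------------------
# Aggregated report

#' Compute the full quality-indicator report for one generative model
#'
#' Mirrors the indicator battery used to compare generative models:
#' correlation score, manifold precision/recall/F1 (k-NN balls, default
#' k = 50), FD-binary and FD-tissue on classifier embeddings, and
#' adversarial accuracy.  Each indicator is aggregated as mean +/- sd over
#' `n_runs` runs: when `model_or_generated` is a trained model, each run
#' regenerates a fresh sample set; when it is a fixed dataset, the data
#' side is deterministic and only the seeded AA subsample varies.
#'
#' @param model_or_generated a `transaug_gan` model or a generated
#'   `expression_dataset`.
#' @param true_train the true training dataset (reference side for every
#'   indicator).
#' @param embeddings named list with elements `binary` and/or `tissue`
#'   (from [fit_embedding()]); missing embeddings skip the corresponding
#'   FD column.
#' @param k neighbors for precision/recall (default 50, reduced with a
#'   warning when a side is too small).
#' @param subset_size AA true-side subsample cap (default
#'   `min(n_true, 2000)`).
#' @param n_runs number of runs (default 5).
#' @param n_generated generated-set size per run when a model is supplied
#'   (default `nrow(true_train)`).
#' @param seed base seed; run r uses `seed + r`.
#' @return A `metrics_report` object: each indicator holds `mean` and `sd`
#'   plus the provenance fields (`k`, set sizes, seeds).
#' @export
compute_report <- function(model_or_generated, true_train, embeddings = list(),
                          k = 50L, subset_size = 2000L, n_runs = 5L,
                          n_generated = NULL, seed = 0L) {
  stopifnot(inherits(true_train, "expression_dataset"))
  is_model <- inherits(model_or_generated, "transaug_gan")
  n_true <- nrow(true_train$values)
  if (is.null(n_generated)) n_generated <- n_true
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    gen <- if (is_model)
      generate_expression(model_or_generated, n_generated,
                          covariate_source = true_train, seed = seed + r)
    else model_or_generated
    kk <- min(k, nrow(gen$values) - 1L, n_true - 1L)
    if (kk < k) warning("k reduced to ", kk, " for small sample sizes")
    pr <- precision_recall(true_train, gen, k = kk)
    fd_b <- if (!is.null(embeddings$binary))
      frechet_distance(embed_samples(embeddings$binary, true_train),
                       embed_samples(embeddings$binary, gen)) else NA_real_
    fd_t <- if (!is.null(embeddings$tissue))
      frechet_distance(embed_samples(embeddings$tissue, true_train),
                       embed_samples(embeddings$tissue, gen)) else NA_real_
    runs[[r]] <- c(correlation = correlation_score(true_train, gen),
                   precision = pr$precision, recall = pr$recall, f1 = pr$f1,
                   fd_binary = fd_b, fd_tissue = fd_t,
                   aa = adversarial_accuracy(true_train, gen,
                                             subset_size = subset_size,
                                             seed = seed + r))
  }
  tab <- do.call(rbind, runs)
  agg <- lapply(colnames(tab), function(cn)
    c(mean = mean(tab[, cn]), sd = stats::sd(tab[, cn])))
  names(agg) <- colnames(tab)
  structure(c(agg, list(k = k, n_true_reference = n_true,
                        n_generated = if (is_model) n_generated
                                      else nrow(model_or_generated$values),
                        n_runs = n_runs,
                        seeds = seed + seq_len(n_runs),
                        per_run = tab)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cols <- c("correlation", "precision", "recall", "f1", "fd_binary",
            "fd_tissue", "aa")
  arrows <- c("↑", "↑", "↑", "↑", "↓", "↓", "")
  cat("<metrics_report> k =", x$k, ", n_true =", x$n_true_reference,
      ", n_generated =", x$n_generated, ", runs =", x$n_runs, "\n")
  for (i in seq_along(cols)) {
    v <- x[[cols[i]]]
    cat(sprintf("  %-12s %s  %.4f +/- %.4f\n", cols[i], arrows[i],
                v["mean"], v["sd"]))
  }
  invisible(x)
}
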