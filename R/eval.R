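# Supervised evaluation harness: task classifiers, the augmentation gain
# DeltaAcc(n, m), reverse validation, augmentation schedules, and the
# top-level benchmark orchestration.

#' Classifier hyperparameter specification
#'
#' Defaults follow the evaluation protocol: binary (cancer yes/no) MLP
#' with one hidden layer of 256 units and learning rate 1e-3; tissue
#' multiclass MLP with 64 units and learning rate 5e-4; both with batch
#' size 32, Adam, ReLU activations and 40 epochs.  The reverse-validation
#' classifier uses one hidden layer of 512 units, learning rate 1e-4 and
#' 35 epochs.
#'
#' @param task `"binary"` or `"tissue"` (selects the label column:
#'   `cancer` or `tissue`).
#' @param hidden_size,lr,batch_size,epochs overrides of the task defaults.
#' @param activation hidden activation (default `"relu"`).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(task = c("binary", "tissue"), hidden_size = NULL,
                            lr = NULL, batch_size = 32L, epochs = 40L,
                            activation = "relu") {
  task <- match.arg(task)
  if (is.null(hidden_size)) hidden_size <- if (task == "binary") 256L else 64L
  if (is.null(lr)) lr <- if (task == "binary") 1e-3 else 5e-4
  structure(list(task = task, hidden_size = as.integer(hidden_size), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), activation = activation,
                 optimizer = "adam"),
            class = "classifier_spec")
}

task_labels <- function(dataset, task) {
  col <- if (task == "binary") "cancer" else "tissue"
  y <- dataset$covariates[[col]]
  if (is.null(y) || all(is.na(y)))
    stop("dataset carries no '", col, "' label for the ", task, " task")
  factor(as.character(y))
}

#' Train a task classifier
#'
#' One-hidden-layer MLP with softmax output and cross-entropy loss,
#' optimized with Adam per the supplied spec.  Training is deterministic
#' for a fixed seed.
#'
#' @param data labelled `expression_dataset` with at least two classes
#'   present for the task.
#' @param spec a [classifier_spec()].
#' @param seed integer seed.
#' @return A `transaug_classifier` exposing predictions
#'   ([predict_classifier()]) and last-hidden-layer activations (used as
#'   the Frechet-distance embedding).
#' @export
train_classifier <- function(data, spec, seed = 0L) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(spec, "classifier_spec"))
  y <- task_labels(data, spec$task)
  lev <- levels(droplevels(y))
  if (length(lev) < 2) stop("single-class training data for the ",
                            spec$task, " task")
  y <- factor(as.character(y), levels = lev)
  X <- data$values
  n <- nrow(X); d <- ncol(X); K <- length(lev)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  net <- mlp_init(c(d, spec$hidden_size, K), act = spec$activation,
                  out_act = "linear")
  params <- list(W = net$W, b = net$b)
  state <- adam_init(params)
  B <- min(spec$batch_size, n)
  for (ep in seq_len(spec$epochs)) {
    perm <- sample.int(n)
    for (start in seq(1, n, by = B)) {
      idx <- perm[start:min(start + B - 1, n)]
      nb <- length(idx)
      fwd <- mlp_forward(net, X[idx, , drop = FALSE])
      logits <- fwd$out
      P <- exp(logits - apply(logits, 1, max))
      P <- P / rowSums(P)
      dOut <- (P - Y[idx, , drop = FALSE]) / nb
      bk <- mlp_backward(net, fwd, dOut)
      upd <- adam_step(params, list(W = bk$dW, b = bk$db), state, spec$lr,
                       beta1 = 0.9, beta2 = 0.999)
      params <- upd$params; state <- upd$state
      net$W <- params$W; net$b <- params$b
    }
  }
  structure(list(net = net, levels = lev, spec = spec, seed = seed),
            class = "transaug_classifier")
}

#' Predict class labels with a trained classifier
#' @param classifier a `transaug_classifier`.
#' @param x matrix or `expression_dataset`.
#' @return Factor of predicted labels.
#' @export
predict_classifier <- function(classifier, x) {
  logits <- mlp_forward(classifier$net, as_values(x))$out
  factor(classifier$levels[max.col(logits, ties.method = "first")],
         levels = classifier$levels)
}

classifier_hidden <- function(classifier, x) {
  mlp_forward(classifier$net, as_values(x))$Z[[2]]
}

#' Classification accuracy on a labelled test set
#' @param classifier a `transaug_classifier`.
#' @param test labelled `expression_dataset`, disjoint from training data.
#' @return Fraction of correct predictions in \[0,1\].
#' @export
accuracy <- function(classifier, test) {
  stopifnot(inherits(test, "expression_dataset"))
  if (nrow(test$values) == 0) stop("empty test set")
  y <- task_labels(test, classifier$spec$task)
  mean(as.character(predict_classifier(classifier, test)) ==
         as.character(y))
}

# stratified subsample of size n_take keeping every class present
stratified_sample <- function(labels, n_take, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labels <- factor(labels)
  lev <- levels(labels)
  if (n_take < length(lev))
    stop("n_true smaller than the number of classes (", length(lev), ")")
  counts <- table(labels)
  quota <- stats::setNames(pmax(1, floor(n_take * counts / sum(counts))),
                           names(counts))
  while (sum(quota) > n_take) {
    i <- which.max(quota); quota[i] <- quota[i] - 1
  }
  while (sum(quota) < n_take) {
    room <- counts - quota
    i <- which.max(room); quota[i] <- quota[i] + 1
  }
  idx <- integer(0)
  for (cls in lev) {
    rows <- which(labels == cls)
    idx <- c(idx, rows[sample.int(length(rows), quota[cls])])
  }
  sort(idx)
}

# materialize m generated samples from an augmentation source
draw_generated <- function(source, m, true_subset, seed) {
  if (inherits(source, "transaug_gan"))
    return(generate_expression(source, m, covariate_source = true_subset,
                               seed = seed))
  if (inherits(source, "expression_dataset")) {
    if (nrow(source$values) < m)
      stop("generated pool supplies only ", nrow(source$values),
           " samples; ", m, " requested")
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    return(subset_samples(source, sample.int(nrow(source$values), m)))
  }
  if (is.function(source)) return(source(m, seed))
  if (identical(source, "gaussian_noise"))
    return(gaussian_noise_augment(true_subset, m, variance = 0.1,
                                  seed = seed))
  stop("unsupported augmentation source")
}

#' Augmentation gain DeltaAcc(n, m)
#'
#' Per run: subsamples `n_true` samples from the pool (stratified on the
#' task label, seeded), appends `m_generated` samples from the source,
#' trains the classifier, and evaluates on the fixed true test set; the
#' no-augmentation arm repeats this with the same seeds and no appended
#' samples.  `DeltaAcc = mean(Acc(n, m)) - mean(Acc(n, 0))`; with
#' `m_generated = 0` both arms are identical and the gain is exactly 0.
#'
#' @param n_true number of true training samples per run.
#' @param m_generated number of generated samples appended per run.
#' @param true_pool labelled pool to subsample from (>= `n_true` rows).
#' @param generated_source a trained `transaug_gan`, a pre-generated
#'   `expression_dataset` pool, a function `(m, seed) -> dataset`, or the
#'   string `"gaussian_noise"` (noise perturbation of the subsampled true
#'   arm, variance 0.1).
#' @param spec a [classifier_spec()].
#' @param test fixed true test set, disjoint from all training inputs.
#' @param n_runs number of runs (default 5).
#' @param seeds optional integer vector of per-run seeds (length
#'   `n_runs`); default `seed_base + 1:n_runs`.
#' @param seed_base base seed used when `seeds` is not given.
#' @return List with `delta_acc`, `acc_with` (mean, sd), `acc_without`
#'   (mean, sd), and the per-run accuracies.
#' @export
augmentation_gain <- function(n_true, m_generated, true_pool,
                              generated_source, spec, test, n_runs = 5L,
                              seeds = NULL, seed_base = 0L) {
  stopifnot(inherits(true_pool, "expression_dataset"))
  if (nrow(true_pool$values) < n_true)
    stop("true_pool has fewer than n_true samples")
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  labels <- task_labels(true_pool, spec$task)
  acc_with <- acc_without <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    s <- seeds[r]
    idx <- stratified_sample(labels, n_true, seed = s)
    base <- subset_samples(true_pool, idx)
    clf0 <- train_classifier(base, spec, seed = s)
    acc_without[r] <- accuracy(clf0, test)
    if (m_generated > 0) {
      gen <- draw_generated(generated_source, m_generated, base, seed = s)
      clf1 <- train_classifier(bind_datasets(base, gen), spec, seed = s)
      acc_with[r] <- accuracy(clf1, test)
    } else acc_with[r] <- acc_without[r]
  }
  list(delta_acc = mean(acc_with) - mean(acc_without),
       acc_with = c(mean = mean(acc_with), sd = stats::sd(acc_with)),
       acc_without = c(mean = mean(acc_without), sd = stats::sd(acc_without)),
       runs = data.frame(seed = seeds, acc_with = acc_with,
                         acc_without = acc_without))
}

#' Reverse validation: train on generated, test on true
#'
#' Trains the reverse-validation classifier (one hidden layer of 512
#' units, learning rate 1e-4, batch size 32, 35 epochs) on the generated
#' data only and returns its accuracy on held-out true data.  Matching
#' train-on-true accuracy indicates the generated data preserve the
#' task-discriminant signal.
#'
#' @param generated labelled `expression_dataset` (labels come from the
#'   sampled covariate patterns).
#' @param true_test held-out true test set.
#' @param task `"binary"` or `"tissue"`.
#' @param seed training seed.
#' @return Accuracy on `true_test` in \[0,1\].
#' @export
reverse_validation <- function(generated, true_test,
                               task = c("binary", "tissue"), seed = 0L) {
  task <- match.arg(task)
  spec <- classifier_spec(task, hidden_size = 512L, lr = 1e-4, epochs = 35L,
                          batch_size = 32L)
  clf <- train_classifier(generated, spec, seed = seed)
  accuracy(clf, true_test)
}

#' Run an augmentation schedule
#'
#' Two schedules are supported: `"fixed_generated"` sweeps a grid of true
#' sample counts with a fixed number of generated samples (default 8000);
#' `"fixed_true"` sweeps a grid of generated sample counts at a fixed
#' number of true samples (protocol values 50 and 100).  Each grid point
#' calls [augmentation_gain()]; one curve is produced per source plus a
#' `"none"` baseline curve from the no-augmentation arm.
#'
#' @param schedule_kind `"fixed_generated"` or `"fixed_true"`.
#' @param true_pool,test labelled datasets (pool to subsample, fixed test
#'   set).
#' @param sources named list of augmentation sources (see
#'   [augmentation_gain()]).
#' @param spec a [classifier_spec()].
#' @param n_true_grid grid of true counts (fixed_generated schedule).
#' @param m_grid grid of generated counts (fixed_true schedule).
#' @param m_fixed generated count for the fixed_generated schedule
#'   (default 8000).
#' @param n_true_fixed true count for the fixed_true schedule (default
#'   50).
#' @param n_runs runs per grid point (default 5).
#' @param seed_base base seed.
#' @return An `augmentation_curves` object: long-format data.frame with
#'   columns task, source, n_true, m_generated, mean_accuracy,
#'   std_accuracy, n_runs.
#' @export
run_schedule <- function(schedule_kind = c("fixed_generated", "fixed_true"),
                         true_pool, test, sources, spec,
                         n_true_grid = NULL, m_grid = NULL, m_fixed = 8000L,
                         n_true_fixed = 50L, n_runs = 5L, seed_base = 0L) {
  schedule_kind <- match.arg(schedule_kind)
  grid <- if (schedule_kind == "fixed_generated") {
    if (is.null(n_true_grid)) stop("fixed_generated schedule needs n_true_grid")
    data.frame(n_true = n_true_grid, m = m_fixed)
  } else {
    if (is.null(m_grid)) stop("fixed_true schedule needs m_grid")
    data.frame(n_true = n_true_fixed, m = m_grid)
  }
  rows <- list()
  for (src_name in names(sources)) {
    for (gi in seq_len(nrow(grid))) {
      res <- augmentation_gain(grid$n_true[gi], grid$m[gi], true_pool,
                               sources[[src_name]], spec, test,
                               n_runs = n_runs,
                               seed_base = seed_base + 1000 * gi)
      rows[[length(rows) + 1]] <- data.frame(
        task = spec$task, source = src_name, n_true = grid$n_true[gi],
        m_generated = grid$m[gi],
        mean_accuracy = unname(res$acc_with["mean"]),
        std_accuracy = unname(res$acc_with["sd"]), n_runs = n_runs)
      rows[[length(rows) + 1]] <- data.frame(
        task = spec$task, source = "none", n_true = grid$n_true[gi],
        m_generated = 0,
        mean_accuracy = unname(res$acc_without["mean"]),
        std_accuracy = unname(res$acc_without["sd"]), n_runs = n_runs)
    }
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  class(out) <- c("augmentation_curves", class(out))
  out
}

#' Run a full augmentation benchmark
#'
#' Orchestrates the comparison of augmentation processes: simulates (or
#' receives) a dataset, splits it, builds the requested attention masks,
#' trains every configured generative model, computes the
#' quality-indicator report per model, runs the augmentation schedules,
#' and writes a machine-readable JSON summary.  A failure in one model is
#' recorded and the remaining models still run.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{data}{an `expression_dataset`, or `NULL` to simulate via
#'       `config$sim` (arguments to [sim_config()]).}
#'     \item{models}{character vector from `"gaussian_noise"`, `"gan"`,
#'       `"wgan_gp"`, `"attgan"`, `"rand_attgan"`.}
#'     \item{train}{list of [train_config()] overrides applied to every
#'       generative model.}
#'     \item{mask}{list with `threshold` (co-expression cutoff, default
#'       0.6) and optional `edges`/`min_score` for a PPI component.}
#'     \item{eval}{list with `k`, `n_runs`, `n_generated`, `tasks`.}
#'     \item{schedule}{optional list with `kind` plus grid arguments for
#'       [run_schedule()].}
#'     \item{split}{list with `val`, `test`, `stratify` (default 1/6, 1/6,
#'       tissue).}
#'     \item{seed}{integer master seed.}
#'   }
#' @param out_dir optional directory; when given, writes `summary.json`
#'   and `curves.csv`.
#' @return List with `reports` (one `metrics_report` per generative
#'   model), `curves`, `errors`, and `summary` (the JSON-ready list).
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  data <- config$data
  if (is.null(data)) {
    sim_args <- if (is.null(config$sim)) list() else config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    data <- simulate_transcriptome(do.call(sim_config, sim_args))
  }
  sp <- config$split
  spec <- split_spec(val_fraction = if (is.null(sp$val)) 1 / 6 else sp$val,
                     test_fraction = if (is.null(sp$test)) 1 / 6 else sp$test,
                     stratify_on = if (is.null(sp$stratify)) "tissue"
                                   else sp$stratify,
                     seed = seed)
  parts <- split_dataset(data, spec)
  train <- parts$train; test <- parts$test

  models <- if (is.null(config$models)) "gaussian_noise" else config$models
  gen_kinds <- setdiff(models, "gaussian_noise")
  mask <- NULL
  if (length(intersect(gen_kinds, c("attgan", "rand_attgan")))) {
    mk <- config$mask
    thr <- if (is.null(mk$threshold)) 0.6 else mk$threshold
    mask <- coexpression_mask(train, thr)
    if (!is.null(mk$edges)) {
      ms <- if (is.null(mk$min_score)) 0 else mk$min_score
      mask <- merge_masks(mask, ppi_mask(mk$edges, train$gene_ids, ms))
    }
  }

  ev <- config$eval
  k <- if (is.null(ev$k)) 50L else ev$k
  n_runs <- if (is.null(ev$n_runs)) 5L else ev$n_runs
  n_generated <- if (is.null(ev$n_generated)) nrow(train$values)
                 else ev$n_generated
  tasks <- if (is.null(ev$tasks)) "binary" else ev$tasks

  embeddings <- list()
  if ("binary" %in% tasks)
    embeddings$binary <- fit_embedding(train, "binary", seed = seed)
  if ("tissue" %in% tasks)
    embeddings$tissue <- fit_embedding(train, "tissue", seed = seed)

  trained <- list(); reports <- list(); errors <- list()
  for (kind in gen_kinds) {
    res <- tryCatch({
      targs <- c(list(model_kind = kind, seed = seed),
                 config$train[setdiff(names(config$train), "model_kind")])
      tc <- do.call(train_config, targs)
      model <- train_gan(train, tc, mask = mask)
      list(model = model,
           report = compute_report(model, train, embeddings, k = k,
                                   n_runs = n_runs,
                                   n_generated = n_generated, seed = seed))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[kind]] <- conditionMessage(res)
    } else {
      trained[[kind]] <- res$model
      reports[[kind]] <- res$report
    }
  }

  sources <- list()
  if ("gaussian_noise" %in% models) sources$gaussian_noise <- "gaussian_noise"
  for (kind in names(trained)) sources[[kind]] <- trained[[kind]]

  curves <- NULL
  if (!is.null(config$schedule) && length(sources)) {
    sc <- config$schedule
    for (task in tasks) {
      cspec <- classifier_spec(task)
      cv <- run_schedule(sc$kind, train, test, sources, cspec,
                         n_true_grid = sc$n_true_grid, m_grid = sc$m_grid,
                         m_fixed = if (is.null(sc$m_fixed)) 8000L
                                   else sc$m_fixed,
                         n_true_fixed = if (is.null(sc$n_true_fixed)) 50L
                                        else sc$n_true_fixed,
                         n_runs = n_runs, seed_base = seed)
      curves <- rbind(curves, cv)
    }
  }

  summary <- list(
    seed = seed,
    sizes = list(train = nrow(train$values), val = nrow(parts$val$values),
                 test = nrow(test$values)),
    sources = names(sources),
    models = names(reports),
    errors = errors,
    reports = lapply(reports, function(r)
      lapply(r[c("correlation", "precision", "recall", "f1", "fd_binary",
                 "fd_tissue", "aa")], as.list)),
    curves = curves)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (!is.null(curves))
      utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                       row.names = FALSE)
  }
  list(reports = reports, curves = curves, errors = errors,
       summary = summary, models = trained, split = parts)
}
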