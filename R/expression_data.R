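#' Construct an expression dataset
#'
#' The universal data container of the package: an `n_samples x n_genes`
#' matrix of (typically normalized) expression values together with one
#' covariate record per sample.  Covariates carry the conditioning
#' variables used by the conditional generative models and the labels used
#' by the evaluation harness: `age` (years, numeric), `gender`
#' (categorical), `tissue` (categorical) and `cancer` (binary 0/1).
#'
#' @param values numeric matrix, samples in rows, genes in columns.  No
#'   missing values are allowed.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column of `values`.
#' @param sample_ids character vector of sample identifiers, one per row.
#' @param covariates data.frame with one row per sample and (at least)
#'   columns `age`, `gender`, `tissue`, `cancer`.
#' @param normalized logical; `TRUE` when `values` are already on the
#'   normalized \[0,1\] scale (affects how [normalize_expression()] treats
#'   the data).
#' @return An object of class `expression_dataset`.
#' @examples
#' ds <- expression_dataset(matrix(runif(6), 3, 2),
#'                          gene_ids = c("g1", "g2"),
#'                          sample_ids = paste0("s", 1:3),
#'                          covariates = data.frame(
#'                            age = c(50, 60, 70),
#'                            gender = "female",
#'                            tissue = "lung",
#'                            cancer = c(0, 1, 0)))
#' dim(ds)
#' @export
expression_dataset <- function(values, gene_ids = colnames(values),
                               sample_ids = rownames(values),
                               covariates = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(d))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyNA(values)) stop("expression values contain missing entries")
  if (length(gene_ids) != d) stop("gene_ids length != number of gene columns")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids length != number of rows")
  if (is.null(covariates)) {
    covariates <- data.frame(age = rep(NA_real_, n),
                             gender = rep(NA_character_, n),
                             tissue = rep(NA_character_, n),
                             cancer = rep(NA_integer_, n),
                             stringsAsFactors = FALSE)
  }
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(covariates) != n)
    stop("covariate row count (", nrow(covariates),
         ") does not match sample count (", n, ")")
  rownames(values) <- sample_ids
  colnames(values) <- gene_ids
  rownames(covariates) <- NULL
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, covariates = covariates,
                 normalized = isTRUE(normalized)),
            class = "expression_dataset")
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$values), " samples x ",
      ncol(x$values), " genes",
      if (isTRUE(x$normalized)) " (normalized)" else "", "\n", sep = "")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression dataset by sample index
#'
#' @param dataset an `expression_dataset`.
#' @param idx integer (or logical) sample indices to keep; duplicates are
#'   allowed (rows are repeated).
#' @param sample_ids optional replacement IDs for the subset.
#' @return An `expression_dataset` with the selected rows; normalization
#'   state and attributes are preserved.
#' @export
subset_samples <- function(dataset, idx, sample_ids = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  vals <- dataset$values[idx, , drop = FALSE]
  ids <- if (is.null(sample_ids)) make.unique(dataset$sample_ids[idx])
         else sample_ids
  out <- expression_dataset(vals, dataset$gene_ids, ids,
                            dataset$covariates[idx, , drop = FALSE],
                            normalized = dataset$normalized)
  attr(out, "norm_stats") <- attr(dataset, "norm_stats")
  out
}

#' Row-bind two expression datasets over the same gene set
#'
#' @param a,b `expression_dataset` objects with identical `gene_ids`.
#' @return Combined dataset; sample IDs are made unique.
#' @export
bind_datasets <- function(a, b) {
  stopifnot(inherits(a, "expression_dataset"), inherits(b, "expression_dataset"))
  if (!identical(a$gene_ids, b$gene_ids))
    stop("datasets have different gene sets")
  cov <- rbind(a$covariates[names(a$covariates)],
               b$covariates[names(a$covariates)])
  expression_dataset(rbind(a$values, b$values), a$gene_ids,
                     make.unique(c(a$sample_ids, b$sample_ids)),
                     cov, normalized = a$normalized && b$normalized)
}

# ---------------------------------------------------------------------------
# IO

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix and covariate table from delimited text
#'
#' Expression layout: header row of gene IDs, first column of sample IDs,
#' numeric body; tab- or comma-separated (auto-detected).  Covariate
#' layout: columns `sample_id`, `age`, `gender`, `tissue`, `cancer`.
#' Covariate rows are matched to expression rows by sample ID; a sample
#' present in one file but not the other is an error.
#'
#' @param path path to the expression table.
#' @param covariate_path optional path to the covariate table.
#' @param normalized logical flag recorded on the returned dataset.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, covariate_path = NULL, normalized = FALSE) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("expression table needs >= 1 gene column")
  sample_ids <- tab[[1]]
  body <- tab[, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1L,
                                       dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric expression value at row ", bad[1, 1],
         " (sample ", sample_ids[bad[1, 1]], "), column ",
         colnames(body)[bad[1, 2]])
  covariates <- NULL
  if (!is.null(covariate_path)) {
    csep <- detect_sep(covariate_path)
    cov <- utils::read.table(covariate_path, header = TRUE, sep = csep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(cov))
      stop("covariate table must have a sample_id column")
    miss <- setdiff(sample_ids, cov$sample_id)
    extra <- setdiff(cov$sample_id, sample_ids)
    if (length(miss) || length(extra))
      stop("sample-ID mismatch between expression and covariates: ",
           length(miss), " missing from covariates, ",
           length(extra), " unknown to expression (e.g. ",
           paste(utils::head(c(miss, extra), 3), collapse = ", "), ")")
    cov <- cov[match(sample_ids, cov$sample_id), , drop = FALSE]
    covariates <- cov[setdiff(names(cov), "sample_id")]
  }
  expression_dataset(vals, colnames(body), sample_ids, covariates,
                     normalized = normalized)
}

#' Write an expression dataset (and optionally its covariates) to TSV
#'
#' @param dataset an `expression_dataset`.
#' @param path output path for the expression table.
#' @param covariate_path optional output path for the covariate table.
#' @param sep field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, covariate_path = NULL, sep = "\t") {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- data.frame(sample_id = dataset$sample_ids,
                    dataset$values, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(covariate_path)) {
    cov <- data.frame(sample_id = dataset$sample_ids, dataset$covariates,
                      check.names = FALSE)
    utils::write.table(cov, covariate_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Normalization

#' Normalize expression to the unit interval
#'
#' Raw expression values are mapped through `log2(1 + x)` and then min-max
#' scaled per gene to \[0,1\] using statistics fitted on `stats_from`
#' (normally the training split).  Values falling outside the fitted range
#' are clipped.  A dataset already flagged as normalized skips the log
#' step, which makes the transformation idempotent when refitted on its
#' own output.  Genes that are constant in `stats_from` have no usable
#' range: their column is mapped to 0 and a warning is emitted.
#'
#' The fitted per-gene statistics are stored in the `norm_stats` attribute
#' and reused by [inverse_normalize()].
#'
#' @param dataset dataset to transform.
#' @param stats_from dataset providing the per-gene statistics; defaults to
#'   `dataset` itself.
#' @return A normalized `expression_dataset` (flag set, stats attached).
#' @export
normalize_expression <- function(dataset, stats_from = dataset) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(stats_from, "expression_dataset"))
  if (!identical(dataset$gene_ids, stats_from$gene_ids))
    stop("stats_from covers a different gene set")
  use_log <- !isTRUE(stats_from$normalized)
  ref <- stats_from$values
  x <- dataset$values
  if (use_log) {
    if (min(ref) <= -1 || min(x) <= -1)
      stop("log2(1 + x) undefined for values <= -1")
    ref <- log2(1 + ref)
    x <- log2(1 + x)
  }
  lo <- apply(ref, 2, min)
  hi <- apply(ref, 2, max)
  rng <- hi - lo
  const <- rng <= 0
  if (any(const)) {
    warning(sum(const), " gene(s) constant in the reference split; ",
            "mapped to 0")
    rng[const] <- 1
  }
  y <- sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
  y[, const] <- 0
  y <- pmin(pmax(y, 0), 1)
  out <- expression_dataset(y, dataset$gene_ids, dataset$sample_ids,
                            dataset$covariates, normalized = TRUE)
  attr(out, "norm_stats") <- list(lo = lo, hi = hi, constant = const,
                                  log = use_log)
  out
}

#' Invert a normalization
#'
#' Maps normalized values back to the raw scale using the statistics
#' stored by [normalize_expression()].  Entries that were clipped during
#' normalization cannot be recovered.
#'
#' @param dataset normalized dataset carrying a `norm_stats` attribute.
#' @return Dataset on the raw scale.
#' @export
inverse_normalize <- function(dataset) {
  st <- attr(dataset, "norm_stats")
  if (is.null(st)) stop("dataset carries no normalization statistics")
  rng <- st$hi - st$lo
  rng[st$constant] <- 0
  x <- sweep(sweep(dataset$values, 2, rng, "*"), 2, st$lo, "+")
  if (st$log) x <- 2^x - 1
  expression_dataset(x, dataset$gene_ids, dataset$sample_ids,
                     dataset$covariates, normalized = FALSE)
}

# ---------------------------------------------------------------------------
# Splitting

#' Specify a train/validation/test split
#'
#' @param val_fraction,test_fraction proportions in (0,1) with
#'   `val_fraction + test_fraction < 1`.  Sizes are `round(n * fraction)`
#'   (round half to even, as in base R), remainder to train; with
#'   one-sixth validation and one-sixth test, 9749 samples split into
#'   6499/1625/1625.
#' @param stratify_on covariate name to stratify on, or `NULL`.
#' @param seed integer seed controlling the random assignment.
#' @return A `split_spec` object.
#' @export
split_spec <- function(val_fraction, test_fraction, stratify_on = NULL,
                       seed = 0L) {
  stopifnot(val_fraction > 0, val_fraction < 1,
            test_fraction > 0, test_fraction < 1)
  if (val_fraction + test_fraction >= 1)
    stop("val_fraction + test_fraction must be < 1")
  structure(list(val_fraction = val_fraction, test_fraction = test_fraction,
                 stratify_on = stratify_on, seed = as.integer(seed)),
            class = "split_spec")
}

split_sizes <- function(n, spec) {
  n_val <- round(n * spec$val_fraction)
  n_test <- round(n * spec$test_fraction)
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

#' Partition a dataset into train/validation/test
#'
#' The partition is disjoint and exhaustive, reproducible per seed, and
#' optionally stratified on a covariate (per-class proportional
#' allocation, largest-remainder rounding of the within-class sizes).
#'
#' @param dataset an `expression_dataset`.
#' @param spec a [split_spec()].
#' @return Named list with elements `train`, `val`, `test` (datasets) and
#'   `indices` (list of the row indices used).
#' @export
split_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(spec, "split_spec"))
  n <- nrow(dataset$values)
  sizes <- split_sizes(n, spec)
  withr_seed <- spec$seed
  idx <- list(val = integer(0), test = integer(0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  if (is.null(spec$stratify_on)) {
    perm <- sample.int(n)
    idx$val <- perm[seq_len(sizes["val"])]
    idx$test <- perm[sizes["val"] + seq_len(sizes["test"])]
  } else {
    strat <- dataset$covariates[[spec$stratify_on]]
    if (is.null(strat)) stop("unknown stratification covariate: ",
                             spec$stratify_on)
    strat <- as.character(strat)
    counts <- table(strat)
    if (any(counts < 3))
      stop("stratification class(es) with fewer samples than splits: ",
           paste(names(counts)[counts < 3], collapse = ", "))
    for (cls in names(counts)) {
      rows <- which(strat == cls)
      rows <- rows[sample.int(length(rows))]
      nv <- round(length(rows) * spec$val_fraction)
      nt <- round(length(rows) * spec$test_fraction)
      # keep at least one sample of each class in train
      while (nv + nt >= length(rows)) {
        if (nt > 0) nt <- nt - 1 else nv <- nv - 1
      }
      idx$val <- c(idx$val, rows[seq_len(nv)])
      idx$test <- c(idx$test, rows[nv + seq_len(nt)])
    }
  }
  train_idx <- setdiff(seq_len(n), c(idx$val, idx$test))
  out <- list(train = subset_samples(dataset, train_idx,
                                     dataset$sample_ids[train_idx]),
              val = subset_samples(dataset, idx$val,
                                   dataset$sample_ids[idx$val]),
              test = subset_samples(dataset, idx$test,
                                    dataset$sample_ids[idx$test]),
              indices = list(train = train_idx, val = idx$val,
                             test = idx$test))
  out
}

# ---------------------------------------------------------------------------
# Gaussian-noise augmentation baseline

#' Gaussian-noise augmentation baseline
#'
#' Draws `m` source rows with replacement from `train` and perturbs every
#' gene with i.i.d. Gaussian noise of the given variance (default 0.1 on
#' normalized data).  Covariates and labels are copied from the source
#' row, so the empirical label distribution of the source draw is
#' preserved exactly.  Values are clipped back to \[0,1\] unless
#' `clip = FALSE`.
#'
#' @param train source `expression_dataset` (non-empty).
#' @param m number of augmented samples to produce (> 0).
#' @param variance noise variance (>= 0), default 0.1.
#' @param seed integer seed.
#' @param clip clip noisy values to \[0,1\] (default `TRUE`).
#' @return An `expression_dataset` of `m` rows; the source row index of
#'   each augmented sample is stored in the `source_idx` attribute.
#' @export
gaussian_noise_augment <- function(train, m, variance = 0.1, seed = 0L,
                                   clip = TRUE) {
  stopifnot(inherits(train, "expression_dataset"))
  n <- nrow(train$values)
  if (n < 1) stop("train is empty")
  if (!is.numeric(m) || m <= 0) stop("m must be a positive count")
  if (variance < 0) stop("variance must be >= 0")
  m <- as.integer(m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  src <- sample.int(n, m, replace = TRUE)
  x <- train$values[src, , drop = FALSE]
  if (variance > 0)
    x <- x + matrix(stats::rnorm(m * ncol(x), sd = sqrt(variance)),
                    m, ncol(x))
  if (clip) x <- pmin(pmax(x, 0), 1)
  out <- expression_dataset(x, train$gene_ids,
                            paste0("aug", seq_len(m)),
                            train$covariates[src, , drop = FALSE],
                            normalized = train$normalized)
  attr(out, "source_idx") <- src
  out
}

# RNG bookkeeping: operations that seed internally must not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
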