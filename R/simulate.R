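#' Configure the synthetic transcriptome simulator
#'
#' The simulator emulates the structure of large pan-cancer bulk RNA-seq
#' compendia at desk scale: samples fall into tissue clusters (Gaussian
#' around a tissue-specific mean profile), genes come in blocks sharing a
#' latent factor (within-block pairwise correlation ~ `block_rho`), a
#' designated gene subset carries a mean shift in cancer-labelled samples,
#' and every sample has age/gender/tissue/cancer covariates.
#'
#' @param n_samples number of samples (default 600).
#' @param n_genes number of genes (default 200).
#' @param n_tissues number of tissue clusters (default 6); samples are
#'   allocated to tissues as evenly as possible.
#' @param block_size genes per correlated block (default 20); must satisfy
#'   `1 <= block_size <= n_genes`.
#' @param block_rho target within-block Pearson correlation in \[0,1)
#'   (default 0.7).
#' @param cancer_fraction proportion of cancer-labelled samples in \[0,1\]
#'   (default 0.5); the count is exact, `round(n_samples * fraction)`.
#' @param cancer_shift mean shift added to the first gene block in cancer
#'   samples, on the latent scale (default 0.15).
#' @param noise_sd within-cluster standard deviation on the latent scale
#'   (default 0.08).
#' @param seed integer seed; the simulation is bit-identical for a fixed
#'   seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_samples = 600L, n_genes = 200L, n_tissues = 6L,
                       block_size = 20L, block_rho = 0.7,
                       cancer_fraction = 0.5, cancer_shift = 0.15,
                       noise_sd = 0.08, seed = 0L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_tissues = as.integer(n_tissues),
              block_size = as.integer(block_size),
              block_rho = block_rho, cancer_fraction = cancer_fraction,
              cancer_shift = cancer_shift, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$n_tissues < 1) stop("n_tissues must be >= 1")
  if (cfg$block_size < 1 || cfg$block_size > cfg$n_genes)
    stop("block_size must satisfy 1 <= block_size <= n_genes")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("block_rho must lie in [0, 1)")
  if (cfg$cancer_fraction < 0 || cfg$cancer_fraction > 1)
    stop("cancer_fraction must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a transcriptome dataset
#'
#' Generative model, per sample s and gene g with tissue t(s) and gene
#' block b(g):
#' \deqn{x_{sg} = \mu_{t(s),g} + \sigma(\sqrt{\rho}\,f_{s,b(g)} +
#'   \sqrt{1-\rho}\,\epsilon_{sg}) + \delta\,1[cancer_s]\,1[g \in S]}
#' with tissue means \eqn{\mu_{t,g} \sim U(0.2, 0.8)}, standard-normal
#' latent block factors f and residuals \eqn{\epsilon}, noise scale
#' \eqn{\sigma} = `noise_sd`, shift \eqn{\delta} = `cancer_shift` on the
#' first block S.  Values are then min-max scaled per gene to \[0,1\]
#' (constant genes map to 0.5).  The linear scaling preserves all
#' within-tissue Pearson correlations, so within-block correlation stays
#' ~ `block_rho`.
#'
#' @param config a [sim_config()].
#' @return A normalized [expression_dataset()]; the indices of the
#'   cancer-shifted genes are stored in the `shift_genes` attribute.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples; d <- config$n_genes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  tissue_id <- sort(rep_len(seq_len(config$n_tissues), n))
  block_of <- ceiling(seq_len(d) / config$block_size)
  n_blocks <- max(block_of)

  mu <- matrix(stats::runif(config$n_tissues * d, 0.2, 0.8),
               config$n_tissues, d)
  f <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  eps <- matrix(stats::rnorm(n * d), n, d)
  rho <- config$block_rho
  x <- mu[tissue_id, , drop = FALSE] +
    config$noise_sd * (sqrt(rho) * f[, block_of, drop = FALSE] +
                       sqrt(1 - rho) * eps)

  n_cancer <- round(config$cancer_fraction * n)
  cancer <- integer(n)
  if (n_cancer > 0) cancer[sample.int(n, n_cancer)] <- 1L
  shift_genes <- which(block_of == 1L)
  if (any(cancer == 1L))
    x[cancer == 1L, shift_genes] <- x[cancer == 1L, shift_genes] +
      config$cancer_shift

  # per-gene min-max to [0,1]; constant genes sit at 0.5
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  const <- rng <= 0
  rng[const] <- 1
  x <- sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
  x[, const] <- 0.5

  covariates <- data.frame(
    age = pmin(pmax(round(stats::rnorm(n, 60, 12)), 18), 95),
    gender = sample(c("female", "male"), n, replace = TRUE),
    tissue = paste0("tissue", formatC(tissue_id, width = 2, flag = "0")),
    cancer = cancer,
    stringsAsFactors = FALSE)

  out <- expression_dataset(x, paste0("gene", formatC(seq_len(d), width = 5,
                                                      flag = "0")),
                            paste0("sample", formatC(seq_len(n), width = 6,
                                                     flag = "0")),
                            covariates, normalized = TRUE)
  attr(out, "shift_genes") <- shift_genes
  attr(out, "sim_config") <- config
  out
}
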