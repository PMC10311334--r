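# Brute-force oracles and toy-data builders shared across the suite.
# The oracles deliberately avoid the package's vectorized distance code:
# plain per-point loops over dist() style computations.

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracle_precision_recall <- function(true_x, gen_x, k) {
  n_t <- nrow(true_x); n_g <- nrow(gen_x)
  radius <- function(X) vapply(seq_len(nrow(X)), function(i) {
    d <- vapply(seq_len(nrow(X)), function(j)
      if (i == j) Inf else euclid(X[i, ], X[j, ]), 0)
    sort(d)[k]
  }, 0)
  r_t <- radius(true_x); r_g <- radius(gen_x)
  prec <- mean(vapply(seq_len(n_g), function(j)
    any(vapply(seq_len(n_t), function(i)
      euclid(true_x[i, ], gen_x[j, ]) <= r_t[i], NA)), NA))
  rec <- mean(vapply(seq_len(n_t), function(i)
    any(vapply(seq_len(n_g), function(j)
      euclid(gen_x[j, ], true_x[i, ]) <= r_g[j], NA)), NA))
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1)
}

oracle_adversarial_accuracy <- function(true_x, gen_x) {
  n_t <- nrow(true_x); n_g <- nrow(gen_x)
  min_to <- function(x, X, skip = 0L) {
    d <- Inf
    for (j in seq_len(nrow(X))) {
      if (j == skip) next
      d <- min(d, euclid(x, X[j, ]))
    }
    d
  }
  tt <- vapply(seq_len(n_t), function(i) min_to(true_x[i, ], true_x, i), 0)
  tg <- vapply(seq_len(n_t), function(i) min_to(true_x[i, ], gen_x), 0)
  gg <- vapply(seq_len(n_g), function(j) min_to(gen_x[j, ], gen_x, j), 0)
  gt <- vapply(seq_len(n_g), function(j) min_to(gen_x[j, ], true_x), 0)
  (mean(tg > tt) + mean(gt > gg)) / 2
}

# Two-component 2-D Gaussian mixture inside [0,1], labelled by component.
make_mixture <- function(n, seed, sd = 0.05) {
  set.seed(seed)
  comp <- sample(0:1, n, replace = TRUE)
  x <- cbind(0.3 + 0.4 * comp + rnorm(n, 0, sd),
             0.3 + 0.4 * comp + rnorm(n, 0, sd))
  x <- pmin(pmax(x, 0), 1)
  expression_dataset(x, c("g1", "g2"), paste0("s", seq_len(n)),
                     data.frame(age = NA_real_, gender = NA_character_,
                                tissue = NA_character_, cancer = comp),
                     normalized = TRUE)
}

# Small well-separated binary classification toy in d dimensions: the
# first gene carries a shift of `gap` class-noise standard deviations.
make_separable <- function(n, d = 10, seed = 1, gap = 6) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * d), n, d)
  x[, 1] <- gap * 0.5 * y + rnorm(n, sd = 0.5)
  x <- apply(x, 2, function(col) (col - min(col)) / (max(col) - min(col)))
  expression_dataset(x, paste0("g", seq_len(d)), paste0("s", seq_len(n)),
                     data.frame(age = 50, gender = "female",
                                tissue = "lung", cancer = y),
                     normalized = TRUE)
}

default_sim <- function(seed = 1, n = 400, d = 60) {
  simulate_transcriptome(sim_config(n_samples = n, n_genes = d,
                                    n_tissues = 3, block_size = min(10, d),
                                    block_rho = 0.7, cancer_fraction = 0.5,
                                    cancer_shift = 0.3, noise_sd = 0.1,
                                    seed = seed))
}

random_mask <- function(d, n_pairs, seed) {
  set.seed(seed)
  pairs <- unique(cbind(sample.int(d, n_pairs * 2, TRUE),
                        sample.int(d, n_pairs * 2, TRUE)))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- pairs[seq_len(min(n_pairs, nrow(pairs))), , drop = FALSE]
  attention_mask(unique(rbind(pairs, pairs[, 2:1])), d, "coexp")
}
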