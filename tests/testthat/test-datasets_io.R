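# Simulator, IO round trips, normalization, splitting, noise baseline.

test_that("simulator honours degenerate and balanced configurations", {
  # zero noise, no cancer, one tissue: every row identical
  ds <- simulate_transcriptome(sim_config(n_samples = 20, n_genes = 15,
                                          n_tissues = 1, block_size = 5,
                                          noise_sd = 0, cancer_fraction = 0,
                                          seed = 3))
  expect_true(all(apply(ds$values, 2, function(col) all(col == col[1]))))

  # balanced tissue allocation
  ds <- simulate_transcriptome(sim_config(n_samples = 300, n_genes = 10,
                                          n_tissues = 3, block_size = 5,
                                          seed = 4))
  expect_equal(unname(table(ds$covariates$tissue)), rep(100L, 3),
               ignore_attr = TRUE)

  # invalid configurations
  expect_error(sim_config(n_tissues = 0), "n_tissues")
  expect_error(sim_config(n_genes = 5, block_size = 10), "block_size")
})

test_that("simulated within-block correlations track block_rho", {
  ds <- simulate_transcriptome(sim_config(n_samples = 2000, n_genes = 30,
                                          n_tissues = 1, block_size = 10,
                                          block_rho = 0.8,
                                          cancer_fraction = 0, seed = 7))
  cc <- cor(ds$values[, 1:10])
  off <- cc[upper.tri(cc)]
  expect_true(all(off > 0.7 & off < 0.9))
  # cross-block correlation near zero
  cross <- cor(ds$values[, 1:10], ds$values[, 11:20])
  expect_lt(max(abs(cross)), 0.2)
})

test_that("simulation is bit-identical across invocations and in [0,1]", {
  cfg <- sim_config(n_samples = 50, n_genes = 20, seed = 11)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$covariates, b$covariates)
  expect_true(all(a$values >= 0 & a$values <= 1))
})

test_that("expression/covariate round trip preserves values and errors on mismatch", {
  dir <- withr::local_tempdir()
  vals <- matrix(c(0.1, 2.5, 3, 0, 1.25, 9.75), 3, 2)
  ds <- expression_dataset(vals, c("gA", "gB"), c("s1", "s2", "s3"),
                           data.frame(age = c(40, 50, 60),
                                      gender = c("f", "m", "f"),
                                      tissue = "lung", cancer = c(0, 1, 0)))
  ep <- file.path(dir, "expr.tsv"); cp <- file.path(dir, "cov.tsv")
  write_expression(ds, ep, cp)
  back <- read_expression(ep, cp)
  expect_equal(dim(back), c(3L, 2L))
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  expect_equal(back$covariates$cancer, c(0, 1, 0))

  # covariate table missing one sample -> alignment error
  cov <- read.table(cp, header = TRUE, sep = "\t")
  write.table(cov[-2, ], cp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(ep, cp), "mismatch")

  # non-numeric cell reported with location
  tab <- readLines(ep)
  tab[3] <- sub("2.5", "oops", tab[3], fixed = TRUE)
  writeLines(tab, ep)
  expect_error(read_expression(ep), "non-numeric")
})

test_that("normalization maps the fitting range to [0,1] and inverts", {
  set.seed(5)
  raw <- expression_dataset(matrix(rexp(200, 0.1), 40, 5))
  nm <- normalize_expression(raw)
  expect_true(all(nm$values >= 0 & nm$values <= 1))
  expect_equal(unname(apply(nm$values, 2, min)), rep(0, 5))
  expect_equal(unname(apply(nm$values, 2, max)), rep(1, 5))
  back <- inverse_normalize(nm)
  expect_equal(back$values, raw$values, tolerance = 1e-9)

  # constant gene: column of zeros plus a warning
  raw2 <- expression_dataset(cbind(raw$values[, 1], 3))
  expect_warning(nm2 <- normalize_expression(raw2), "constant")
  expect_equal(unname(nm2$values[, 2]), rep(0, 40))
})

test_that("normalize is idempotent on its own output", {
  set.seed(6)
  raw <- expression_dataset(matrix(rexp(300, 0.2), 60, 5))
  once <- normalize_expression(raw)
  twice <- normalize_expression(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("out-of-range values are clipped against training statistics", {
  tr <- expression_dataset(matrix(seq(0, 9), 5, 2), c("a", "b"))
  te <- expression_dataset(matrix(c(-0.5, 20, 1, 2, 3, 100), 3, 2),
                           c("a", "b"))
  nm <- normalize_expression(te, stats_from = tr)
  expect_true(all(nm$values >= 0 & nm$values <= 1))
})

test_that("split sizes, disjointness and stratification behave", {
  # protocol arithmetic: 9749 with one-sixth val and test
  spec <- split_spec(1 / 6, 1 / 6, seed = 1)
  sizes <- transaug:::split_sizes(9749, spec)
  expect_equal(unname(sizes), c(6499, 1625, 1625))

  ds <- default_sim(seed = 2, n = 120, d = 10)
  parts <- split_dataset(ds, split_spec(1 / 3, 1 / 3, seed = 9))
  idx <- parts$indices
  expect_equal(sort(c(idx$train, idx$val, idx$test)), seq_len(120))
  expect_equal(lengths(idx[c("train", "val", "test")]),
               c(train = 40L, val = 40L, test = 40L))

  # tiny exact division
  small <- subset_samples(ds, 1:6)
  p6 <- split_dataset(small, split_spec(1 / 3, 1 / 3, seed = 1))
  expect_equal(unname(vapply(p6[1:3], function(p) nrow(p$values), 0L)),
               c(2L, 2L, 2L))

  # stratified binary 50/50
  y <- rep(c("a", "b"), each = 60)
  strat <- expression_dataset(ds$values, ds$gene_ids, ds$sample_ids,
                              data.frame(age = 50, gender = "f",
                                         tissue = y, cancer = 0))
  ps <- split_dataset(strat, split_spec(0.25, 0.25, stratify_on = "tissue",
                                        seed = 2))
  for (part in ps[1:3]) {
    tab <- table(part$covariates$tissue)
    expect_lte(abs(tab[["a"]] - tab[["b"]]), 2)
  }

  # reproducibility per seed
  pa <- split_dataset(ds, split_spec(0.2, 0.2, seed = 5))
  pb <- split_dataset(ds, split_spec(0.2, 0.2, seed = 5))
  expect_identical(pa$indices, pb$indices)

  # class with too few members
  bad <- strat
  bad$covariates$tissue[1:118] <- "a"
  bad$covariates$tissue[119:120] <- "rare"
  expect_error(split_dataset(bad, split_spec(0.2, 0.2,
                                             stratify_on = "tissue",
                                             seed = 1)),
               "fewer samples")
})

test_that("split partition property holds across random fractions and seeds", {
  ds <- default_sim(seed = 3, n = 97, d = 8)
  set.seed(42)
  for (i in 1:10) {
    v <- runif(1, 0.05, 0.4); t <- runif(1, 0.05, 0.4)
    p <- split_dataset(ds, split_spec(v, t, seed = i))
    idx <- p$indices
    expect_equal(sort(c(idx$train, idx$val, idx$test)), seq_len(97))
    expect_equal(length(idx$val), round(97 * v))
    expect_equal(length(idx$test), round(97 * t))
  }
})

test_that("gaussian noise augmentation copies labels and matches variance", {
  ds <- default_sim(seed = 4, n = 50, d = 30)
  # zero variance reproduces source rows
  aug0 <- gaussian_noise_augment(ds, 20, variance = 0, seed = 1)
  src <- attr(aug0, "source_idx")
  expect_equal(aug0$values, ds$values[src, ], ignore_attr = TRUE)
  expect_equal(aug0$covariates$cancer, ds$covariates$cancer[src])

  # counting and label provenance
  aug <- gaussian_noise_augment(ds, 1000, seed = 2)
  expect_equal(nrow(aug$values), 1000L)
  expect_true(all(aug$covariates$tissue %in% ds$covariates$tissue))
  expect_true(all(aug$values >= 0 & aug$values <= 1))
  # label distribution equals that of the source draw, exactly
  src <- attr(aug, "source_idx")
  expect_identical(aug$covariates$cancer, ds$covariates$cancer[src])

  # unclipped noise variance close to 0.1
  augu <- gaussian_noise_augment(ds, 4000, variance = 0.1, seed = 3,
                                 clip = FALSE)
  diff <- augu$values - ds$values[attr(augu, "source_idx"), ]
  per_gene_var <- apply(diff, 2, var)
  expect_true(all(per_gene_var > 0.08 & per_gene_var < 0.12))

  expect_error(gaussian_noise_augment(ds, 0), "positive")
})
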