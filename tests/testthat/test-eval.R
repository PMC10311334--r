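# Supervised harness: classifiers, augmentation gain, reverse validation,
# schedules and benchmark orchestration.

fast_spec <- function(task = "binary", hidden = 16L, epochs = 10L)
  classifier_spec(task, hidden_size = hidden, epochs = epochs)

test_that("classifier learns separable data and is deterministic", {
  tr <- make_separable(200, d = 10, seed = 1)
  te <- make_separable(200, d = 10, seed = 2)
  spec <- fast_spec(hidden = 32L, epochs = 30L)
  clf <- train_classifier(tr, spec, seed = 3)
  expect_gte(accuracy(clf, te), 0.95)

  clf2 <- train_classifier(tr, spec, seed = 3)
  expect_identical(predict_classifier(clf, te), predict_classifier(clf2, te))

  # single-class data errors
  one <- subset_samples(tr, which(tr$covariates$cancer == 1))
  expect_error(train_classifier(one, fast_spec()), "single-class")
})

test_that("random-label training yields chance-level accuracy", {
  ds <- default_sim(seed = 12, n = 300, d = 20)
  te <- default_sim(seed = 13, n = 300, d = 20)
  accs <- numeric(5)
  for (s in 1:5) {
    perm <- ds
    set.seed(s)
    perm$covariates$tissue <- sample(perm$covariates$tissue)
    clf <- train_classifier(perm, fast_spec("tissue", epochs = 5L), seed = s)
    accs[s] <- accuracy(clf, te)
  }
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.47)
})

test_that("accuracy counts correct predictions", {
  tr <- make_separable(100, seed = 4)
  clf <- train_classifier(tr, fast_spec(), seed = 1)
  # constant predictor: zero out the network, bias the first class
  const <- clf
  const$net$W <- lapply(const$net$W, function(w) w * 0)
  const$net$b[[length(const$net$b)]] <- c(10, 0)
  te <- make_separable(100, seed = 5)  # balanced labels
  expect_equal(accuracy(const, te), 0.5)
  expect_error(accuracy(clf, subset_samples(te, integer(0))), "empty")
})

test_that("augmentation gain is exactly zero at m = 0 and validates inputs", {
  pool <- default_sim(seed = 14, n = 120, d = 15)
  test <- default_sim(seed = 15, n = 100, d = 15)
  for (n_true in c(20, 57)) {
    res <- augmentation_gain(n_true, 0, pool, "gaussian_noise",
                             fast_spec(epochs = 3L), test, n_runs = 2,
                             seed_base = n_true)
    expect_identical(res$delta_acc, 0)
    expect_identical(res$runs$acc_with, res$runs$acc_without)
  }
  expect_error(augmentation_gain(500, 0, pool, "gaussian_noise",
                                 fast_spec(), test), "fewer")
  small_pool <- subset_samples(pool, 1:30)
  expect_error(augmentation_gain(10, 50, small_pool,
                                 subset_samples(pool, 1:20),
                                 fast_spec(epochs = 1L), test, n_runs = 1),
               "supplies only")
})

test_that("noise dilution hurts an easy task", {
  pool <- make_separable(600, d = 8, seed = 6)
  test <- make_separable(300, d = 8, seed = 7)
  noise_source <- function(m, seed) {
    set.seed(seed)
    expression_dataset(matrix(runif(m * 8), m, 8), pool$gene_ids,
                       paste0("n", seq_len(m)),
                       data.frame(age = 50, gender = "female",
                                  tissue = "lung",
                                  cancer = sample(0:1, m, TRUE)),
                       normalized = TRUE)
  }
  # the baseline must be near-converged, otherwise the extra gradient
  # steps contributed by the appended samples mask the dilution effect
  res <- augmentation_gain(500, 2000, pool, noise_source,
                           fast_spec(hidden = 32L, epochs = 30L), test,
                           n_runs = 3, seed_base = 1)
  expect_lte(res$delta_acc, 0)
})

test_that("reverse validation matches train-on-true for an identity generator", {
  ds <- default_sim(seed = 16, n = 200, d = 30)
  te <- default_sim(seed = 17, n = 200, d = 30)
  rv <- reverse_validation(ds, te, task = "binary", seed = 2)
  spec <- classifier_spec("binary", hidden_size = 512L, lr = 1e-4,
                          epochs = 35L, batch_size = 32L)
  direct <- accuracy(train_classifier(ds, spec, seed = 2), te)
  expect_equal(rv, direct)  # same spec, same seed, same data
  expect_error(reverse_validation(make_mixture(50, 1), te, task = "tissue"),
               "label")
})

test_that("centroid-coded generated data reach high reverse validation", {
  te <- make_separable(300, d = 6, seed = 8)
  cent0 <- colMeans(te$values[te$covariates$cancer == 0, ])
  cent1 <- colMeans(te$values[te$covariates$cancer == 1, ])
  gen <- expression_dataset(rbind(matrix(cent0, 100, 6, byrow = TRUE),
                                  matrix(cent1, 100, 6, byrow = TRUE)),
                            te$gene_ids, paste0("c", 1:200),
                            data.frame(age = 50, gender = "female",
                                       tissue = "lung",
                                       cancer = rep(0:1, each = 100)),
                            normalized = TRUE)
  expect_gte(reverse_validation(gen, te, task = "binary", seed = 1), 0.9)
})

test_that("run_schedule bookkeeping and degenerate grid", {
  pool <- default_sim(seed = 18, n = 100, d = 10)
  test <- default_sim(seed = 19, n = 80, d = 10)
  cv <- run_schedule("fixed_true", pool, test,
                     sources = list(noise = "gaussian_noise"),
                     spec = fast_spec(epochs = 2L), m_grid = c(0, 10),
                     n_true_fixed = 30, n_runs = 2, seed_base = 1)
  expect_s3_class(cv, "augmentation_curves")
  # m = 0 point equals the baseline accuracy
  aug0 <- cv[cv$source == "noise" & cv$m_generated == 0, ]
  base <- cv[cv$source == "none" & cv$n_true == 30, ]
  expect_equal(aug0$mean_accuracy, base$mean_accuracy[1])
  expect_true(all(cv$mean_accuracy >= 0 & cv$mean_accuracy <= 1))
  expect_error(run_schedule("fixed_true", pool, test,
                            sources = list(noise = "gaussian_noise"),
                            spec = fast_spec()), "m_grid")
})

test_that("benchmark with only the noise source and determinism", {
  cfg <- list(sim = list(n_samples = 90, n_genes = 12, n_tissues = 3,
                         block_size = 4, seed = 5),
              models = "gaussian_noise",
              eval = list(k = 5, n_runs = 2, tasks = "binary"),
              schedule = list(kind = "fixed_true", m_grid = c(5),
                              n_true_fixed = 20),
              train = list(epochs = 1),
              seed = 5)
  out <- withr::local_tempdir()
  res <- run_benchmark(cfg, out_dir = out)
  expect_identical(res$summary$sources, "gaussian_noise")
  expect_length(res$reports, 0)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "curves.csv")))

  res2 <- run_benchmark(cfg)
  expect_equal(res$curves$mean_accuracy, res2$curves$mean_accuracy)
})

test_that("benchmark trains a tiny generative model and reports it", {
  cfg <- list(sim = list(n_samples = 60, n_genes = 8, n_tissues = 2,
                         block_size = 4, seed = 6),
              models = c("gaussian_noise", "gan"),
              train = list(epochs = 2, d_z = 8, g_hidden = 16,
                           d_hidden = 16, batch_size = 32),
              eval = list(k = 3, n_runs = 2, tasks = "binary",
                          n_generated = 30),
              seed = 6)
  res <- suppressWarnings(run_benchmark(cfg))
  expect_named(res$reports, "gan")
  expect_s3_class(res$reports$gan, "metrics_report")
  expect_length(res$errors, 0)
  expect_setequal(res$summary$sources, c("gaussian_noise", "gan"))
})
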