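# Losses, gradient penalty, sparse attention, architectures, training
# bookkeeping and reproducibility.

test_that("gan_losses matches hand-evaluated objective values", {
  # maximal confusion
  l <- gan_losses(rep(0.5, 4), rep(0.5, 4))
  expect_equal(l$value, 2 * log(0.5), tolerance = 1e-12)
  # perfect discriminator (clamped at eps, so ~0)
  l2 <- gan_losses(rep(1, 3), rep(0, 3))
  expect_equal(l2$value, 0, tolerance = 1e-5)
  # direct evaluation
  l3 <- gan_losses(0.8, 0.3)
  expect_equal(l3$value, log(0.8) + log(0.7), tolerance = 1e-12)
  expect_equal(l3$discriminator_loss, -(log(0.8) + log(0.7)),
               tolerance = 1e-12)
  expect_equal(l3$generator_loss, -log(0.3), tolerance = 1e-12)
  expect_equal(l3$generator_loss_saturating, log(0.7), tolerance = 1e-12)
  expect_error(gan_losses(1.2, 0.5), "probabilities")
})

test_that("wgan_gp_losses follows the standard sign convention", {
  l <- wgan_gp_losses(1, 0, penalty = 0)
  expect_equal(l$wasserstein, 1)
  expect_equal(l$critic_loss, -1)
  expect_equal(wgan_gp_losses(c(3, 5), c(3, 5))$wasserstein, 0)
  l3 <- wgan_gp_losses(c(2, 4), c(1, 1), penalty = 0.5)
  expect_equal(l3$critic_loss, 1 - 3 + 0.5)
  expect_equal(l3$generator_loss, -1)
})

test_that("gradient penalty matches analytic critics", {
  set.seed(1)
  xt <- matrix(rnorm(20), 10, 2); xf <- matrix(rnorm(20), 10, 2)
  w <- c(3, 4) / 5  # unit norm
  unit <- list(grad = function(X) matrix(w, nrow(X), 2, byrow = TRUE))
  expect_equal(gradient_penalty(unit, xt, xf, 10, seed = 1), 0)
  const <- list(grad = function(X) matrix(0, nrow(X), ncol(X)))
  expect_equal(gradient_penalty(const, xt, xf, 7, seed = 1), 7)
  double <- list(grad = function(X) matrix(2 * w, nrow(X), 2, byrow = TRUE))
  expect_equal(gradient_penalty(double, xt, xf, 10, seed = 1), 10)
  # nonnegative for arbitrary MLP critics
  set.seed(2)
  net <- transaug:::mlp_init(c(2, 8, 1))
  expect_gte(gradient_penalty(net, xt, xf, 10, seed = 3), 0)
  expect_error(gradient_penalty(unit, xt, xf[1:5, ], 10), "shapes")
})

test_that("sparse attention reproduces the hand-worked softmin example", {
  m <- attention_mask(rbind(c(1L, 2L), c(2L, 1L)), 2, "coexp")
  p <- attention_params(m, gamma = 1)
  out <- sparse_attention(c(1, 2), p)
  a11 <- exp(0) / (exp(0) + exp(-1))
  expect_equal(out[1], 1 + a11 * 1 + (1 - a11) * 2, tolerance = 1e-12)
  expect_equal(out[1], 2.269, tolerance = 1e-3)

  # gamma = 0 is the identity
  p0 <- attention_params(m, gamma = 0)
  x <- runif(2)
  expect_identical(sparse_attention(x, p0), x)

  # two neighbors at equal scores share the weight
  w <- attention_weights(c(0.5, 0.5), p, gene = 1)
  expect_equal(unname(w), c(0.5, 0.5))
})

test_that("softmin weights sum to one over every neighborhood", {
  set.seed(3)
  d <- 25
  mask <- random_mask(d, 80, seed = 3)
  p <- attention_params(mask, w_k = rnorm(d, 1, 0.3), w_q = rnorm(d, 1, 0.3),
                        w_v = rnorm(d), gamma = 0.5)
  for (rep in 1:5) {
    x <- runif(d)
    for (g in sample.int(d, 5))
      expect_equal(sum(attention_weights(x, p, g)), 1, tolerance = 1e-6)
  }
})

test_that("attention backward matches finite differences", {
  ta <- asNamespace("transaug")
  set.seed(4)
  d <- 8; B <- 3
  mask <- random_mask(d, 20, seed = 4)
  par <- attention_params(mask, w_k = rnorm(d, 1, 0.2),
                          w_q = rnorm(d, 1, 0.2), w_v = rnorm(d, 0, 0.5),
                          gamma = 0.6)
  prep <- ta$att_prepare(mask)
  X <- matrix(runif(B * d), B, d)
  dY <- matrix(rnorm(B * d), B, d)
  fw <- ta$att_forward(X, par, prep)
  bk <- ta$att_backward(dY, X, par, prep, fw)
  lossf <- function(par2, X2) sum(dY * ta$att_forward(X2, par2, prep)$Y)
  eps <- 1e-6
  num_dx <- (lossf(par, X + eps * (row(X) == 2 & col(X) == 3)) -
             lossf(par, X - eps * (row(X) == 2 & col(X) == 3))) / (2 * eps)
  expect_equal(num_dx, bk$dX[2, 3], tolerance = 1e-5)
  for (nm in c("w_k", "w_q", "w_v")) {
    j <- 5
    pp <- par; pp[[nm]][j] <- pp[[nm]][j] + eps
    pm <- par; pm[[nm]][j] <- pm[[nm]][j] - eps
    num <- (lossf(pp, X) - lossf(pm, X)) / (2 * eps)
    grad <- bk[[paste0("d", sub("_", "", nm))]][j]
    expect_equal(num, grad, tolerance = 1e-5)
  }
})

test_that("as_printed attention collapses to a per-gene rescaling", {
  d <- 6
  mask <- random_mask(d, 12, seed = 5)
  set.seed(5)
  wv <- rnorm(d)
  p <- attention_params(mask, w_v = wv, gamma = 0.9, as_printed = TRUE)
  x <- runif(d)
  expect_equal(sparse_attention(x, p), x + 0.9 * wv * x, tolerance = 1e-12)
})

test_that("generator contracts: shape, bounds, seeding, mask requirement", {
  cfg <- toy_train_config("wgan_gp", epochs = 1)
  set.seed(1)
  g1 <- build_generator(cfg, n_genes = 12, covariate_dims = 0)
  set.seed(1)
  g2 <- build_generator(cfg, n_genes = 12, covariate_dims = 0)
  expect_identical(g1$net$W, g2$net$W)
  Z <- matrix(rnorm(7 * cfg$d_z), 7, cfg$d_z)
  out <- transaug:::gen_forward(g1, Z)$X
  expect_equal(dim(out), c(7L, 12L))
  expect_true(all(out >= 0 & out <= 1))
  acfg <- toy_train_config("attgan", epochs = 1)
  expect_error(build_generator(acfg, 12, 0, mask = NULL), "mask")
})

test_that("training bookkeeping, determinism and generation contracts", {
  ds <- make_mixture(80, seed = 21)
  cfg <- toy_train_config("wgan_gp", epochs = 1, batch_size = 80,
                          conditional = FALSE, seed = 3)
  m <- train_gan(ds, cfg)
  expect_length(m$history$g_loss, 1L)
  expect_length(m$history$d_loss, 1L)
  expect_true(is.finite(m$history$wasserstein))

  gen1 <- generate_expression(m, 50, seed = 7)
  gen2 <- generate_expression(m, 50, seed = 7)
  expect_identical(gen1$values, gen2$values)
  expect_equal(nrow(gen1$values), 50L)
  expect_true(all(gen1$values >= 0 & gen1$values <= 1))
  expect_error(generate_expression(m, 0), "positive")

  # conditional path: generated covariate patterns are observed patterns
  ds2 <- default_sim(seed = 22, n = 60, d = 12)
  cfg2 <- toy_train_config("gan", epochs = 2, batch_size = 60, seed = 4)
  m2 <- train_gan(ds2, cfg2)
  g <- generate_expression(m2, 200, seed = 1)
  obs <- unique(paste(ds2$covariates$gender, ds2$covariates$tissue,
                      ds2$covariates$cancer))
  expect_true(all(paste(g$covariates$gender, g$covariates$tissue,
                        g$covariates$cancer) %in% obs))
})

test_that("gamma-fixed-at-0 attention training equals the attention-free run", {
  ds <- make_mixture(60, seed = 23)
  mask <- random_mask(2, 2, seed = 1)
  cfg_att <- toy_train_config("attgan", epochs = 2, batch_size = 60,
                              conditional = FALSE, gamma_mode = "fixed",
                              gamma = 0, seed = 5)
  cfg_plain <- toy_train_config("wgan_gp", epochs = 2, batch_size = 60,
                                conditional = FALSE, seed = 5)
  m_att <- train_gan(ds, cfg_att, mask = mask)
  m_plain <- train_gan(ds, cfg_plain)
  expect_equal(m_att$history$d_loss, m_plain$history$d_loss,
               tolerance = 1e-12)
  expect_equal(m_att$history$g_loss, m_plain$history$g_loss,
               tolerance = 1e-12)
  expect_equal(m_att$generator$net$W, m_plain$generator$net$W,
               tolerance = 1e-12)
})

test_that("rand_attgan permutes the mask before training", {
  ds <- default_sim(seed = 24, n = 40, d = 15)
  mask <- random_mask(15, 30, seed = 2)
  cfg <- toy_train_config("rand_attgan", epochs = 1, batch_size = 40,
                          seed = 6)
  m <- train_gan(ds, cfg, mask = mask)
  expect_identical(m$mask$provenance, "random")
  expect_equal(mask_size(m$mask), mask_size(mask))
  expect_equal(sort(mask_degrees(m$mask)), sort(mask_degrees(mask)))
})

test_that("pretraining freezes attention during warm-up epochs", {
  ds <- make_mixture(60, seed = 25)
  mask <- random_mask(2, 2, seed = 1)
  cfg <- toy_train_config("attgan", epochs = 1, pretrain_epochs = 2,
                          batch_size = 60, conditional = FALSE,
                          gamma_mode = "learned", seed = 7)
  m <- train_gan(ds, cfg, mask = mask)
  # history covers only the post-warm-up epochs
  expect_length(m$history$g_loss, 1L)
  expect_true(is.finite(m$history$g_loss))
})
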