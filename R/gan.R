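# Generative adversarial models for expression data.
#
# Three training objectives are provided: the original min-max GAN loss
# (with the non-saturating generator variant used for optimization), the
# WGAN-GP loss with a gradient penalty enforcing a 1-Lipschitz critic, and
# their conditional variants (covariate one-hots concatenated to both the
# generator input and the critic input).  The attention GAN appends a
# sparse softmin/L1 attention layer that polishes the primary generator
# output over masked gene pairs.

#' GAN discriminator/generator losses
#'
#' For sigmoid discriminator outputs `d_true` (real batch) and `d_fake`
#' (generated batch), the discriminator loss is
#' `-mean(log d_true) - mean(log(1 - d_fake))`; the generator is trained
#' with the non-saturating form `-mean(log d_fake)` (the saturating value
#' `mean(log(1 - d_fake))` is reported too, as is the min-max objective
#' value `mean(log d_true) + mean(log(1 - d_fake))`).  Outputs outside
#' \[0,1\] are a domain error; values at exactly 0 or 1 are clamped by
#' `eps` before taking logs.
#'
#' @param d_true,d_fake numeric vectors of discriminator probabilities.
#' @param eps clamping epsilon, default 1e-7.
#' @return List with `discriminator_loss`, `generator_loss`,
#'   `generator_loss_saturating`, and `value` (the min-max objective).
#' @export
gan_losses <- function(d_true, d_fake, eps = 1e-7) {
  if (any(d_true < 0 | d_true > 1) || any(d_fake < 0 | d_fake > 1))
    stop("discriminator outputs must be probabilities in [0, 1]")
  d_true <- pmin(pmax(d_true, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  list(discriminator_loss = -mean(log(d_true)) - mean(log(1 - d_fake)),
       generator_loss = -mean(log(d_fake)),
       generator_loss_saturating = mean(log(1 - d_fake)),
       value = mean(log(d_true)) + mean(log(1 - d_fake)))
}

#' WGAN-GP critic/generator losses
#'
#' Standard sign convention: the critic minimizes
#' `mean(d_fake) - mean(d_true) + penalty`, the generator minimizes
#' `-mean(d_fake)`; the Wasserstein estimate
#' `mean(d_true) - mean(d_fake)` is returned alongside.
#'
#' @param d_true,d_fake numeric vectors of unconstrained critic scores.
#' @param penalty gradient-penalty term (already scaled by lambda).
#' @return List with `critic_loss`, `generator_loss`, `wasserstein`.
#' @export
wgan_gp_losses <- function(d_true, d_fake, penalty = 0) {
  list(critic_loss = mean(d_fake) - mean(d_true) + penalty,
       generator_loss = -mean(d_fake),
       wasserstein = mean(d_true) - mean(d_fake))
}

#' WGAN gradient penalty
#'
#' Interpolates `x_tilde = u * x_true + (1 - u) * x_fake` with one uniform
#' `u` per sample and returns
#' `lambda * mean((||grad_x D(x_tilde)||_2 - 1)^2)`.
#'
#' @param critic either a network of class `transaug_mlp` (a trained
#'   critic, scalar output) or a list with an element `grad`, a function
#'   mapping a batch matrix to the matrix of input gradients of D (used
#'   for analytic test critics).
#' @param x_true,x_fake batch matrices of identical shape.
#' @param lambda penalty weight (>= 0), default 10.
#' @param seed optional seed for the interpolation draw.
#' @return Scalar penalty value.
#' @export
gradient_penalty <- function(critic, x_true, x_fake, lambda = 10,
                             seed = NULL) {
  x_true <- as.matrix(x_true); x_fake <- as.matrix(x_fake)
  if (!all(dim(x_true) == dim(x_fake)))
    stop("x_true and x_fake must have identical shapes")
  if (lambda < 0) stop("lambda must be >= 0")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  u <- stats::runif(nrow(x_true))
  xi <- x_true * u + x_fake * (1 - u)
  g <- if (inherits(critic, "transaug_mlp")) {
    fwd <- mlp_forward(critic, xi)
    mlp_input_grad(critic, fwd)$g
  } else if (is.list(critic) && is.function(critic$grad)) {
    critic$grad(xi)
  } else stop("critic must be a transaug_mlp or a list with a grad function")
  lambda * mean((sqrt(rowSums(g^2)) - 1)^2)
}

# ---------------------------------------------------------------------------
# Covariate conditioning

# One-hot encoder for the conditional models: age standardized (z-score on
# the fitting data), gender/tissue one-hot, cancer as a single 0/1 column.
# Covariate columns that are entirely NA are dropped.
build_cov_encoder <- function(covariates) {
  enc <- list()
  if (!all(is.na(covariates$age))) {
    mu <- mean(covariates$age, na.rm = TRUE)
    sdv <- stats::sd(covariates$age, na.rm = TRUE)
    enc$age <- list(mu = mu, sd = if (is.na(sdv) || sdv == 0) 1 else sdv)
  }
  for (v in c("gender", "tissue")) {
    x <- covariates[[v]]
    if (!all(is.na(x))) enc[[v]] <- sort(unique(as.character(x)))
  }
  if (!all(is.na(covariates$cancer))) enc$cancer <- TRUE
  enc
}

encode_covariates <- function(enc, covariates) {
  n <- nrow(covariates)
  cols <- list()
  if (!is.null(enc$age))
    cols$age <- (covariates$age - enc$age$mu) / enc$age$sd
  for (v in c("gender", "tissue")) {
    if (is.null(enc[[v]])) next
    lev <- enc[[v]]
    m <- matrix(0, n, length(lev),
                dimnames = list(NULL, paste0(v, "_", lev)))
    hit <- match(as.character(covariates[[v]]), lev)
    ok <- !is.na(hit)
    m[cbind(which(ok), hit[ok])] <- 1
    cols[[v]] <- m
  }
  if (!is.null(enc$cancer)) cols$cancer <- as.numeric(covariates$cancer)
  if (length(cols) == 0) return(matrix(0, n, 0))
  do.call(cbind, cols)
}

# ---------------------------------------------------------------------------
# Configuration

#' Configure generative-model training
#'
#' @param model_kind one of `"gan"`, `"wgan_gp"`, `"attgan"`,
#'   `"rand_attgan"`.
#' @param epochs training epochs (default 800).
#' @param batch_size minibatch size (default 64).
#' @param lr_g,lr_d Adam learning rates for generator and
#'   discriminator/critic; defaults 2e-4/2e-4 (GAN) or 1e-4/4e-4 (WGAN
#'   family, a two-time-scale update rule keeping the critic near
#'   optimality).
#' @param beta1,beta2 Adam moment decays; defaults (0.5, 0.999) for GAN
#'   and (0.5, 0.9) for the WGAN family (community-standard settings).
#' @param lambda_gp gradient-penalty weight (>= 0), default 10.
#' @param n_critic critic updates per generator update; default 1 for
#'   plain GAN, 5 for the WGAN family.
#' @param gamma_mode `"fixed"` or `"learned"` attention mixing weight.
#' @param gamma value of the fixed gamma (ignored when learned; a learned
#'   gamma starts at 0).
#' @param pretrain_epochs attention-free warm-up epochs (gamma forced to 0
#'   and attention parameters frozen) before attention is enabled.
#' @param d_z latent dimension (default 64).
#' @param g_hidden,d_hidden integer vectors of hidden-layer widths;
#'   default `c(128, 128)`.
#' @param conditional condition both networks on the observed covariate
#'   patterns (default `TRUE`; ignored when the data carry no usable
#'   covariates).
#' @param as_printed use the degenerate self-value attention aggregation
#'   (see [attention_params()]).
#' @param seed integer seed governing initialization and the training
#'   stream.
#' @return A `train_config` object.
#' @export
train_config <- function(model_kind = c("gan", "wgan_gp", "attgan",
                                        "rand_attgan"),
                         epochs = 800L, batch_size = 64L,
                         lr_g = NULL, lr_d = NULL,
                         beta1 = NULL, beta2 = NULL,
                         lambda_gp = 10, n_critic = NULL,
                         gamma_mode = c("fixed", "learned"), gamma = 1,
                         pretrain_epochs = 0L, d_z = 64L,
                         g_hidden = c(128L, 128L), d_hidden = c(128L, 128L),
                         conditional = TRUE, as_printed = FALSE, seed = 0L) {
  model_kind <- match.arg(model_kind)
  gamma_mode <- match.arg(gamma_mode)
  wgan <- model_kind != "gan"
  # two-time-scale update rule for the WGAN family: the critic must stay
  # near its optimum for the Wasserstein estimate to be meaningful
  if (is.null(lr_g)) lr_g <- if (wgan) 1e-4 else 2e-4
  if (is.null(lr_d)) lr_d <- if (wgan) 4e-4 else 2e-4
  if (is.null(beta1)) beta1 <- 0.5
  if (is.null(beta2)) beta2 <- if (wgan) 0.9 else 0.999
  if (is.null(n_critic)) n_critic <- if (wgan) 5L else 1L
  if (lambda_gp < 0) stop("lambda_gp must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(model_kind = model_kind, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_g = lr_g,
                 lr_d = lr_d, beta1 = beta1, beta2 = beta2,
                 lambda_gp = lambda_gp, n_critic = as.integer(n_critic),
                 gamma_mode = gamma_mode, gamma = gamma,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 d_z = as.integer(d_z), g_hidden = as.integer(g_hidden),
                 d_hidden = as.integer(d_hidden),
                 conditional = isTRUE(conditional),
                 as_printed = isTRUE(as_printed), seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' Shrinks the architecture and budget for toy problems and tests.
#' @param model_kind model family, as in [train_config()].
#' @param epochs epochs (default 200).
#' @param ... further overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
toy_train_config <- function(model_kind = "wgan_gp", epochs = 200L, ...) {
  args <- list(...)
  defaults <- list(d_z = 16L, g_hidden = c(64L, 64L), d_hidden = c(64L, 64L),
                   batch_size = 64L)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(train_config, c(list(model_kind = model_kind, epochs = epochs),
                          args))
}

# ---------------------------------------------------------------------------
# Architectures

#' Build a generator network
#'
#' A multilayer perceptron mapping `(z, covariate encoding)` to an
#' expression vector with a bounded (sigmoid) output in \[0,1\].  When a
#' mask is supplied, a sparse attention layer polishes the primary output.
#' Uses the current RNG stream, so initialization is reproducible under
#' `set.seed()`.
#'
#' @param config a [train_config()].
#' @param n_genes output dimension.
#' @param covariate_dims number of conditioning columns (0 for
#'   unconditional).
#' @param mask optional [attention_mask()]; required for the attention
#'   model kinds.
#' @return A `transaug_generator` (network + optional attention params).
#' @export
build_generator <- function(config, n_genes, covariate_dims = 0L,
                            mask = NULL) {
  attn <- config$model_kind %in% c("attgan", "rand_attgan")
  if (attn && is.null(mask))
    stop("attention model requested but no attention mask supplied")
  net <- mlp_init(c(config$d_z + covariate_dims, config$g_hidden, n_genes),
                  act = "relu", out_act = "sigmoid")
  att <- NULL; prep <- NULL
  if (attn) {
    gamma0 <- if (config$gamma_mode == "learned") 0 else config$gamma
    att <- attention_params(mask,
                            w_k = stats::rnorm(n_genes, 1, 0.05),
                            w_q = stats::rnorm(n_genes, 1, 0.05),
                            w_v = stats::rnorm(n_genes, 0, 0.05),
                            gamma = gamma0, as_printed = config$as_printed)
    prep <- att_prepare(mask)
  }
  structure(list(net = net, att = att, prep = prep, d_z = config$d_z,
                 covariate_dims = covariate_dims, n_genes = n_genes),
            class = "transaug_generator")
}

build_discriminator <- function(config, n_genes, covariate_dims = 0L) {
  # linear output: logits for the GAN loss, scores for the WGAN critic
  mlp_init(c(n_genes + covariate_dims, config$d_hidden, 1L),
           act = "relu", out_act = "linear")
}

gen_forward <- function(gen, Z, gamma_override = NULL) {
  fwd <- mlp_forward(gen$net, Z)
  X <- fwd$out
  attc <- NULL
  if (!is.null(gen$att)) {
    par <- gen$att
    if (!is.null(gamma_override)) par$gamma <- gamma_override
    attc <- att_forward(X, par, gen$prep)
    X <- attc$Y
  }
  list(X = X, fwd = fwd, attc = attc, Xpre = fwd$out)
}

# returns grads structured as list(net = list(dW, db), att = list(...))
gen_backward <- function(gen, cache, dX, gamma_override = NULL,
                         freeze_att = FALSE) {
  att_grads <- NULL
  if (!is.null(gen$att)) {
    par <- gen$att
    if (!is.null(gamma_override)) par$gamma <- gamma_override
    ab <- att_backward(dX, cache$Xpre, par, gen$prep, cache$attc)
    dX <- ab$dX
    att_grads <- if (freeze_att) NULL
                 else list(w_k = ab$dwk, w_q = ab$dwq, w_v = ab$dwv,
                           gamma = ab$dgamma)
  }
  bk <- mlp_backward(gen$net, cache$fwd, dX)
  list(net = list(dW = bk$dW, db = bk$db), att = att_grads)
}

# ---------------------------------------------------------------------------
# Training

#' Train a generative model on an expression dataset
#'
#' Alternates `n_critic` discriminator/critic updates per generator update
#' (1 for the plain GAN).  When conditioning is active, the covariate
#' encoding is concatenated to both the generator input and the critic
#' input; generated batches draw covariate patterns observed in the
#' training data with replacement.  For the attention kinds, an optional
#' attention-free warm-up (`pretrain_epochs` with gamma forced to 0 and
#' attention parameters frozen) precedes attention-enabled training; the
#' `rand_attgan` kind first replaces the supplied mask with its
#' degree-preserving random permutation (lesion control).  Training is
#' deterministic for a fixed seed.  A non-finite loss aborts with a
#' diagnostic naming the epoch and the loss components.
#'
#' @param train_data normalized `expression_dataset` (values in \[0,1\]).
#' @param config a [train_config()].
#' @param mask [attention_mask()], required for attention model kinds.
#' @return A `transaug_gan` model: generator, discriminator, covariate
#'   encoder, per-epoch loss history, config snapshot and seed.
#' @export
train_gan <- function(train_data, config, mask = NULL) {
  stopifnot(inherits(train_data, "expression_dataset"),
            inherits(config, "train_config"))
  X <- train_data$values
  if (min(X) < -1e-9 || max(X) > 1 + 1e-9)
    warning("training values outside [0,1]; the generator output is bounded")
  n <- nrow(X); d <- ncol(X)
  wgan <- config$model_kind != "gan"

  if (config$model_kind == "rand_attgan") {
    if (is.null(mask)) stop("rand_attgan requires a source mask")
    mask <- random_permutation_mask(mask, seed = config$seed)
  }

  enc <- NULL; Cenc <- matrix(0, n, 0)
  if (config$conditional) {
    enc <- build_cov_encoder(train_data$covariates)
    Cenc <- encode_covariates(enc, train_data$covariates)
    if (ncol(Cenc) == 0) enc <- NULL
  }
  c_dim <- ncol(Cenc)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  # discriminator first: the generator's optional attention parameters
  # consume extra draws, and the discriminator initialization must not
  # depend on whether attention is present
  dis <- build_discriminator(config, d, c_dim)
  gen <- build_generator(config, d, c_dim, mask)

  g_params <- list(W = gen$net$W, b = gen$net$b)
  has_att <- !is.null(gen$att)
  if (has_att)
    g_params$att <- list(w_k = gen$att$w_k, w_q = gen$att$w_q,
                         w_v = gen$att$w_v, gamma = gen$att$gamma)
  d_params <- list(W = dis$W, b = dis$b)
  g_state <- adam_init(g_params)
  d_state <- adam_init(d_params)

  sync_gen <- function() {
    gen$net$W <<- g_params$W; gen$net$b <<- g_params$b
    if (has_att) {
      gen$att$w_k <<- g_params$att$w_k; gen$att$w_q <<- g_params$att$w_q
      gen$att$w_v <<- g_params$att$w_v; gen$att$gamma <<- g_params$att$gamma
    }
  }
  sync_dis <- function() { dis$W <<- d_params$W; dis$b <<- d_params$b }

  B <- min(config$batch_size, n)
  steps_per_epoch <- max(1L, ceiling(n / B))
  hist <- list(d_loss = numeric(config$epochs),
               g_loss = numeric(config$epochs),
               wasserstein = if (wgan) numeric(config$epochs) else NULL,
               g_loss_saturating = if (!wgan) numeric(config$epochs) else NULL,
               penalty = if (wgan) numeric(config$epochs) else NULL)

  draw_fake_inputs <- function() {
    pidx <- sample.int(n, B, replace = TRUE)
    Z <- matrix(stats::rnorm(B * config$d_z), B, config$d_z)
    list(Z = cbind(Z, Cenc[pidx, , drop = FALSE]),
         C = Cenc[pidx, , drop = FALSE])
  }

  # re-seed so that the training stream does not depend on how many draws
  # initialization consumed (keeps gamma=0 attention trajectories
  # bit-identical to the attention-free architecture)
  set.seed(config$seed)
  total_epochs <- config$pretrain_epochs + config$epochs
  for (ep in seq_len(total_epochs)) {
    pretrain <- ep <= config$pretrain_epochs
    gamma_override <- if (pretrain && has_att) 0 else NULL
    ep_rec <- if (pretrain) NULL else ep - config$pretrain_epochs
    acc <- c(d = 0, g = 0, w = 0, p = 0, sat = 0)
    for (st in seq_len(steps_per_epoch)) {
      for (ct in seq_len(config$n_critic)) {
        idx <- sample.int(n, B, replace = B > n)
        inr <- cbind(X[idx, , drop = FALSE], Cenc[idx, , drop = FALSE])
        fk <- draw_fake_inputs()
        gf <- gen_forward(gen, fk$Z, gamma_override)
        inf <- cbind(gf$X, fk$C)
        fr <- mlp_forward(dis, inr)
        ff <- mlp_forward(dis, inf)
        if (wgan) {
          bk_r <- mlp_backward(dis, fr, matrix(-1 / B, B, 1))
          bk_f <- mlp_backward(dis, ff, matrix(1 / B, B, 1))
          u <- stats::runif(B)
          xi <- inr * u + inf * (1 - u)
          fi <- mlp_forward(dis, xi)
          ig <- mlp_input_grad(dis, fi)
          gp <- mlp_gp_grads(dis, fi, ig, config$lambda_gp)
          grads <- list(W = add_grads(add_grads(bk_r$dW, bk_f$dW), gp$dW),
                        b = add_grads(add_grads(bk_r$db, bk_f$db), gp$db))
          losses <- wgan_gp_losses(fr$out, ff$out, gp$penalty)
          acc["d"] <- acc["d"] + losses$critic_loss
          acc["w"] <- acc["w"] + losses$wasserstein
          acc["p"] <- acc["p"] + gp$penalty
        } else {
          pr <- 1 / (1 + exp(-fr$out)); pf <- 1 / (1 + exp(-ff$out))
          bk_r <- mlp_backward(dis, fr, -(1 - pr) / B)
          bk_f <- mlp_backward(dis, ff, pf / B)
          grads <- list(W = add_grads(bk_r$dW, bk_f$dW),
                        b = add_grads(bk_r$db, bk_f$db))
          losses <- gan_losses(pr, pf)
          acc["d"] <- acc["d"] + losses$discriminator_loss
        }
        upd <- adam_step(d_params, grads, d_state, config$lr_d,
                         config$beta1, config$beta2)
        d_params <- upd$params; d_state <- upd$state
        sync_dis()
      }
      # generator step
      fk <- draw_fake_inputs()
      gf <- gen_forward(gen, fk$Z, gamma_override)
      inf <- cbind(gf$X, fk$C)
      ff <- mlp_forward(dis, inf)
      if (wgan) {
        dOut <- matrix(-1 / B, B, 1)
        acc["g"] <- acc["g"] + (-mean(ff$out))
      } else {
        pf <- 1 / (1 + exp(-ff$out))
        dOut <- -(1 - pf) / B
        acc["g"] <- acc["g"] + (-mean(log(pmax(pf, 1e-7))))
        acc["sat"] <- acc["sat"] + mean(log(pmax(1 - pf, 1e-7)))
      }
      bkD <- mlp_backward(dis, ff, dOut, need_input_grad = TRUE)
      dXgene <- bkD$dX[, seq_len(d), drop = FALSE]
      gb <- gen_backward(gen, gf, dXgene, gamma_override,
                         freeze_att = pretrain)
      grads <- list(W = gb$net$dW, b = gb$net$db)
      if (has_att && !pretrain) {
        if (config$gamma_mode == "fixed") gb$att$gamma <- 0
        grads$att <- gb$att
      }
      upd <- adam_step(g_params, grads, g_state, config$lr_g,
                       config$beta1, config$beta2)
      g_params <- upd$params; g_state <- upd$state
      sync_gen()
    }
    acc <- acc / steps_per_epoch
    acc[c("d", "g")] <- acc[c("d", "g")] /
      c(config$n_critic, 1)
    if (!all(is.finite(acc[c("d", "g")])))
      stop("non-finite loss at epoch ", ep, " (d_loss = ", acc["d"],
           ", g_loss = ", acc["g"], "); try lowering the learning rates")
    if (!is.null(ep_rec)) {
      hist$d_loss[ep_rec] <- acc["d"]
      hist$g_loss[ep_rec] <- acc["g"]
      if (wgan) {
        hist$wasserstein[ep_rec] <- acc["w"] / config$n_critic
        hist$penalty[ep_rec] <- acc["p"] / config$n_critic
      } else hist$g_loss_saturating[ep_rec] <- acc["sat"]
    }
  }

  structure(list(generator = gen, discriminator = dis, encoder = enc,
                 config = config, mask = mask, history = hist,
                 gene_ids = train_data$gene_ids,
                 train_covariates = train_data$covariates,
                 seed = config$seed),
            class = "transaug_gan")
}

#' @export
print.transaug_gan <- function(x, ...) {
  cat("<transaug_gan> ", x$config$model_kind, ", ", x$config$epochs,
      " epochs, ", length(x$gene_ids), " genes",
      if (!is.null(x$encoder)) ", conditional" else "", "\n", sep = "")
  invisible(x)
}

#' Generate expression samples from a trained model
#'
#' Each sample draws one covariate pattern observed in `covariate_source`
#' (with replacement, so the empirical pattern distribution is respected)
#' and one standard-Gaussian latent vector; the generated rows carry the
#' sampled covariates as labels.  Output values are clipped to \[0,1\].
#'
#' @param model a `transaug_gan` from [train_gan()].
#' @param m number of samples to generate (> 0).
#' @param covariate_source `expression_dataset` supplying the empirical
#'   covariate-pattern distribution; defaults to the training covariates
#'   stored in the model.
#' @param seed integer seed; generation is reproducible per seed.
#' @return An `expression_dataset` of `m` generated samples.
#' @export
generate_expression <- function(model, m, covariate_source = NULL,
                                seed = 0L) {
  stopifnot(inherits(model, "transaug_gan"))
  if (!is.numeric(m) || m <= 0) stop("m must be a positive count")
  m <- as.integer(m)
  cov <- if (is.null(covariate_source)) model$train_covariates
         else covariate_source$covariates
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pidx <- sample.int(nrow(cov), m, replace = TRUE)
  covs <- cov[pidx, , drop = FALSE]
  C <- if (is.null(model$encoder)) matrix(0, m, 0)
       else encode_covariates(model$encoder, covs)
  Z <- cbind(matrix(stats::rnorm(m * model$generator$d_z), m,
                    model$generator$d_z), C)
  X <- gen_forward(model$generator, Z)$X
  X <- pmin(pmax(X, 0), 1)
  expression_dataset(X, model$gene_ids, paste0("gen", seq_len(m)), covs,
                     normalized = TRUE)
}
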