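# Minimal dense neural-network engine.
#
# All generative models and classifiers in this package are small
# multilayer perceptrons; this file provides their shared machinery:
# initialization, forward/backward passes, Adam, gradients of a scalar
# critic with respect to its *inputs*, and the exact parameter gradient of
# the WGAN gradient penalty for piecewise-linear (ReLU-family) critics.
# Everything runs on base-R matrix algebra: batches are B x d matrices,
# layer l maps through U = Z %*% W_l + b_l.

act_forward <- function(name, U) {
  switch(name,
         linear = U,
         relu = pmax(U, 0),
         lrelu = ifelse(U > 0, U, 0.2 * U),
         sigmoid = 1 / (1 + exp(-U)),
         tanh = tanh(U),
         stop("unknown activation: ", name))
}

# derivative as a function of pre-activation U and activation Z
act_grad <- function(name, U, Z) {
  switch(name,
         linear = 1,
         relu = (U > 0) * 1,
         lrelu = ifelse(U > 0, 1, 0.2),
         sigmoid = Z * (1 - Z),
         tanh = 1 - Z^2,
         stop("unknown activation: ", name))
}

# sizes: c(n_in, hidden..., n_out); draws from the current RNG stream
mlp_init <- function(sizes, act = "relu", out_act = "linear") {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sd <- if (l < L && act %in% c("relu", "lrelu")) sqrt(2 / fan_in)
          else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(W = W, b = b, act = act, out_act = out_act, sizes = sizes),
            class = "transaug_mlp")
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  Z <- vector("list", L + 1L); U <- vector("list", L)
  Z[[1]] <- X
  for (l in seq_len(L)) {
    U[[l]] <- sweep(Z[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    nm <- if (l == L) net$out_act else net$act
    Z[[l + 1L]] <- act_forward(nm, U[[l]])
  }
  list(out = Z[[L + 1L]], Z = Z, U = U)
}

# dOut: gradient of the loss w.r.t. the network output (B x n_out).
# Returns per-layer weight/bias gradients (summed over the batch; divide
# by B upstream if a mean is wanted) and the gradient w.r.t. the input.
mlp_backward <- function(net, fwd, dOut, need_input_grad = FALSE) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  E <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    nm <- if (l == L) net$out_act else net$act
    e <- d * act_grad(nm, fwd$U[[l]], fwd$Z[[l + 1L]])
    dW[[l]] <- crossprod(fwd$Z[[l]], e)
    db[[l]] <- colSums(e)
    E[[l]] <- e
    if (l > 1L || need_input_grad) d <- tcrossprod(e, net$W[[l]])
  }
  list(dW = dW, db = db, dX = if (need_input_grad) d else NULL, E = E)
}

# Gradient of a scalar-output network w.r.t. its input, batched, together
# with the backward caches needed by the gradient-penalty derivative.
mlp_input_grad <- function(net, fwd) {
  B <- nrow(fwd$Z[[1L]])
  stopifnot(ncol(fwd$out) == 1L)
  bk <- mlp_backward(net, fwd, matrix(1, B, 1L), need_input_grad = TRUE)
  list(g = bk$dX, E = bk$E)
}

# Exact parameter gradient of P = lambda * mean_b (||g_b|| - 1)^2 where
# g_b is the critic's input gradient at interpolate b, valid for critics
# whose hidden activations are piecewise linear (relu/lrelu/linear: the
# activation pattern has zero second derivative almost everywhere).
# Derivation: with masks frozen, s_b = r_b . g_b is linear in each W_l and
# d s/d W_l = V_{l-1}^T E_l, where V is a forward tangent pass seeded with
# r_b = d(||g||-1)^2 / d g and E_l the backward caches of the input-grad
# pass.  Biases receive zero gradient.
mlp_gp_grads <- function(net, fwd, ig, lambda) {
  g <- ig$g
  B <- nrow(g)
  nrm <- sqrt(rowSums(g^2))
  penalty <- lambda * mean((nrm - 1)^2)
  coef <- 2 * (nrm - 1) / pmax(nrm, 1e-12)
  R <- g * coef                      # d penalty-sum / d g, up to lambda/B
  L <- length(net$W)
  V <- R
  dW <- vector("list", L); db <- vector("list", L)
  for (l in seq_len(L)) {
    nm <- if (l == L) net$out_act else net$act
    dW[[l]] <- (lambda / B) * crossprod(V, ig$E[[l]])
    db[[l]] <- numeric(length(net$b[[l]]))
    Tl <- V %*% net$W[[l]]
    V <- Tl * act_grad(nm, fwd$U[[l]], fwd$Z[[l + 1L]])
  }
  list(penalty = penalty, dW = dW, db = db)
}

# --- Adam over arbitrary nested lists of numeric arrays -------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

.adam_rec <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (k in keys) {
      gk <- if (is.character(k) && !k %in% names(g)) NULL else g[[k]]
      if (is.null(gk)) next
      r <- .adam_rec(p[[k]], gk, m[[k]], v[[k]], lr_t, beta1, beta2, eps)
      out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m2 <- beta1 * m + (1 - beta1) * g
  v2 <- beta2 * v + (1 - beta2) * g^2
  list(p = p - lr_t * m2 / (sqrt(v2) + eps), m = m2, v = v2)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  r <- .adam_rec(params, grads, state$m, state$v, lr_t, beta1, beta2, eps)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}
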