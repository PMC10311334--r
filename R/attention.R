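# Sparse softmin/L1 self-attention over masked gene pairs.
#
# Genes are scalars, so attention scores use the L1 distance between key-
# and query-scaled gene values rather than a dot product, and the usual
# softmax becomes a softmin: small discrepancies get large weights.  Only
# pairs present in the attention mask (plus each gene's self pair) ever
# interact, keeping memory linear in the number of masked pairs.

#' Construct sparse attention-layer parameters
#'
#' Per-gene scalar key/query/value weights (`w_k`, `w_q`, `w_v`), a scalar
#' mixing weight `gamma`, and the attention mask restricting which gene
#' pairs may attend.  For gene i with neighborhood N(i) = masked partners
#' of i plus i itself:
#' \deqn{e_{ij} = |w_k[i] x_i - w_q[j] x_j|,\quad
#'       \alpha_{ij} = \mathrm{softmin}_j(e_{ij}),\quad
#'       y_i = x_i + \gamma \sum_{j \in N(i)} \alpha_{ij} w_v[j] x_j.}
#' With `as_printed = TRUE` the aggregated value uses the *self* value
#' \eqn{w_v[i] x_i} for every neighbor; since the softmin weights sum to
#' one this collapses to \eqn{y_i = x_i + \gamma w_v[i] x_i}, a degenerate
#' per-gene rescaling kept only for auditability.
#'
#' @param mask an [attention_mask()].
#' @param w_k,w_q,w_v numeric vectors of length `n_genes`; default 1.
#' @param gamma scalar mixing weight; `gamma = 0` makes the layer the
#'   identity.
#' @param as_printed use the degenerate self-value aggregation.
#' @return An `attention_params` object.
#' @export
attention_params <- function(mask, w_k = NULL, w_q = NULL, w_v = NULL,
                             gamma = 1, as_printed = FALSE) {
  stopifnot(inherits(mask, "attention_mask"))
  d <- mask$n_genes
  one <- function(w) if (is.null(w)) rep(1, d) else {
    stopifnot(length(w) == d); as.numeric(w)
  }
  structure(list(w_k = one(w_k), w_q = one(w_q), w_v = one(w_v),
                 gamma = as.numeric(gamma), mask = mask,
                 as_printed = isTRUE(as_printed)),
            class = "attention_params")
}

# Precompute the pair index vectors (self pairs appended) and the sparse
# aggregation operators: S sums pair entries into their attending gene i,
# Sj into their partner gene j.
att_prepare <- function(mask) {
  d <- mask$n_genes
  ii <- c(mask$pairs[, 1], seq_len(d))
  jj <- c(mask$pairs[, 2], seq_len(d))
  P <- length(ii)
  list(ii = ii, jj = jj, d = d,
       S = Matrix::sparseMatrix(i = seq_len(P), j = ii, x = 1,
                                dims = c(P, d)),
       Sj = Matrix::sparseMatrix(i = seq_len(P), j = jj, x = 1,
                                 dims = c(P, d)))
}

att_forward <- function(X, par, prep) {
  if (par$as_printed) {
    agg <- sweep(X, 2, par$w_v, "*")
    return(list(Y = X + par$gamma * agg, agg = agg))
  }
  ii <- prep$ii; jj <- prep$jj
  Xi <- X[, ii, drop = FALSE]; Xj <- X[, jj, drop = FALSE]
  K <- sweep(Xi, 2, par$w_k[ii], "*")
  Q <- sweep(Xj, 2, par$w_q[jj], "*")
  E <- abs(K - Q)
  Wexp <- exp(-E)
  denom <- as.matrix(Wexp %*% prep$S)
  A <- Wexp / denom[, ii, drop = FALSE]
  Vals <- sweep(Xj, 2, par$w_v[jj], "*")
  agg <- as.matrix((A * Vals) %*% prep$S)
  list(Y = X + par$gamma * agg, agg = agg, A = A, Vals = Vals,
       sgn = sign(K - Q), Xi = Xi, Xj = Xj)
}

# Backward pass: dY is the upstream gradient (B x d); returns gradients
# w.r.t. X and all attention parameters (summed over the batch).
att_backward <- function(dY, X, par, prep, cache) {
  g <- par$gamma
  if (par$as_printed) {
    dX <- dY + g * sweep(dY, 2, par$w_v, "*")
    dwv <- g * colSums(dY * X)
    return(list(dX = dX, dwk = numeric(prep$d), dwq = numeric(prep$d),
                dwv = dwv, dgamma = sum(dY * cache$agg)))
  }
  ii <- prep$ii; jj <- prep$jj
  A <- cache$A; Vals <- cache$Vals; sgn <- cache$sgn
  Xi <- cache$Xi; Xj <- cache$Xj
  dgamma <- sum(dY * cache$agg)
  dAggP <- g * dY[, ii, drop = FALSE]      # upstream at each pair slot
  # value path
  dVals <- A * dAggP
  dwv <- as.vector(colSums(dVals * Xj) %*% prep$Sj)
  dX <- dY + as.matrix(sweep(dVals, 2, par$w_v[jj], "*") %*% prep$Sj)
  # softmin path: dL/dalpha = dAggP * Vals; softmax-with-negated-input rule
  Cp <- dAggP * Vals
  mdot <- as.matrix((A * Cp) %*% prep$S)
  dE <- -A * (Cp - mdot[, ii, drop = FALSE])
  dK <- dE * sgn
  dQ <- -dK
  dwk <- as.vector(colSums(dK * Xi) %*% prep$S)
  dwq <- as.vector(colSums(dQ * Xj) %*% prep$Sj)
  dX <- dX + as.matrix(sweep(dK, 2, par$w_k[ii], "*") %*% prep$S) +
             as.matrix(sweep(dQ, 2, par$w_q[jj], "*") %*% prep$Sj)
  list(dX = dX, dwk = dwk, dwq = dwq, dwv = dwv, dgamma = dgamma)
}

#' Apply sparse softmin/L1 attention to expression vectors
#'
#' @param x numeric vector of length `n_genes`, or a matrix with one
#'   sample per row.
#' @param params an [attention_params()] object.
#' @return Object of the same shape as `x` after the attention update
#'   `x + gamma * att(x)`.
#' @examples
#' m <- attention_mask(rbind(c(1, 2), c(2, 1)), 2, "coexp")
#' p <- attention_params(m, gamma = 1)
#' sparse_attention(c(1, 2), p)
#' @export
sparse_attention <- function(x, params) {
  stopifnot(inherits(params, "attention_params"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != params$mask$n_genes)
    stop("input length ", ncol(X), " does not match mask over ",
         params$mask$n_genes, " genes")
  prep <- att_prepare(params$mask)
  Y <- att_forward(X, params, prep)$Y
  if (vec) drop(Y) else Y
}

#' Softmin attention weights for one gene
#'
#' Diagnostic helper returning the attention distribution alpha over the
#' neighborhood N(i) (masked partners plus self) for a single input.
#'
#' @param x numeric vector of gene values.
#' @param params an [attention_params()].
#' @param gene index of the attending gene i.
#' @return Named numeric vector of weights summing to 1.
#' @export
attention_weights <- function(x, params, gene) {
  prep <- att_prepare(params$mask)
  sel <- prep$ii == gene
  js <- prep$jj[sel]
  e <- abs(params$w_k[gene] * x[gene] - params$w_q[js] * x[js])
  w <- exp(-e)
  stats::setNames(w / sum(w), js)
}
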