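# Minimal neural-network primitives: Glorot initialization, activations,
# softmax, and an Adam optimizer over flat named lists of parameter arrays.
# Gradients everywhere in this package are hand-derived reverse-mode and
# checked against finite differences in the test suite.

nn_init_mat <- function(nout, nin) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -s, s), nout, nin)
}

nn_init_vec <- function(n, scale = 0) {
  if (scale == 0) numeric(n) else stats::rnorm(n, 0, scale)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

drelu <- function(pre) (pre > 0) * 1

#' Softmax of a numeric vector
#'
#' Numerically stable; the returned probabilities are positive and sum to 1.
#' @param x numeric vector of logits
#' @return numeric vector of the same length
#' @export
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# row-wise softmax of a matrix
softmax_rows <- function(X) {
  Z <- exp(X - apply(X, 1, max))
  Z / rowSums(Z)
}

# backprop through softmax: given p = softmax(s) and dL/dp, return dL/ds
softmax_backward <- function(p, dp) {
  p * (dp - sum(dp * p))
}

softmax_rows_backward <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate a gradient contribution into a flat named list
acc_grad <- function(grads, nm, g) {
  grads[[nm]] <- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  grads
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# sum per-atom rows of E (rows = directed edges or bonds) into per-atom
# accumulators given a grouping index; returns an n x d matrix
rowsum_into <- function(E, group, n) {
  out <- matrix(0, n, ncol(E))
  if (nrow(E) == 0) return(out)
  rs <- rowsum(E, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}
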