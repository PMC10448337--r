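# Dense / layer-norm / GELU / softmax / 1-D convolution primitives with
# explicit backward passes.  All activations are (rows x hidden) matrices;
# a batch of B examples of length S is stored row-concatenated as a
# (B*S) x H matrix.  Everything is double precision and seeded through R's
# own RNG, so runs are bit-reproducible on one machine.

.dense_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2L, b, "+")
  list(y = y, x = x)
}

.dense_bwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

LN_EPS <- 1e-12

.ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, g, "*")
  y <- sweep(y, 2L, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

.ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  H <- ncol(xhat)
  dxhat <- sweep(dy, 2L, g, "*")
  # dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.gelu_fwd <- function(x) {
  list(y = x * stats::pnorm(x), x = x)
}

.gelu_bwd <- function(dy, cache) {
  x <- cache$x
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}

.softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# kernel-3, stride-1, same-padding 1-D convolution over the sequence axis.
# W is a list of three (H_in x H_out) matrices (previous, current, next
# position); edges see zeros, which coincides with masked padding.
.shift_down <- function(x) rbind(0, x[-nrow(x), , drop = FALSE])  # row t-1
.shift_up <- function(x) rbind(x[-1L, , drop = FALSE], 0)          # row t+1

.conv3_fwd <- function(x, Wp, Wc, Wn, b) {
  y <- .shift_down(x) %*% Wp + x %*% Wc + .shift_up(x) %*% Wn
  y <- sweep(y, 2L, b, "+")
  list(y = y, x = x)
}

.conv3_bwd <- function(dy, cache, Wp, Wc, Wn) {
  x <- cache$x
  dx <- .shift_up(dy) %*% t(Wp) + dy %*% t(Wc) + .shift_down(dy) %*% t(Wn)
  list(dx = dx,
       dWp = crossprod(.shift_down(x), dy),
       dWc = crossprod(x, dy),
       dWn = crossprod(.shift_up(x), dy),
       db = colSums(dy))
}

.dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  keep <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(keep) <- dim(x)
  list(y = x * keep, mask = keep)
}

.dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

.trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}
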