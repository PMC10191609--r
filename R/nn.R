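# Batched 1-D convolution / pooling primitives backed by compiled kernels.
#
# Feature maps are 3-d arrays [channels, positions, batch]. Convolutions use
# "same" padding (left pad floor((m-1)/2)); weights are [out_channels,
# in_channels * m] matrices with the input channel running fastest within
# each tap.

# Returns list(out = [Cout, L, B], cols = im2col matrix kept for backward).
conv1d_forward <- function(x, W, bias, m) {
  d <- dim(x)
  cols <- cpp_im2col(x, m)
  out <- W %*% cols + bias
  dim(out) <- c(nrow(W), d[2], d[3])
  list(out = out, cols = cols)
}

conv1d_backward <- function(dY, cols, W, m) {
  d <- dim(dY)
  dYm <- matrix(dY, d[1], d[2] * d[3])
  dcols <- crossprod(W, dYm)
  list(dW = tcrossprod(dYm, cols), db = rowSums(dYm),
       dX = cpp_col2im(dcols, nrow(cols) %/% m, d[2], d[3], m))
}

pool_avg <- function(x) cpp_pool_avg(x)

# val: C x B; arg: C x B of 1-based positions
pool_max <- function(x) cpp_pool_max(x)

unpool_max <- function(dval, arg, L) {
  C <- nrow(arg)
  B <- ncol(arg)
  out <- numeric(C * L * B)
  idx <- as.vector(seq_len(C) + (arg - 1L) * C) +
    rep((seq_len(B) - 1L) * C * L, each = C)
  out[idx] <- as.vector(dval)
  dim(out) <- c(C, L, B)
  out
}

# Broadcast a C x B matrix over positions to [C, L, B].
broadcast_cb <- function(w, L) {
  aperm(array(w, c(nrow(w), ncol(w), L)), c(1, 3, 2))
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}
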