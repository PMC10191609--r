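#' Adaptive attention kernel size
#'
#' The channel-attention stage mixes information across neighbouring kernels
#' with a 1-D convolution whose width adapts to the number of kernels:
#' `kappa = |log2(C)/gamma + b/gamma|_odd`, the nearest odd integer (ties at
#' an even value round up), never below 1. With the fixed hyperparameters
#' `gamma = 2`, `b = 1`: C = 2 gives 1, C = 16 gives 3, C = 256 gives 5.
#'
#' @param C Number of channels (kernels); powers of two recommended.
#' @param gamma,b Fixed scaling hyperparameters (defaults 2 and 1).
#' @return An odd integer kernel size.
#' @export
adaptive_kernel_size <- function(C, gamma = 2, b = 1) {
  if (!is.numeric(C) || length(C) != 1 || C < 1) abort("`C` must be >= 1.")
  if (C >= 2 && abs(log2(C) - round(log2(C))) > 1e-9) {
    warn("channel count is not a power of two; kernel size still defined.")
  }
  k <- log2(C) / gamma + b / gamma
  lower <- 2 * floor((k - 1) / 2) + 1 # largest odd <= k (k >= 1 here)
  if (k < 1) return(1L)
  upper <- lower + 2
  kappa <- if (k - lower < upper - k) lower else upper
  as.integer(max(1, kappa))
}

#' Motif-scanning convolution of a feature map
#'
#' Width-`m` "same"-padded 1-D convolution followed by ReLU; each output
#' channel is one learnable motif/epigenomic-pattern detector scanned along
#' the window.
#'
#' @param x Input feature map, `in_channels x L` matrix.
#' @param W Kernel weights, `out_channels x in_channels x m` array.
#' @param bias Length-`out_channels` bias.
#' @return An `out_channels x L` non-negative matrix.
#' @export
conv_encode <- function(x, W, bias = numeric(dim(W)[1])) {
  stopifnot(is.matrix(x), length(dim(W)) == 3, dim(W)[2] == nrow(x))
  m <- dim(W)[3]
  if (m > ncol(x)) abort("kernel wider than the sequence.")
  xf <- conv1d_forward(array(x, c(dim(x), 1)), matrix(W, nrow = dim(W)[1]),
                       bias, m)$out
  out <- xf[, , 1, drop = FALSE]
  dim(out) <- dim(out)[1:2]
  pmax(out, 0)
}

#' Channel descriptor combining average- and max-pooled statistics
#'
#' For each channel, global average (`avg`) and max (`mx`) pooling over
#' positions are blended as `alpha * avg + (avg + mx)/2 + beta * mx`, i.e.
#' `(alpha + 1/2) * avg + (beta + 1/2) * mx`. The learnable `alpha`,
#' `beta` in `[0, 1]` let the block lean toward diffuse or peaky evidence.
#'
#' @param x A `channels x L` feature map.
#' @param alpha,beta Mixing parameters in `[0, 1]`.
#' @return A length-`channels` numeric vector.
#' @export
channel_descriptor <- function(x, alpha = 0.5, beta = 0.5) {
  stopifnot(is.matrix(x), ncol(x) >= 1)
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    abort("`alpha` and `beta` must lie in [0, 1].")
  }
  avg <- rowMeans(x)
  mx <- apply(x, 1, max)
  (alpha + 0.5) * avg + (beta + 0.5) * mx
}

#' Channel attention map
#'
#' Convolves the channel descriptor across the channel axis with an odd
#' width-`kappa` kernel ("same" padding) and squashes through a sigmoid,
#' giving one weight in (0, 1) per channel.
#'
#' @param descriptor Length-`C` channel descriptor.
#' @param weights Length-`kappa` convolution kernel (`kappa` odd).
#' @param bias Scalar bias (default 0).
#' @return Length-`C` vector of attention weights in (0, 1).
#' @export
attention_map <- function(descriptor, weights, bias = 0) {
  kappa <- length(weights)
  if (kappa %% 2 == 0) abort("`weights` must have odd length.")
  xf <- conv1d_forward(array(descriptor, c(1, length(descriptor), 1)),
                       matrix(weights, 1), bias, kappa)
  sigmoid(as.vector(xf$out))
}

#' Recalibrate a feature map by per-channel attention weights
#'
#' @param x A `channels x L` feature map.
#' @param weights One weight per channel.
#' @return `x` with channel `c` scaled by `weights[c]`.
#' @export
recalibrate <- function(x, weights) {
  stopifnot(is.matrix(x))
  if (length(weights) != nrow(x)) {
    abort("need exactly one weight per channel.")
  }
  x * weights
}

# ---- batched stream module used inside the model ---------------------------
#
# All experts' blocks for one feature stream convolve the same projected
# latent, so their kernels are stacked into one weight matrix and run as a
# single im2col + gemm; pooling, the adaptive attention and recalibration
# then operate on the stacked [n_experts * C, L, B] map.

new_block_params <- function(C, Cin, m, kappa) {
  list(W = matrix(rnorm(C * Cin * m, sd = sqrt(2 / (Cin * m))), C, Cin * m),
       b = numeric(C),
       a0 = 0, b0 = 0, # alpha = beta = sigmoid(0) = 0.5
       wk = rnorm(kappa, sd = sqrt(1 / kappa)),
       bk = 0)
}

# blocks: list over experts of block parameter lists (one stream).
stream_forward <- function(blocks, x, m) {
  E <- length(blocks)
  C <- nrow(blocks[[1]]$W)
  B <- dim(x)[3]
  Wstack <- do.call(rbind, lapply(blocks, `[[`, "W"))
  bstack <- unlist(lapply(blocks, `[[`, "b"), use.names = FALSE)
  cf <- conv1d_forward(x, Wstack, bstack, m)
  pre <- cf$out # (E*C, L, B)
  xt <- pre
  xt[xt < 0] <- 0
  avg <- pool_avg(xt)
  mx <- pool_max(xt)
  alpha <- sigmoid(vapply(blocks, `[[`, 0, "a0"))
  beta <- sigmoid(vapply(blocks, `[[`, 0, "b0"))
  aexp <- rep(alpha, each = C)
  bexp <- rep(beta, each = C)
  desc <- (aexp + 0.5) * avg + (bexp + 0.5) * mx$val
  w <- matrix(0, E * C, B)
  kcols <- vector("list", E)
  for (e in seq_len(E)) {
    rows <- (e - 1L) * C + seq_len(C)
    kf <- conv1d_forward(array(desc[rows, , drop = FALSE], c(1, C, B)),
                         matrix(blocks[[e]]$wk, 1), blocks[[e]]$bk,
                         length(blocks[[e]]$wk))
    kcols[[e]] <- kf$cols
    w[rows, ] <- sigmoid(matrix(kf$out, C, B))
  }
  list(out = cpp_scale_channels(xt, w),
       cache = list(cols = cf$cols, pre = pre, xt = xt, avg = avg, mx = mx,
                    alpha = alpha, beta = beta, kcols = kcols, w = w,
                    m = m, C = C, E = E))
}

# G: gradient on the stacked recalibrated output. Returns per-expert grads
# (same field order as new_block_params) and the gradient on the latent.
stream_backward <- function(blocks, G, cache) {
  w <- cache$w
  C <- cache$C
  E <- cache$E
  B <- ncol(w)
  L <- dim(G)[2]
  dw_att <- cpp_sum_prod_positions(G, cache$xt)
  dxt <- cpp_scale_channels(G, w)
  de <- dw_att * w * (1 - w)
  ddesc <- matrix(0, E * C, B)
  grads <- vector("list", E)
  for (e in seq_len(E)) {
    rows <- (e - 1L) * C + seq_len(C)
    kb <- conv1d_backward(array(de[rows, , drop = FALSE], c(1, C, B)),
                          cache$kcols[[e]], matrix(blocks[[e]]$wk, 1),
                          length(blocks[[e]]$wk))
    ddesc[rows, ] <- matrix(kb$dX, C, B)
    grads[[e]] <- list(W = NULL, b = NULL, a0 = 0, b0 = 0,
                       wk = as.vector(kb$dW), bk = as.numeric(kb$db))
  }
  for (e in seq_len(E)) {
    rows <- (e - 1L) * C + seq_len(C)
    al <- cache$alpha[e]
    be <- cache$beta[e]
    grads[[e]]$a0 <- sum(ddesc[rows, ] * cache$avg[rows, ]) * al * (1 - al)
    grads[[e]]$b0 <- sum(ddesc[rows, ] * cache$mx$val[rows, ]) * be * (1 - be)
  }
  aexp <- rep(cache$alpha, each = C)
  bexp <- rep(cache$beta, each = C)
  davg <- ddesc * (aexp + 0.5)
  dmax <- ddesc * (bexp + 0.5)
  dxt <- dxt + broadcast_cb(davg / L, L) + unpool_max(dmax, cache$mx$arg, L)
  dpre <- dxt * (cache$pre > 0)
  Wstack <- do.call(rbind, lapply(blocks, `[[`, "W"))
  cb <- conv1d_backward(dpre, cache$cols, Wstack, cache$m)
  for (e in seq_len(E)) {
    rows <- (e - 1L) * C + seq_len(C)
    grads[[e]]$W <- cb$dW[rows, , drop = FALSE]
    grads[[e]]$b <- cb$db[rows]
    grads[[e]] <- grads[[e]][c("W", "b", "a0", "b0", "wk", "bk")]
  }
  list(grads = grads, dX = cb$dX)
}

# slice expert e's [C, L, B] map out of a stacked [E*C, L, B] map
stream_slice <- function(stacked, e, C) {
  stacked[(e - 1L) * C + seq_len(C), , , drop = FALSE]
}
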