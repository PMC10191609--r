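#' Model configuration
#'
#' Architecture hyperparameters of the gated multi-task model. One specific
#' expert module per cell type plus one shared expert module; each expert is
#' three channel-attention convolutional blocks (one per feature stream:
#' k-mer, shape, histone). A per-cell-type softmax gate mixes the six expert
#' feature maps; a small MLP head turns the mix into a binding probability.
#' All six maps share `n_kernels` and `motif_width`, a structural requirement
#' of the gated weighted sum.
#'
#' @param n_cells Number of cell types (prediction tasks).
#' @param kmer_order k-mer order `h` (1-4).
#' @param n_kernels Kernels per convolutional block (default 16).
#' @param motif_width Convolution width `m`, nominally the motif length of
#'   the TF (default 15).
#' @param gamma,b Attention kernel-size hyperparameters (fixed 2 and 1).
#' @param hidden_units Hidden width of each prediction head (default 64).
#' @param dropout Dropout rate in the head during training (default 0.2).
#' @param window_size Window width `L` (default 101).
#' @param head_input `"pool"` (default) feeds per-kernel global-max-pooled
#'   activations to the head, the position-invariant readout standard in
#'   motif-scanning CNNs; `"flatten"` feeds the full `n_kernels x L` map.
#' @param features Feature streams to use; excluded streams are zeroed at the
#'   input (encoder bypassed), the mechanism behind feature-combination
#'   ablations.
#' @param drop_shape_rows,drop_histone_rows Names of individual shape
#'   features / histone marks to zero, for leave-one-track-out ablations.
#' @return A `tfgate_config` object.
#' @export
tfgate_config <- function(n_cells, kmer_order = 2, n_kernels = 16,
                          motif_width = 15, gamma = 2, b = 1,
                          hidden_units = 64, dropout = 0.2,
                          window_size = 101,
                          head_input = c("pool", "flatten"),
                          features = c("kmer", "shape", "histone"),
                          drop_shape_rows = NULL, drop_histone_rows = NULL) {
  head_input <- match.arg(head_input)
  if (!n_cells >= 1) abort("`n_cells` must be >= 1.")
  if (!kmer_order %in% 1:4) abort("`kmer_order` must be in 1..4.")
  if (motif_width > window_size) abort("`motif_width` exceeds the window.")
  features <- match.arg(features, several.ok = TRUE)
  if (!length(features)) abort("at least one feature stream is required.")
  if (length(bad <- setdiff(drop_shape_rows, shape_features()))) {
    abort(sprintf("unknown shape feature(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(bad <- setdiff(drop_histone_rows, histone_marks()))) {
    abort(sprintf("unknown histone mark(s): %s", paste(bad, collapse = ", ")))
  }
  structure(list(n_cells = as.integer(n_cells),
                 kmer_order = as.integer(kmer_order),
                 n_kernels = as.integer(n_kernels),
                 motif_width = as.integer(motif_width),
                 gamma = gamma, b = b,
                 hidden_units = as.integer(hidden_units), dropout = dropout,
                 window_size = as.integer(window_size),
                 head_input = head_input, features = features,
                 drop_shape_rows = drop_shape_rows,
                 drop_histone_rows = drop_histone_rows),
            class = "tfgate_config")
}

stream_names <- function() c("kmer", "shape", "histone")

stream_rows <- function(config) {
  c(kmer = 4L^config$kmer_order, shape = 4L, histone = 8L)
}

#' Initialize model parameters
#'
#' @param config A [tfgate_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `tfgate_model` (parameter list + config); weights are He-scaled
#'   Gaussian, attention mixing parameters start at `alpha = beta = 0.5`.
#' @export
init_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "tfgate_config"))
  C <- config$n_kernels
  m <- config$motif_width
  L <- config$window_size
  kappa <- adaptive_kernel_size(C, config$gamma, config$b)
  rows <- stream_rows(config)
  with_local_seed(derive_seed(seed, "init"), {
    proj <- lapply(rows, function(r) {
      list(W = matrix(rnorm(4 * r, sd = sqrt(2 / r)), 4, r), b = numeric(4))
    })
    experts <- lapply(seq_len(config$n_cells + 1L), function(e) {
      st <- lapply(stream_names(), function(s) new_block_params(C, 4L, m, kappa))
      stats::setNames(st, stream_names())
    })
    gate_in <- sum(rows)
    gates <- lapply(seq_len(config$n_cells), function(k) {
      list(W = matrix(rnorm(6 * gate_in, sd = 0.01), 6, gate_in),
           b = numeric(6))
    })
    head_in <- if (config$head_input == "flatten") C * L else C
    heads <- lapply(seq_len(config$n_cells), function(k) {
      list(W1 = matrix(rnorm(config$hidden_units * head_in,
                             sd = sqrt(2 / head_in)),
                       config$hidden_units, head_in),
           b1 = numeric(config$hidden_units),
           W2 = matrix(rnorm(config$hidden_units,
                             sd = sqrt(1 / config$hidden_units)), 1),
           b2 = 0)
    })
    structure(list(params = list(proj = proj, experts = experts,
                                 gates = gates, heads = heads),
                   config = config, kappa = kappa),
              class = "tfgate_model")
  })
}

#' @export
print.tfgate_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<tfgate_model> %d cell type(s), %d+1 experts x 3 ",
                     "attention blocks (C=%d, m=%d, kappa=%d), h=%d\n",
                     "  parameters: %d\n"),
              cfg$n_cells, cfg$n_cells, cfg$n_kernels, cfg$motif_width,
              x$kappa, cfg$kmer_order, n_parameters(x)))
  invisible(x)
}

#' Total number of learnable parameters
#' @param model A `tfgate_model` or `tfgate_fit`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "tfgate_fit")) model <- model$model
  length(flatten_params(model$params))
}

# Zero excluded feature streams / individual tracks on encoded arrays.
apply_feature_mask <- function(feats, config) {
  for (s in stream_names()) {
    if (!s %in% config$features) feats[[s]][] <- 0
  }
  if (length(config$drop_shape_rows)) {
    feats$shape[match(config$drop_shape_rows, shape_features()), , ] <- 0
  }
  if (length(config$drop_histone_rows)) {
    feats$histone[match(config$drop_histone_rows, histone_marks()), , ] <- 0
  }
  feats
}

# feats: list(kmer [4^h,L,B], shape [4,L,B], histone [8,L,B]).
model_forward <- function(model, feats, train = FALSE, keep_cache = FALSE,
                          keep_maps = FALSE) {
  p <- model$params
  cfg <- model$config
  C <- cfg$n_kernels
  L <- cfg$window_size
  B <- dim(feats$kmer)[3]
  n_cells <- cfg$n_cells
  # width-1 projection of each stream to the common 4 x L latent space
  raw_m <- lapply(stream_names(), function(s) {
    matrix(feats[[s]], dim(feats[[s]])[1], L * B)
  })
  names(raw_m) <- stream_names()
  lat <- lapply(stream_names(), function(s) {
    z <- p$proj[[s]]$W %*% raw_m[[s]] + p$proj[[s]]$b
    dim(z) <- c(4, L, B)
    z
  })
  names(lat) <- stream_names()
  n_exp <- n_cells + 1L
  C <- cfg$n_kernels
  streams <- lapply(stats::setNames(stream_names(), stream_names()),
                    function(s) {
    stream_forward(lapply(p$experts, `[[`, s), lat[[s]], cfg$motif_width)
  })
  # per-expert recalibrated maps, sliced once from the stacked outputs
  maps <- lapply(streams, function(sf) {
    lapply(seq_len(n_exp), function(e) stream_slice(sf$out, e, C))
  })
  # gate input: global max pool over positions of the channel-stacked raw
  # feature matrices
  P <- do.call(rbind, lapply(stream_names(),
                             function(s) pool_max(feats[[s]])$val))
  probs <- matrix(0, n_cells, B)
  gates <- vector("list", n_cells)
  heads <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    logits <- p$gates[[k]]$W %*% P + p$gates[[k]]$b
    wg <- softmax_cols(logits) # 6 x B
    E <- list(maps$kmer[[k]], maps$shape[[k]], maps$histone[[k]],
              maps$kmer[[n_exp]], maps$shape[[n_exp]], maps$histone[[n_exp]])
    gk <- cpp_gate_mix(E, wg)
    v <- if (cfg$head_input == "flatten") matrix(gk, C * L, B)
         else pool_max(gk)$val
    hp <- p$heads[[k]]
    h1 <- hp$W1 %*% v + hp$b1
    r <- pmax(h1, 0)
    if (train && cfg$dropout > 0) {
      mask <- matrix(stats::runif(length(r)) >= cfg$dropout, nrow(r)) /
        (1 - cfg$dropout)
    } else {
      mask <- 1
    }
    rd <- r * mask
    z <- hp$W2 %*% rd + hp$b2
    probs[k, ] <- sigmoid(z)
    gates[[k]] <- list(wg = wg, E = E)
    if (keep_cache) {
      heads[[k]] <- list(v = v, h1 = h1, mask = mask, rd = rd,
                         gk_pool = if (cfg$head_input == "pool")
                           pool_max(gk) else NULL)
    }
  }
  out <- list(probs = probs,
              gate_weights = lapply(gates, `[[`, "wg"),
              attention = lapply(seq_len(n_exp), function(e) {
                lapply(streams, function(sf) {
                  sf$cache$w[(e - 1L) * C + seq_len(C), , drop = FALSE]
                })
              }))
  if (keep_maps) {
    # recalibrated maps (the experts' outputs) and the pre-attention ReLU
    # conv maps used for kernel-to-motif extraction
    out$feature_maps <- lapply(seq_len(n_exp), function(e) {
      lapply(maps, `[[`, e)
    })
    out$conv_maps <- lapply(seq_len(n_exp), function(e) {
      lapply(streams, function(sf) stream_slice(sf$cache$xt, e, C))
    })
  }
  if (keep_cache) {
    out$cache <- list(raw_m = raw_m, lat = lat, streams = streams, P = P,
                      gates = gates, heads = heads, B = B)
  }
  out
}

# dz: n_cells x B matrix of dLoss/d(pre-sigmoid output).
model_backward <- function(model, fwd, dz) {
  p <- model$params
  cfg <- model$config
  ca <- fwd$cache
  C <- cfg$n_kernels
  L <- cfg$window_size
  B <- ca$B
  n_cells <- cfg$n_cells
  n_exp <- n_cells + 1L
  g <- list(
    proj = lapply(p$proj, function(x) list(W = x$W * 0, b = x$b * 0)),
    experts = NULL,
    gates = lapply(p$gates, function(x) list(W = x$W * 0, b = x$b * 0)),
    heads = lapply(p$heads, function(x) {
      list(W1 = x$W1 * 0, b1 = x$b1 * 0, W2 = x$W2 * 0, b2 = 0)
    })
  )
  # gradient accumulators on the stacked recalibrated stream outputs
  Gstack <- lapply(stats::setNames(stream_names(), stream_names()),
                   function(s) array(0, c(n_exp * C, L, B)))
  for (k in seq_len(n_cells)) {
    hd <- ca$heads[[k]]
    hp <- p$heads[[k]]
    dzk <- matrix(dz[k, ], 1, B)
    g$heads[[k]]$W2 <- dzk %*% t(hd$rd)
    g$heads[[k]]$b2 <- sum(dzk)
    drd <- crossprod(hp$W2, dzk)
    dr <- drd * hd$mask
    dh1 <- dr * (hd$h1 > 0)
    g$heads[[k]]$W1 <- dh1 %*% t(hd$v)
    g$heads[[k]]$b1 <- rowSums(dh1)
    dv <- crossprod(hp$W1, dh1)
    dgk <- if (cfg$head_input == "flatten") array(dv, c(C, L, B))
           else unpool_max(dv, hd$gk_pool$arg, L)
    # gate-weighted sum backward
    wg <- ca$gates[[k]]$wg
    dwg <- cpp_gate_mix_backward_w(ca$gates[[k]]$E, dgk)
    for (j in 1:6) {
      e_idx <- if (j <= 3) k else n_exp
      s <- stream_names()[(j - 1L) %% 3L + 1L]
      # in-place accumulation: Gstack arrays are private to this call
      cpp_axpy_sample_rows(Gstack[[s]], dgk, wg[j, ], (e_idx - 1L) * C + 1L)
    }
    dlogits <- wg * (dwg - rep(colSums(wg * dwg), each = 6))
    g$gates[[k]]$W <- dlogits %*% t(ca$P)
    g$gates[[k]]$b <- rowSums(dlogits)
  }
  # stream modules backward, accumulating into the shared latents
  expert_grads <- lapply(seq_len(n_exp), function(e) list())
  dlat <- list()
  for (s in stream_names()) {
    sb <- stream_backward(lapply(p$experts, `[[`, s), Gstack[[s]],
                          ca$streams[[s]]$cache)
    for (e in seq_len(n_exp)) expert_grads[[e]][[s]] <- sb$grads[[e]]
    dlat[[s]] <- sb$dX
  }
  g$experts <- expert_grads
  for (s in stream_names()) {
    dl <- matrix(dlat[[s]], 4, L * B)
    g$proj[[s]]$W <- tcrossprod(dl, ca$raw_m[[s]])
    g$proj[[s]]$b <- rowSums(dl)
  }
  g
}

# ---- parameter <-> flat vector ---------------------------------------------

flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- flat[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  rebuild(skeleton)
}
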