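#' Extract motifs from high-attention convolutional kernels
#'
#' Ranks the kernels of a feature stream by their dataset-mean channel
#' attention weight, then, for each of the `top_k` best, collects the raw
#' `m`-bp subsequences under each sample's maximal conv activation whenever
#' that activation exceeds half the kernel's global maximum, and summarizes
#' them as a position weight matrix (position frequency matrix with
#' pseudocount 1, columns normalized). Kernels that never activate above the
#' threshold are skipped with a warning.
#'
#' @param fit A `tfgate_fit`.
#' @param dataset A `tfgate_dataset`; typically its positive windows
#'   (at least ~100 recommended).
#' @param top_k Number of kernels to report (default 1).
#' @param stream Feature stream whose blocks are scanned (default `"kmer"`).
#' @param rank_by `"mean"` (dataset-mean attention, default) or `"max"`
#'   (per-sample maximum).
#' @return A list of `tfgate_pwm` objects (4 x m column-stochastic matrices)
#'   with a `source` attribute: expert, stream, kernel index, attention
#'   score, number of contributing sites.
#' @export
extract_motifs <- function(fit, dataset, top_k = 1, stream = "kmer",
                           rank_by = c("mean", "max")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(fit, "tfgate_fit"))
  stream <- match.arg(stream, stream_names())
  model <- fit$model
  cfg <- model$config
  m <- cfg$motif_width
  padl <- (m - 1L) %/% 2L
  L <- cfg$window_size
  enc <- encode_dataset(dataset, fit$shape_table, cfg$kmer_order)
  enc[stream_names()] <- apply_feature_mask(enc[stream_names()], cfg)
  n <- nrow(dataset)
  n_exp <- cfg$n_cells + 1L
  C <- cfg$n_kernels
  att_stat <- matrix(if (rank_by == "mean") 0 else -Inf, n_exp, C)
  mx_val <- array(0, c(n_exp, C, n)) # per-sample max conv activation
  mx_pos <- array(0L, c(n_exp, C, n))
  batches <- split(seq_len(n), ceiling(seq_len(n) / 256L))
  for (bi in batches) {
    fw <- model_forward(model, slice_feats(enc, bi), keep_maps = TRUE)
    for (e in seq_len(n_exp)) {
      w <- fw$attention[[e]][[stream]] # C x B
      att_stat[e, ] <- if (rank_by == "mean") att_stat[e, ] + rowSums(w)
        else pmax(att_stat[e, ], apply(w, 1, max))
      xt <- fw$conv_maps[[e]][[stream]]
      pm <- pool_max(xt)
      mx_val[e, , bi] <- pm$val
      mx_pos[e, , bi] <- matrix((pm$arg - 1L) %% L + 1L, C, length(bi))
    }
  }
  score <- if (rank_by == "mean") att_stat / n else att_stat
  ord <- order(score, decreasing = TRUE)
  out <- list()
  for (r in ord[seq_len(min(top_k, length(ord)))] ) {
    e <- (r - 1L) %% n_exp + 1L
    ch <- (r - 1L) %/% n_exp + 1L
    vals <- mx_val[e, ch, ]
    thr <- max(vals) / 2
    hit <- which(vals > thr & vals > 0)
    counts <- matrix(1, 4, m, dimnames = list(dna_bases(), NULL)) # pseudocount
    n_sites <- 0L
    for (i in hit) {
      t0 <- mx_pos[e, ch, i] - padl
      if (t0 < 1L || t0 + m - 1L > L) next
      sub <- substring(dataset$sequence[i], t0, t0 + m - 1L)
      b <- match(strsplit(sub, "")[[1]], dna_bases())
      if (anyNA(b)) next
      counts[cbind(b, seq_len(m))] <- counts[cbind(b, seq_len(m))] + 1
      n_sites <- n_sites + 1L
    }
    if (n_sites == 0L) {
      warn(sprintf("kernel %d of expert %d never activated above threshold; skipped.",
                   ch, e))
      next
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    attr(pwm, "source") <- list(
      expert = if (e == n_exp) "shared" else fit$cell_types[e],
      stream = stream, kernel = ch, attention = score[e, ch],
      n_sites = n_sites)
    class(pwm) <- c("tfgate_pwm", class(pwm))
    out[[length(out) + 1L]] <- pwm
  }
  out
}

#' @export
print.tfgate_pwm <- function(x, ...) {
  s <- attr(x, "source")
  cat(sprintf("<tfgate_pwm> %d bp", ncol(x)))
  if (!is.null(s)) {
    cat(sprintf(" | expert %s / %s kernel %d, attention %.3f, %d sites",
                s$expert, s$stream, s$kernel, s$attention, s$n_sites))
  }
  cat(sprintf("\n  consensus %s, %.1f bits\n", pwm_consensus(x),
              sum(pwm_information(x))))
  invisible(x)
}

#' Per-column information content of a PWM
#' @param pwm A 4-row column-stochastic matrix.
#' @return Numeric vector of bits per column (0 to 2).
#' @export
pwm_information <- function(pwm) {
  p <- pmax(unclass(pwm), 0)
  apply(p, 2, function(col) {
    nz <- col[col > 0]
    2 + sum(nz * log2(nz))
  })
}

#' Best column-wise Pearson correlation between two PWMs
#'
#' Mean per-column Pearson correlation of base probabilities, maximized over
#' relative offsets (learned kernels often carry a motif at a shift). With
#' `allow_shift = FALSE` the PWMs are compared at fixed alignment.
#'
#' @param pwm_a,pwm_b 4-row column-stochastic matrices.
#' @param allow_shift Search over offsets (default TRUE).
#' @param min_overlap Minimum overlapping columns when shifting (default 8).
#' @return The best mean column-wise correlation.
#' @export
pwm_similarity <- function(pwm_a, pwm_b, allow_shift = TRUE, min_overlap = 8) {
  a <- unclass(pwm_a); b <- unclass(pwm_b)
  col_cor <- function(x, y) {
    vapply(seq_len(ncol(x)), function(i) {
      if (stats::sd(x[, i]) == 0 || stats::sd(y[, i]) == 0) return(0)
      stats::cor(x[, i], y[, i])
    }, numeric(1))
  }
  shifts <- if (allow_shift) {
    (-(ncol(a) - min_overlap)):(ncol(b) - min_overlap)
  } else 0L
  best <- -1
  for (s in shifts) {
    ia <- max(1, 1 - s):min(ncol(a), ncol(b) - s)
    ib <- ia + s
    if (length(ia) < min(min_overlap, ncol(a), ncol(b))) next
    best <- max(best, mean(col_cor(a[, ia, drop = FALSE],
                                   b[, ib, drop = FALSE])))
  }
  best
}

#' Gate utilization per cell type
#'
#' Mean softmax gate weight each cell type's gate assigns to the six
#' sub-experts (specific k-mer/shape/histone, then shared k-mer/shape/
#' histone), averaged over the dataset. Each cell type's six utilizations
#' sum to 1.
#'
#' @param fit A `tfgate_fit`.
#' @param dataset A `tfgate_dataset`.
#' @param split Split to average over (default `"all"`).
#' @return A `tfgate_gate_utilization` tibble: `cell_type`, `sub_expert`,
#'   `utilization`.
#' @export
gate_utilization <- function(fit, dataset, split = "all") {
  stopifnot(inherits(fit, "tfgate_fit"))
  model <- fit$model
  idx <- eval_indices(dataset, split)
  enc <- encode_dataset(dataset, fit$shape_table, model$config$kmer_order)
  enc[stream_names()] <- apply_feature_mask(enc[stream_names()],
                                            model$config)
  n_cells <- model$config$n_cells
  acc <- matrix(0, n_cells, 6)
  batches <- split(seq_along(idx), ceiling(seq_along(idx) / 512L))
  for (s in batches) {
    fw <- model_forward(model, slice_feats(enc, idx[s]))
    for (k in seq_len(n_cells)) acc[k, ] <- acc[k, ] +
        rowSums(fw$gate_weights[[k]])
  }
  acc <- acc / length(idx)
  sub <- c("specific_kmer", "specific_shape", "specific_histone",
           "shared_kmer", "shared_shape", "shared_histone")
  out <- tibble::tibble(
    cell_type = rep(fit$cell_types, each = 6),
    sub_expert = factor(rep(sub, n_cells), levels = sub),
    utilization = as.vector(t(acc)))
  class(out) <- c("tfgate_gate_utilization", class(out))
  out
}

# ---- MEME minimal motif format ---------------------------------------------

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms A `tfgate_pwm` or list of them.
#' @param path Output path.
#' @param names Motif names (defaults to `motif_1`, ...).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, names = NULL) {
  if (inherits(pwms, "tfgate_pwm") || (is.matrix(pwms) && nrow(pwms) == 4)) {
    pwms <- list(pwms)
  }
  names <- names %||% sprintf("motif_%d", seq_along(pwms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_along(pwms)) {
    p <- unclass(pwms[[i]])
    if (any(abs(colSums(p) - 1) > 1e-6) || any(p < 0)) {
      abort("malformed PWM: columns must be probabilities summing to 1.")
    }
    src <- attr(pwms[[i]], "source")
    nsites <- if (!is.null(src)) src$n_sites else 20L
    writeLines(sprintf("MOTIF %s", names[i]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(p), nsites), con)
    writeLines(apply(p, 2, function(col) {
      paste(sprintf("%.6f", col), collapse = "  ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal motif file
#' @param path A MEME-format file.
#' @return A named list of `tfgate_pwm` matrices.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    nm <- sub("^MOTIF +", "", lines[s])
    nm <- strsplit(nm, " +")[[1]][1]
    hdr <- s + grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    p <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), " +")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    pwm <- t(p)
    rownames(pwm) <- dna_bases()
    class(pwm) <- c("tfgate_pwm", class(pwm))
    out[[nm]] <- pwm
  }
  out
}
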