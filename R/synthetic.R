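#' Specification for a synthetic multi-cell-type TFBS dataset
#'
#' Describes a planted-motif benchmark with the statistical structure the
#' model assumes: multi-cell-type binary labels driven by cell-type-shared
#' and cell-type-specific motifs, histone coverage with position-dependent
#' signal shapes, and a deterministic pentamer shape table. Defaults give two
#' cell types sharing one strong 15-bp motif (about 17 bits of information),
#' equal numbers of bound and unbound windows, and the qualitative histone
#' geometry seen around real binding sites: acetylation/H3K4 methylation marks
#' flanking the site bimodally, H3K36me3/H3K27me3 depleted at the core.
#'
#' @param n_cells Number of cell types.
#' @param n_shared_pos Positives carrying a shared motif, labelled 1 in every
#'   cell type.
#' @param n_specific_pos Per cell type, positives carrying that cell's own
#'   motif, labelled 1 only there.
#' @param n_neg Background-only windows, labelled 0 everywhere.
#' @param L Window width in bp.
#' @param shared_motifs List of PWMs (4 x width column-stochastic matrices)
#'   available to every cell type.
#' @param specific_motifs List (length `n_cells`) of PWM lists, one per cell
#'   type; required if `n_specific_pos > 0`.
#' @param insertion_prob Probability that a positive window actually receives
#'   a motif instance (default 1).
#' @param background Base composition of background sequence (sums to 1).
#' @param histone_profiles Named list per mark:
#'   `list(shape = "flat"|"bimodal_flank"|"core_depleted", amplitude, noise_sd,
#'   baseline)`. See [default_histone_profiles()].
#' @param label_rule `"motif"`: histone signal is drawn identically for
#'   positives and negatives (uninformative). `"motif_histone"`: profile
#'   amplitude is applied only to positive windows, making the marked
#'   coverage predictive of the label.
#' @param seed Integer seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_cells = 2, n_shared_pos = 500,
                           n_specific_pos = 0, n_neg = 500, L = 101,
                           shared_motifs = list(planted_pwm()),
                           specific_motifs = NULL, insertion_prob = 1,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           histone_profiles = default_histone_profiles(),
                           label_rule = c("motif", "motif_histone"),
                           seed = 1) {
  label_rule <- match.arg(label_rule)
  stopifnot(n_cells >= 1, L >= 5, insertion_prob >= 0, insertion_prob <= 1)
  total <- n_shared_pos + n_cells * n_specific_pos + n_neg
  if (total < 10) abort("need at least 10 samples in total.")
  check_pwm_list <- function(pwms, what) {
    for (p in pwms) {
      if (!is.matrix(p) || nrow(p) != 4 ||
          any(abs(colSums(p) - 1) > 1e-6) || any(p < 0)) {
        abort(sprintf("%s must be 4-row column-stochastic matrices.", what))
      }
      if (ncol(p) > L) abort("motif wider than the window.")
    }
  }
  check_pwm_list(shared_motifs, "shared_motifs")
  if (n_specific_pos > 0) {
    if (is.null(specific_motifs) || length(specific_motifs) != n_cells) {
      abort("`specific_motifs` must list one PWM set per cell type.")
    }
    for (s in specific_motifs) check_pwm_list(s, "specific_motifs")
  }
  if (abs(sum(background) - 1) > 1e-8 || any(background < 0)) {
    abort("`background` must be a probability vector over A,C,G,T.")
  }
  miss <- setdiff(histone_marks(), names(histone_profiles))
  if (length(miss)) abort(sprintf("histone profile(s) missing: %s",
                                  paste(miss, collapse = ", ")))
  for (p in histone_profiles) {
    if (!p$shape %in% c("flat", "bimodal_flank", "core_depleted")) {
      abort("histone profile shape must be flat, bimodal_flank or core_depleted.")
    }
    if (p$amplitude < 0 || p$noise_sd < 0 || p$baseline < 0) {
      abort("histone profile amplitude/noise_sd/baseline must be >= 0.")
    }
  }
  structure(list(n_cells = n_cells, n_shared_pos = n_shared_pos,
                 n_specific_pos = n_specific_pos, n_neg = n_neg, L = L,
                 shared_motifs = shared_motifs,
                 specific_motifs = specific_motifs,
                 insertion_prob = insertion_prob, background = background,
                 histone_profiles = histone_profiles,
                 label_rule = label_rule, seed = seed),
            class = "synthetic_spec")
}

#' Default qualitative histone signal profiles
#'
#' Bimodal flanking signal for H3K27ac, H3K4me2, H3K9ac, H3K4me1, H3K4me3 and
#' H3K9me3; core-depleted signal for H3K36me3 and H3K27me3; shared baseline 1,
#' amplitude 2, Gaussian noise sd 0.5 truncated at 0.
#'
#' @return A named list of profile descriptions, one per mark.
#' @export
default_histone_profiles <- function() {
  bimodal <- c("H3K27ac", "H3K4me2", "H3K9ac", "H3K4me1", "H3K4me3", "H3K9me3")
  out <- lapply(histone_marks(), function(mk) {
    list(shape = if (mk %in% bimodal) "bimodal_flank" else "core_depleted",
         amplitude = 2, noise_sd = 0.5, baseline = 1)
  })
  stats::setNames(out, histone_marks())
}

#' A strong planted position weight matrix
#'
#' Each column puts probability `dominant` on the consensus base and splits
#' the rest uniformly; at the default `dominant = 0.85` a 15-bp motif carries
#' about 17 bits of information.
#'
#' @param consensus Consensus string (default a fixed 15-mer).
#' @param dominant Probability of the consensus base per column.
#' @return A `4 x nchar(consensus)` column-stochastic matrix.
#' @export
planted_pwm <- function(consensus = "TCACGTGACTGATCG", dominant = 0.85) {
  b <- match(strsplit(toupper(consensus), "")[[1]], dna_bases())
  if (anyNA(b)) abort("consensus must be over {A,C,G,T}.")
  w <- length(b)
  p <- matrix((1 - dominant) / 3, nrow = 4, ncol = w,
              dimnames = list(dna_bases(), NULL))
  p[cbind(b, seq_len(w))] <- dominant
  p
}

#' @rdname planted_pwm
#' @export
orthogonal_pwm <- function(dominant = 0.85) {
  planted_pwm("GATTACAGGCCATAA", dominant)
}

pwm_consensus <- function(pwm) {
  paste(dna_bases()[apply(pwm, 2, which.max)], collapse = "")
}

sample_background <- function(n, L, background) {
  m <- matrix(sample(dna_bases(), n * L, replace = TRUE, prob = background),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

sample_from_pwm <- function(pwm) {
  paste(apply(pwm, 2, function(p) sample(dna_bases(), 1, prob = p)),
        collapse = "")
}

profile_curve <- function(profile, n_pos, L) {
  x <- seq_len(n_pos) - 1
  center <- 50 + (L - 1) / 2 # window centre within the flanked coverage
  base <- switch(profile$shape,
    flat = rep(1, n_pos),
    bimodal_flank = exp(-((x - center + 30)^2) / (2 * 15^2)) +
      exp(-((x - center - 30)^2) / (2 * 15^2)),
    core_depleted = 1 - exp(-((x - center)^2) / (2 * 25^2))
  )
  profile$baseline + profile$amplitude * base
}

#' Generate a synthetic multi-cell-type TFBS dataset
#'
#' Positive windows receive one motif instance (sampled from the assigned
#' PWM) at a uniform random position with probability `insertion_prob`;
#' negatives are background-only. Histone coverage is drawn per mark from its
#' profile with truncated Gaussian noise. The returned dataset carries a
#' ground-truth manifest (attribute `"manifest"`) recording, for every
#' sample, its construction type, motif identity and insertion position,
#' from which every label can be recomputed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `tfgate_dataset` with `manifest` and `spec` attributes.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cell_types <- paste0("cell", seq_len(spec$n_cells))
  plan <- tibble::tibble(
    type = c(rep("shared", spec$n_shared_pos),
             rep(cell_types, each = spec$n_specific_pos),
             rep("negative", spec$n_neg)),
  )
  n <- nrow(plan)
  L <- spec$L
  with_local_seed(derive_seed(spec$seed, "simulate"), {
    sequences <- sample_background(n, L, spec$background)
    motif_id <- rep(NA_character_, n)
    motif_pos <- rep(NA_integer_, n)
    for (i in which(plan$type != "negative")) {
      if (stats::runif(1) > spec$insertion_prob) next
      pwms <- if (plan$type[i] == "shared") spec$shared_motifs
              else spec$specific_motifs[[match(plan$type[i], cell_types)]]
      j <- sample.int(length(pwms), 1)
      pwm <- pwms[[j]]
      w <- ncol(pwm)
      pos <- sample.int(L - w + 1L, 1)
      ins <- sample_from_pwm(pwm)
      substr(sequences[i], pos, pos + w - 1L) <- ins
      motif_id[i] <- paste0(if (plan$type[i] == "shared") "shared" else
        plan$type[i], "_m", j)
      motif_pos[i] <- pos
    }
    labels <- lapply(seq_len(n), function(i) {
      l <- integer(spec$n_cells)
      if (plan$type[i] == "shared") l[] <- 1L
      else if (plan$type[i] != "negative") l[match(plan$type[i], cell_types)] <- 1L
      stats::setNames(l, cell_types)
    })
    is_pos <- plan$type != "negative"
    n_cov <- L + 100L
    histone <- lapply(seq_len(n), function(i) {
      m <- matrix(0, 8, n_cov, dimnames = list(histone_marks(), NULL))
      for (mk in histone_marks()) {
        pr <- spec$histone_profiles[[mk]]
        amp_on <- spec$label_rule == "motif" || is_pos[i]
        pr_i <- pr
        if (!amp_on) pr_i$amplitude <- 0
        m[mk, ] <- pmax(profile_curve(pr_i, n_cov, L) +
                          stats::rnorm(n_cov, 0, pr$noise_sd), 0)
      }
      m
    })
    samples <- tibble::tibble(
      id = sprintf("syn%05d", seq_len(n)), chrom = "syn",
      start = (seq_len(n) - 1L) * (L + 100L) + 50L,
      end = (seq_len(n) - 1L) * (L + 100L) + 50L + L,
      sequence = sequences, labels = labels, histone = histone,
      is_positive = is_pos)
    ds <- new_tfgate_dataset(samples, cell_types, L)
    attr(ds, "manifest") <- tibble::tibble(
      id = samples$id, type = plan$type, motif = motif_id,
      insert_pos = motif_pos)
    attr(ds, "spec") <- spec
    ds
  })
}

#' Deterministic synthetic pentamer shape table
#'
#' A stand-in for measured pentamer shape tables: pseudo-random values inside
#' plausible physical ranges (MGW 2.8-6.2 Angstrom, ProT -17-0 deg, HelT
#' 30-40 deg, Roll -8-10 deg) for all 1024 pentamers, with MGW and ProT made
#' reverse-complement symmetric (those features describe the duplex, not a
#' strand). Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @return A `shape_table`.
#' @export
make_shape_table <- function(seed = 1) {
  pent <- all_kmers(5)
  ranges <- list(MGW = c(2.8, 6.2), ProT = c(-17, 0),
                 HelT = c(30, 40), Roll = c(-8, 10))
  with_local_seed(derive_seed(seed, "shape_table"), {
    vals <- sapply(names(ranges), function(f) {
      stats::runif(length(pent), ranges[[f]][1], ranges[[f]][2])
    })
    rownames(vals) <- pent
    rc <- revcomp(pent)
    canonical <- pmin(pent, rc)
    for (f in c("MGW", "ProT")) vals[, f] <- vals[canonical, f]
    as_shape_table(vals, pent)
  })
}

#' Cross-cell-type site pairs with controlled sequence identity
#'
#' Emits a two-cell-type dataset in which each positive of cell 1 has a
#' counterpart positive in cell 2 agreeing at exactly `round(identity * L)`
#' positions (every non-identical position is substituted with a different
#' base). Exercises the >75%-identity shared/specific boundary.
#'
#' @param n_pairs Number of site pairs.
#' @param identity Target identity fraction in `[0, 1]`.
#' @param L Window width.
#' @param seed Integer seed.
#' @return A `tfgate_dataset` with `2 * n_pairs` positive windows.
#' @export
generate_shared_specific_pair <- function(n_pairs = 20, identity = 1,
                                          L = 101, seed = 1) {
  stopifnot(identity >= 0, identity <= 1, n_pairs >= 1)
  cell_types <- c("cell1", "cell2")
  n_keep <- round(identity * L)
  with_local_seed(derive_seed(seed, "pair"), {
    seq_a <- sample_background(n_pairs, L, c(A = .25, C = .25, G = .25, T = .25))
    seq_b <- vapply(seq_a, function(s) {
      ch <- strsplit(s, "")[[1]]
      flip <- sample.int(L, L - n_keep)
      for (i in flip) ch[i] <- sample(setdiff(dna_bases(), ch[i]), 1)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    n <- 2L * n_pairs
    samples <- tibble::tibble(
      id = sprintf("pair%04d_%s", rep(seq_len(n_pairs), 2),
                   rep(c("a", "b"), each = n_pairs)),
      chrom = "syn",
      start = (seq_len(n) - 1L) * (L + 100L) + 50L,
      end = (seq_len(n) - 1L) * (L + 100L) + 50L + L,
      sequence = c(seq_a, seq_b),
      labels = c(rep(list(c(cell1 = 1L, cell2 = 0L)), n_pairs),
                 rep(list(c(cell1 = 0L, cell2 = 1L)), n_pairs)),
      histone = rep(list(matrix(0, 8, L + 100L,
                                dimnames = list(histone_marks(), NULL))), n),
      is_positive = TRUE)
    new_tfgate_dataset(samples, cell_types, L)
  })
}
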