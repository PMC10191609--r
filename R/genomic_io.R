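#' Centre a peak on a fixed-width window
#'
#' ChIP-seq binding events of arbitrary width are reduced to fixed windows
#' centred on the peak midpoint: the window spans
#' `[centre - floor(L/2), centre - floor(L/2) + L)` with
#' `centre = floor((start + end) / 2)`. Coordinates are 0-based half-open.
#'
#' @param start,end Peak interval (0-based half-open), vectorized.
#' @param L Window width (default 101).
#' @return A tibble with columns `start`, `end`, `center` (`end - start == L`).
#' @export
extract_window <- function(start, end, L = 101) {
  if (any(end <= start)) abort("peak intervals must be non-empty.")
  center <- (start + end) %/% 2
  ws <- center - L %/% 2
  tibble::tibble(start = ws, end = ws + L, center = center)
}

#' Read a BED file of ChIP-seq peaks
#' @param path BED file (3+ columns).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
}

#' Read a genome (or any sequence set) from FASTA
#' @param path FASTA file.
#' @return A named character vector of sequences, one per record.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a per-base coverage track
#'
#' Accepts bedGraph (4-column text: chrom, start, end, value) or bigWig.
#'
#' @param path Track file; format guessed from the extension.
#' @return A named list of per-chromosome numeric vectors (per-base values).
#' @export
read_coverage_track <- function(path) {
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "BigWig"
         else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  cov <- GenomicRanges::coverage(gr, weight = "score")
  lapply(as.list(cov), as.numeric)
}

# Coverage for [start - flank, end + flank) on one chromosome; positions
# outside the recorded track are 0.
slice_coverage <- function(track_chrom, start, end, flank = 50) {
  lo <- start - flank
  hi <- end + flank
  out <- numeric(hi - lo)
  if (is.null(track_chrom)) return(out)
  n <- length(track_chrom)
  src <- max(lo, 0L):min(hi - 1L, n - 1L)
  if (length(src) && src[1] <= src[length(src)]) {
    out[src - lo + 1L] <- track_chrom[src + 1L]
  }
  out
}

#' Assemble a multi-cell-type TFBS dataset from peak files
#'
#' Builds one multi-label sample per binding site: windows are extracted from
#' the union of all cell types' peaks, near-duplicate windows (>50% reciprocal
#' overlap) are merged, and each window is labelled 1 in every cell type whose
#' peaks it overlaps. Negative (unbound) windows are added either by
#' dinucleotide-shuffling the positive sequences (preserving composition and
#' coordinates, hence chromatin context) or by sampling random genomic windows
#' that overlap no peak.
#'
#' @param peaks Named list (one per cell type) of peak tibbles
#'   (`chrom`, `start`, `end`) as returned by [read_peaks()].
#' @param genome Named character vector of chromosome sequences
#'   ([read_genome()]).
#' @param histone_tracks Named list over the eight marks of coverage tracks
#'   ([read_coverage_track()]), or `NULL` for all-zero coverage.
#' @param L Window width (default 101).
#' @param negatives_mode `"dinucleotide_shuffle"` or `"random_genomic"`.
#' @param negative_ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return A `tfgate_dataset`.
#' @export
build_multitask_dataset <- function(peaks, genome, histone_tracks = NULL,
                                    L = 101,
                                    negatives_mode = c("dinucleotide_shuffle",
                                                       "random_genomic"),
                                    negative_ratio = 1, seed = 1) {
  negatives_mode <- match.arg(negatives_mode)
  if (!is.list(peaks) || is.null(names(peaks)) || length(peaks) < 1) {
    abort("`peaks` must be a named list with one peak table per cell type.")
  }
  if (any(vapply(peaks, nrow, 0L) == 0)) {
    abort("every cell type must have at least one peak.")
  }
  cell_types <- names(peaks)
  all_peaks <- dplyr::bind_rows(peaks, .id = "cell_type")
  win <- dplyr::bind_cols(all_peaks["chrom"],
                          extract_window(all_peaks$start, all_peaks$end, L))
  win <- dplyr::arrange(dplyr::distinct(win, .data$chrom, .data$start,
                                        .data$end), .data$chrom, .data$start)
  # merge windows with >50% reciprocal overlap (equal width L: centre distance
  # <= floor(L/2)); greedy left-to-right, keeping the leftmost of each cluster
  keep <- logical(nrow(win))
  last_chrom <- ""
  last_start <- -Inf
  for (i in seq_len(nrow(win))) {
    if (win$chrom[i] != last_chrom || win$start[i] - last_start > L %/% 2) {
      keep[i] <- TRUE
      last_chrom <- win$chrom[i]
      last_start <- win$start[i]
    }
  }
  win <- win[keep, ]
  # drop windows past chromosome bounds
  clen <- nchar(genome)[win$chrom]
  oob <- is.na(clen) | win$start < 0 | win$end > clen
  if (any(oob)) {
    warn(sprintf("dropping %d window(s) outside chromosome bounds.", sum(oob)))
    win <- win[!oob, ]
  }
  if (nrow(win) == 0) abort("no usable windows remain.")
  # per-cell labels by any overlap with that cell's peaks
  win_gr <- GenomicRanges::GRanges(win$chrom,
                                   IRanges::IRanges(win$start + 1L, win$end))
  labels <- matrix(0L, nrow(win), length(cell_types),
                   dimnames = list(NULL, cell_types))
  for (ct in cell_types) {
    p <- peaks[[ct]]
    p_gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
    hit <- GenomicRanges::countOverlaps(win_gr, p_gr) > 0
    labels[hit, ct] <- 1L
  }
  sequences <- unname(toupper(substring(genome[win$chrom], win$start + 1L,
                                        win$end)))
  get_hist <- function(chrom, start, end) {
    m <- matrix(0, nrow = 8, ncol = L + 100,
                dimnames = list(histone_marks(), NULL))
    if (!is.null(histone_tracks)) {
      miss <- setdiff(histone_marks(), names(histone_tracks))
      if (length(miss)) abort(sprintf("missing histone track(s): %s",
                                      paste(miss, collapse = ", ")))
      for (mk in histone_marks()) {
        m[mk, ] <- slice_coverage(histone_tracks[[mk]][[chrom]], start, end)
      }
    }
    m
  }
  pos <- tibble::tibble(
    id = sprintf("pos%05d", seq_len(nrow(win))),
    chrom = win$chrom, start = win$start, end = win$end,
    sequence = sequences,
    labels = lapply(seq_len(nrow(win)),
                    function(i) stats::setNames(labels[i, ], cell_types)),
    histone = purrr::pmap(list(win$chrom, win$start, win$end), get_hist),
    is_positive = TRUE
  )
  n_neg <- round(negative_ratio * nrow(pos))
  neg <- with_local_seed(derive_seed(seed, "negatives"), {
    if (negatives_mode == "dinucleotide_shuffle") {
      src <- sample(seq_len(nrow(pos)), n_neg, replace = n_neg > nrow(pos))
      tibble::tibble(
        id = sprintf("neg%05d", seq_len(n_neg)),
        chrom = pos$chrom[src], start = pos$start[src], end = pos$end[src],
        sequence = vapply(pos$sequence[src], dinucleotide_shuffle,
                          character(1), USE.NAMES = FALSE),
        labels = rep(list(stats::setNames(integer(length(cell_types)),
                                          cell_types)), n_neg),
        histone = pos$histone[src],
        is_positive = FALSE
      )
    } else {
      sample_background_windows(n_neg, genome, win_gr, get_hist, cell_types, L)
    }
  })
  new_tfgate_dataset(dplyr::bind_rows(pos, neg), cell_types, L)
}

sample_background_windows <- function(n_neg, genome, peak_gr, get_hist,
                                      cell_types, L) {
  chroms <- names(genome)
  clen <- nchar(genome)
  usable <- chroms[clen >= L]
  if (!length(usable)) abort("no chromosome long enough for background windows.")
  out <- list()
  got <- 0
  tries <- 0
  while (got < n_neg && tries < 50 * n_neg + 100) {
    tries <- tries + 1
    ch <- sample(usable, 1, prob = clen[usable])
    st <- sample.int(clen[ch] - L + 1L, 1) - 1L
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st + 1L, st + L))
    if (GenomicRanges::countOverlaps(gr, peak_gr) > 0) next
    sq <- toupper(substring(genome[[ch]], st + 1L, st + L))
    if (grepl("N", sq)) next
    got <- got + 1
    out[[got]] <- tibble::tibble(
      id = sprintf("neg%05d", got), chrom = ch, start = st, end = st + L,
      sequence = sq,
      labels = list(stats::setNames(integer(length(cell_types)), cell_types)),
      histone = list(get_hist(ch, st, st + L)), is_positive = FALSE)
  }
  if (got < n_neg) warn(sprintf("only %d of %d background windows found.",
                                got, n_neg))
  dplyr::bind_rows(out)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns a random sequence with exactly the same
#' dinucleotide (and hence mononucleotide) counts as the input, and the same
#' first and last base. Used to build negative windows that destroy motifs
#' while preserving local composition.
#'
#' @param sequence A DNA string.
#' @return A shuffled string of the same length.
#' @export
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  if (n < 3 || length(unique(s)) == 1) return(paste(s, collapse = ""))
  verts <- unique(s)
  edges <- split(s[-1], factor(s[-n], levels = verts)) # outgoing targets
  terminal <- s[n]
  # choose a random last outgoing edge per non-terminal vertex such that the
  # chosen edges form a tree into the terminal vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == terminal || !length(edges[[v]])) NA_character_
      else sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == terminal || !length(edges[[v]])) next
      cur <- v
      seen <- character(0)
      while (cur != terminal) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle remaining edges, append the reserved last edge
  lists <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == terminal || !length(e)) return(sample(e))
    drop <- match(last_edge[[v]], e)
    c(sample(e[-drop]), last_edge[[v]])
  })
  names(lists) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Tag positive sites as cell-type-shared or cell-type-specific
#'
#' A bound window of cell type `k` is *shared* if some bound window of another
#' cell type matches it at strictly more than `identity_threshold` of its
#' positions (ungapped, same orientation, equal length); otherwise it is
#' *specific*. With the default threshold 0.75 on 101-bp windows, 76 identical
#' positions make a site shared and 75 leave it specific.
#'
#' @param dataset A `tfgate_dataset`.
#' @param identity_threshold Fraction of identical positions that must be
#'   exceeded (default 0.75).
#' @return A tibble (`id`, `cell_type`, `tag`, `best_identity`) with one row
#'   per positive (window, cell type) pair; `tag` is `"shared"` or
#'   `"specific"`.
#' @export
classify_shared_specific <- function(dataset, identity_threshold = 0.75) {
  stopifnot(inherits(dataset, "tfgate_dataset"))
  L <- attr(dataset, "window_size")
  cell_types <- attr(dataset, "cell_types")
  labs <- label_matrix(dataset)
  M <- seq_to_int(dataset$sequence)
  res <- list()
  for (k in seq_along(cell_types)) {
    idx_k <- which(labs[, k] == 1L)
    if (!length(idx_k)) next
    # candidate sites bound in some other cell type; a multi-label window is
    # its own >threshold match (the same site bound in another cell type)
    others <- which(rowSums(labs[, -k, drop = FALSE] == 1L) > 0)
    best <- numeric(length(idx_k))
    if (length(others)) {
      Mc <- M[others, , drop = FALSE]
      for (j in seq_along(idx_k)) {
        i <- idx_k[j]
        ident <- rowSums(Mc == matrix(M[i, ], nrow(Mc), L, byrow = TRUE))
        best[j] <- max(ident) / L
      }
    }
    res[[k]] <- tibble::tibble(
      id = dataset$id[idx_k], cell_type = cell_types[k],
      tag = ifelse(best > identity_threshold, "shared", "specific"),
      best_identity = best)
  }
  dplyr::bind_rows(res)
}

#' Export dataset sequences to FASTA
#' @param dataset A `tfgate_dataset`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(dataset, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(dataset$sequence, dataset$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export per-cell-type positive windows to BED files
#' @param dataset A `tfgate_dataset`.
#' @param dir Output directory; one `peaks_<cell>.bed` per cell type.
#' @return The written paths, invisibly.
#' @export
export_bed <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- label_matrix(dataset)
  paths <- character(0)
  for (ct in colnames(labs)) {
    i <- which(labs[, ct] == 1L)
    gr <- GenomicRanges::GRanges(dataset$chrom[i],
                                 IRanges::IRanges(dataset$start[i] + 1L,
                                                  dataset$end[i]),
                                 name = dataset$id[i])
    p <- file.path(dir, sprintf("peaks_%s.bed", ct))
    rtracklayer::export(gr, p, format = "BED")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export histone coverage to bedGraph files
#'
#' Writes one bedGraph per mark covering each window's `[start-50, end+50)`
#' neighbourhood, so [read_coverage_track()] round-trips synthetic coverage.
#' Overlapping windows are written as-is (later windows win on read-back).
#'
#' @param dataset A `tfgate_dataset`.
#' @param dir Output directory; one `<mark>.bedGraph` per mark.
#' @return The written paths, invisibly.
#' @export
export_bedgraph <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (mk in histone_marks()) {
    rows <- purrr::pmap_dfr(
      list(dataset$chrom, dataset$start, dataset$histone),
      function(chrom, start, h) {
        v <- h[mk, ]
        pos0 <- start - 50L + seq_along(v) - 1L
        tibble::tibble(chrom = chrom, start = pos0, end = pos0 + 1L,
                       value = v)
      })
    rows <- rows[rows$start >= 0, ]
    p <- file.path(dir, sprintf("%s.bedGraph", mk))
    readr::write_tsv(rows, p, col_names = FALSE, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
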