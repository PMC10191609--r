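#' k-mer one-hot encoding of a DNA sequence
#'
#' Represents a length-`L` sequence as a `4^h x L` binary matrix in which
#' column `i` one-hot encodes the k-mer starting at position `i`. Overlapping
#' k-mers make neighbouring columns statistically dependent, which is the
#' point: the matrix carries order-`h` nucleotide dependencies that a plain
#' one-hot encoding (`h = 1`) cannot.
#'
#' Indexing is lexicographic with the most significant base first
#' (`A = 0, C = 1, G = 2, T = 3`), so for `h = 2` the dinucleotide `AA` maps to
#' row 1 and `AC` to row 2. Columns whose k-mer window would run past the
#' sequence end, or which cover an ambiguous base (`N`), are all-zero; this
#' keeps the matrix width at exactly `L`.
#'
#' @param sequence A single DNA string over `{A,C,G,T,N}`.
#' @param order_h Integer k-mer order, one of 1, 2, 3, 4.
#' @return A `4^order_h x L` numeric matrix with 0/1 entries. Row names are
#'   the k-mers in lexicographic order.
#' @examples
#' encode_kmer("ACGT", 2)[1:4, ]
#' @export
encode_kmer <- function(sequence, order_h = 2) {
  seq <- check_dna(sequence)
  if (!is.numeric(order_h) || length(order_h) != 1 || !order_h %in% 1:4) {
    abort("`order_h` must be one of 1, 2, 3, 4.")
  }
  h <- as.integer(order_h)
  L <- nchar(seq)
  b <- match(strsplit(seq, "")[[1]], dna_bases()) - 1L # 0-based, NA for N
  n_rows <- 4L^h
  out <- matrix(0, nrow = n_rows, ncol = L,
                dimnames = list(all_kmers(h), NULL))
  n_full <- L - h + 1L
  if (n_full >= 1L) {
    code <- integer(n_full)
    for (j in seq_len(h)) {
      code <- code + b[j:(n_full + j - 1L)] * 4L^(h - j)
    }
    ok <- which(!is.na(code))
    out[cbind(code[ok] + 1L, ok)] <- 1
  }
  out
}

all_kmers <- function(h) {
  k <- dna_bases()
  for (i in seq_len(h - 1)) k <- as.vector(t(outer(k, dna_bases(), paste0)))
  k
}

#' Read a pentamer DNA shape lookup table
#'
#' Reads a 5-column TSV (`pentamer`, `MGW`, `ProT`, `HelT`, `Roll`) mapping
#' A/C/G/T pentamers to the four structural descriptors: minor groove width
#' (Angstrom), propeller twist (degrees), helix twist (degrees) and roll
#' (degrees). Tables may carry all 1024 pentamers or only one strand of each
#' reverse-complement pair; lookups fall back to the reverse complement.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `shape_table` object (numeric matrix, pentamer row names).
#' @seealso [make_shape_table()] for a deterministic synthetic table.
#' @export
read_shape_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    pentamer = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  need <- c("pentamer", shape_features())
  if (!all(need %in% names(df))) {
    abort(sprintf("shape table must have columns: %s", paste(need, collapse = ", ")))
  }
  as_shape_table(as.matrix(df[shape_features()]), toupper(df$pentamer))
}

as_shape_table <- function(values, pentamers) {
  if (any(nchar(pentamers) != 5) || any(grepl("[^ACGT]", pentamers))) {
    abort("pentamers must be 5-mers over {A,C,G,T}.")
  }
  if (anyDuplicated(pentamers)) abort("duplicated pentamers in shape table.")
  if (any(!is.finite(values))) abort("shape table values must be finite.")
  rownames(values) <- pentamers
  structure(values, class = c("shape_table", class(values)))
}

#' @export
print.shape_table <- function(x, ...) {
  cat(sprintf("<shape_table> %d pentamers x %d features (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  invisible(x)
}

#' Write a shape table to TSV
#' @param table A `shape_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_table <- function(table, path) {
  df <- tibble::as_tibble(unclass(table)[, , drop = FALSE])
  df <- dplyr::bind_cols(tibble::tibble(pentamer = rownames(table)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

lookup_pentamers <- function(pentamers, table) {
  i <- match(pentamers, rownames(table))
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- match(revcomp(pentamers[miss]), rownames(table))
    if (anyNA(i)) {
      abort(sprintf("pentamer(s) absent from shape table even via reverse complement: %s",
                    paste(utils::head(pentamers[miss][is.na(i[miss])], 3), collapse = ", ")))
    }
  }
  unclass(table)[i, , drop = FALSE]
}

#' DNA shape feature matrix of a sequence
#'
#' Looks up the four structural descriptors of every pentamer in the sequence
#' and assigns them to the pentamer's centre position, yielding `n - 4`
#' interior values per feature for a length-`n` sequence. HelT and Roll, which
#' describe base-pair steps rather than single bases, are additionally
#' smoothed by averaging each pair of neighbouring values (the final value is
#' carried over so all rows keep `n - 4` interior entries). Every row is then
#' padded with two zeros on each side so the matrix width equals the sequence
#' length, ready to be stacked with the other per-position encodings.
#'
#' @param sequence A single DNA string over `{A,C,G,T}`, length >= 5.
#' @param table A `shape_table` (see [read_shape_table()], [make_shape_table()]).
#' @return A `4 x n` numeric matrix with rows `MGW`, `ProT`, `HelT`, `Roll`.
#' @export
encode_shape <- function(sequence, table) {
  seq <- check_dna(sequence)
  n <- nchar(seq)
  if (n < 5) abort("`sequence` must have length >= 5 for pentamer shape lookup.")
  if (grepl("N", seq)) abort("`sequence` must be N-free for shape lookup.")
  pent <- substring(seq, seq_len(n - 4L), seq_len(n - 4L) + 4L)
  vals <- lookup_pentamers(pent, table) # (n-4) x 4
  out <- matrix(0, nrow = 4, ncol = n, dimnames = list(shape_features(), NULL))
  core <- 3:(n - 2)
  out["MGW", core] <- vals[, "MGW"]
  out["ProT", core] <- vals[, "ProT"]
  for (f in c("HelT", "Roll")) {
    r <- vals[, f]
    r_next <- c(r[-1], r[length(r)]) # replicate last step value
    out[f, core] <- (r + r_next) / 2
  }
  out
}

#' Histone modification feature matrix of a window
#'
#' Converts per-base coverage of the eight histone marks over a window plus
#' 50-bp flanks into a smoothed `8 x L` matrix. Coverage is first averaged in
#' non-overlapping 25-bp bins on a grid anchored at `window_start - 50`; each
#' output position then receives the mean of the four consecutive 25-bp bins
#' whose 100-bp span surrounds it (the position falls in the third bin of its
#' span). This two-level binning equals a 100-bp moving average whose start is
#' quantized to the 25-bp grid, and needs exactly the 50-bp flanks.
#'
#' @param coverage A numeric matrix with one row per mark (rows named as
#'   [histone_marks()], any order) and `L + 100` columns spanning
#'   `[window_start - 50, window_end + 50)`, or a named list of such vectors.
#'   `NA` values (coverage gaps) are treated as 0 with a warning.
#' @param L Window width in bp (default 101).
#' @return An `8 x L` numeric matrix, rows in the fixed mark order.
#' @export
encode_histone <- function(coverage, L = 101) {
  marks <- histone_marks()
  if (is.list(coverage)) coverage <- do.call(rbind, coverage)
  if (!is.matrix(coverage) || is.null(rownames(coverage))) {
    abort("`coverage` must be a matrix (or named list) with mark row names.")
  }
  missing <- setdiff(marks, rownames(coverage))
  if (length(missing)) {
    abort(sprintf("missing histone mark(s): %s", paste(missing, collapse = ", ")))
  }
  coverage <- coverage[marks, , drop = FALSE]
  if (ncol(coverage) < L + 100) {
    abort(sprintf("coverage must span the window plus 50 bp flanks (need %d columns, got %d).",
                  L + 100, ncol(coverage)))
  }
  if (anyNA(coverage)) {
    warn("coverage gaps (NA) treated as 0.")
    coverage[is.na(coverage)] <- 0
  }
  if (any(coverage < 0)) abort("histone coverage must be non-negative.")
  coverage %*% histone_bin_matrix(L, ncol(coverage))
}

# (L+100) x L averaging operator: column i averages the 100 coverage columns
# of the four 25-bp bins around position i. Cached per (L, n_cols).
histone_bin_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(L, n_cols) {
    key <- paste(L, n_cols)
    if (!is.null(cache[[key]])) return(cache[[key]])
    M <- matrix(0, nrow = n_cols, ncol = L)
    for (i in seq_len(L)) {
      o <- i + 49L                        # 0-based offset of position i in coverage
      b <- o %/% 25L                      # 25-bp grid bin of the position
      cols <- (25L * (b - 2L) + 1L):(25L * (b + 2L)) # four bins = 100 columns
      M[cols, i] <- 1 / 100
    }
    cache[[key]] <- M
    M
  }
})

#' Encode every sample of a dataset into feature arrays
#'
#' Produces the three stacked feature arrays consumed by the model: k-mer
#' (`4^h x L x N`), shape (`4 x L x N`) and histone (`8 x L x N`), plus the
#' label matrix.
#'
#' @param dataset A `tfgate_dataset` tibble (see [generate_dataset()],
#'   [build_multitask_dataset()]).
#' @param shape_table A `shape_table` for the shape features.
#' @param kmer_order k-mer order `h` (1-4).
#' @return A list with elements `kmer`, `shape`, `histone` (3-d arrays),
#'   `labels` (`N x n_cells` matrix) and `kmer_order`.
#' @export
encode_dataset <- function(dataset, shape_table, kmer_order = 2) {
  stopifnot(inherits(dataset, "tfgate_dataset"))
  L <- attr(dataset, "window_size")
  n <- nrow(dataset)
  K <- array(0, c(4^kmer_order, L, n))
  S <- array(0, c(4, L, n))
  for (i in seq_len(n)) {
    K[, , i] <- encode_kmer(dataset$sequence[i], kmer_order)
    S[, , i] <- encode_shape(dataset$sequence[i], shape_table)
  }
  # histone: one big matmul across samples
  cov_all <- do.call(rbind, dataset$histone) # (8*n) x (L+100)
  enc <- cov_all %*% histone_bin_matrix(L, ncol(cov_all))
  H <- array(0, c(8, L, n))
  for (i in seq_len(n)) H[, , i] <- enc[(i - 1) * 8 + 1:8, ]
  labels <- do.call(rbind, dataset$labels)
  colnames(labels) <- attr(dataset, "cell_types")
  list(kmer = K, shape = S, histone = H, labels = labels, kmer_order = kmer_order)
}
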