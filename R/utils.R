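#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm runif predict
#' @useDynLib tfgate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# Fixed row orders used throughout: these are contracts, not conveniences.
histone_marks <- function() {
  c("H3K27ac", "H3K36me3", "H3K4me2", "H3K9ac",
    "H3K27me3", "H3K4me1", "H3K4me3", "H3K9me3")
}

shape_features <- function() c("MGW", "ProT", "HelT", "Roll")

dna_bases <- function() c("A", "C", "G", "T")

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a reproducible stage seed from a global seed
#'
#' A single run seed fans out to per-stage seeds through a stable string hash,
#' so individual pipeline stages (simulation, splitting, training) are
#' independently reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) %% 31L + 1L))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587)
}

check_dna <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    abort(sprintf("`%s` must be a single character string.", arg))
  }
  if (nchar(sequence) == 0) {
    abort(sprintf("`%s` is empty.", arg))
  }
  seq <- toupper(sequence)
  if (grepl("[^ACGTN]", seq)) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T,N}.", arg))
  }
  seq
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Split sequences into an integer matrix (n x L), 1..4 = A,C,G,T, NA otherwise.
seq_to_int <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1) abort("sequences must share one length.")
  m <- matrix(match(unlist(strsplit(toupper(sequences), "")), dna_bases()),
              nrow = length(sequences), ncol = L, byrow = TRUE)
  m
}
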