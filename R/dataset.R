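#' Construct a multi-cell-type TFBS dataset
#'
#' A `tfgate_dataset` is a tibble with one row per 101-bp window and
#' list-columns for the per-cell-type binary labels and the raw histone
#' coverage (marks x window + 50-bp flanks). Cell types, mark order, window
#' size and the train/validation/test split live in attributes.
#'
#' @param samples A tibble with columns `id`, `chrom`, `start`, `end`,
#'   `sequence`, `labels` (list of named 0/1 integer vectors), `histone`
#'   (list of `8 x (L+100)` matrices), `is_positive`.
#' @param cell_types Character vector of cell-type names.
#' @param window_size Window width `L` in bp.
#' @param split Optional list with integer index vectors `train`, `valid`,
#'   `test`.
#' @return A `tfgate_dataset` tibble.
#' @keywords internal
#' @export
new_tfgate_dataset <- function(samples, cell_types, window_size = 101,
                               split = NULL) {
  stopifnot(is.data.frame(samples))
  need <- c("id", "chrom", "start", "end", "sequence", "labels", "histone",
            "is_positive")
  if (!all(need %in% names(samples))) {
    abort(sprintf("dataset needs columns: %s", paste(need, collapse = ", ")))
  }
  bad <- nchar(samples$sequence) != window_size
  if (any(bad)) abort("every sequence must have length `window_size`.")
  lab_ok <- vapply(samples$labels, function(l) {
    length(l) == length(cell_types) && all(l %in% c(0L, 1L))
  }, logical(1))
  if (!all(lab_ok)) abort("labels must be 0/1 vectors, one entry per cell type.")
  out <- tibble::as_tibble(samples)
  class(out) <- c("tfgate_dataset", class(out))
  attr(out, "cell_types") <- cell_types
  attr(out, "marks") <- histone_marks()
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "split") <- split
  out
}

#' @export
print.tfgate_dataset <- function(x, ...) {
  ct <- attr(x, "cell_types")
  sp <- attr(x, "split")
  cat(sprintf("<tfgate_dataset> %d windows of %d bp, %d cell type(s): %s\n",
              nrow(x), attr(x, "window_size"), length(ct),
              paste(ct, collapse = ", ")))
  if (!is.null(sp)) {
    cat(sprintf("  split: %d train / %d valid / %d test\n",
                length(sp$train), length(sp$valid), length(sp$test)))
  }
  NextMethod()
}

label_matrix <- function(dataset) {
  m <- do.call(rbind, dataset$labels)
  colnames(m) <- attr(dataset, "cell_types")
  m
}

#' Random train/validation/test split
#'
#' Randomly partitions sample indices at the given fractions (default
#' 60/20/20). The validation and test sizes are `round(f * N)`; any rounding
#' remainder goes to the training set.
#'
#' @param dataset A `tfgate_dataset`.
#' @param fractions Length-3 numeric summing to 1 (train, valid, test).
#' @param seed Integer seed making the split reproducible.
#' @return The dataset with a `split` attribute (`train`, `valid`, `test`
#'   integer index vectors, disjoint and exhaustive).
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(inherits(dataset, "tfgate_dataset"))
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0)) {
    abort("`fractions` must be three non-negative numbers summing to 1.")
  }
  n <- nrow(dataset)
  if (n < 5) abort("need at least 5 samples to split.")
  n_valid <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_valid - n_test
  if (n_train < 0) abort("rounding left no training samples.")
  perm <- with_local_seed(seed, sample.int(n))
  split <- list(
    train = sort(perm[seq_len(n_train)]),
    valid = sort(perm[n_train + seq_len(n_valid)]),
    test = sort(perm[n_train + n_valid + seq_len(n_test)])
  )
  attr(dataset, "split") <- split
  dataset
}

#' Access the split of a dataset
#' @param dataset A `tfgate_dataset`.
#' @return A list with `train`, `valid`, `test` index vectors (or `NULL`).
#' @export
dataset_split <- function(dataset) attr(dataset, "split")

# Run code under a temporary RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write a dataset to a directory of plain-text files
#'
#' Serializes a `tfgate_dataset` as `samples.tsv`, `histone.tsv` (one row per
#' sample x mark) and a JSON `manifest.json` recording cell types, marks,
#' window size and split indices. [read_dataset()] restores it losslessly.
#'
#' @param dataset A `tfgate_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- vapply(dataset$labels, paste, character(1), collapse = ",")
  readr::write_tsv(
    tibble::tibble(id = dataset$id, chrom = dataset$chrom,
                   start = dataset$start, end = dataset$end,
                   sequence = dataset$sequence, labels = labs,
                   is_positive = dataset$is_positive),
    file.path(dir, "samples.tsv"), progress = FALSE)
  hist_tbl <- purrr::map2_dfr(dataset$id, dataset$histone, function(id, h) {
    tibble::tibble(id = id, mark = rownames(h),
                   values = apply(h, 1, paste, collapse = ","))
  })
  readr::write_tsv(hist_tbl, file.path(dir, "histone.tsv"), progress = FALSE)
  manifest <- list(
    cell_types = attr(dataset, "cell_types"),
    marks = attr(dataset, "marks"),
    window_size = attr(dataset, "window_size"),
    n_samples = nrow(dataset),
    split = attr(dataset, "split")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory containing `samples.tsv`, `histone.tsv`,
#'   `manifest.json`.
#' @return A `tfgate_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  smp <- readr::read_tsv(file.path(dir, "samples.tsv"), progress = FALSE,
                         col_types = readr::cols())
  hist_tbl <- readr::read_tsv(file.path(dir, "histone.tsv"), progress = FALSE,
                              col_types = readr::cols())
  cell_types <- manifest$cell_types
  labels <- lapply(strsplit(smp$labels, ","), function(x) {
    stats::setNames(as.integer(x), cell_types)
  })
  hist_split <- split(hist_tbl, factor(hist_tbl$id, levels = smp$id))
  histone <- lapply(hist_split, function(d) {
    m <- do.call(rbind, lapply(strsplit(d$values, ","), as.numeric))
    rownames(m) <- d$mark
    m[histone_marks(), , drop = FALSE]
  })
  split <- manifest$split
  if (!is.null(split)) split <- lapply(split, as.integer)
  new_tfgate_dataset(
    tibble::tibble(id = smp$id, chrom = smp$chrom, start = smp$start,
                   end = smp$end, sequence = smp$sequence, labels = labels,
                   histone = unname(histone), is_positive = smp$is_positive),
    cell_types = cell_types, window_size = manifest$window_size,
    split = split
  )
}
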