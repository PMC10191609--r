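#' Per-cell-type auROC of a fitted model
#'
#' Scores the requested split of a dataset and computes rank-based auROC per
#' cell type, optionally stratified into cell-type-shared and
#' cell-type-specific positives (negatives are always all included). A cell
#' type whose evaluated set lacks a class gets `NA` rather than an error.
#'
#' @param fit A `tfgate_fit`.
#' @param dataset A `tfgate_dataset` (defaults to evaluating the same data
#'   the model was fitted on).
#' @param split One of `"test"`, `"valid"`, `"train"`, `"all"`.
#' @param stratum_tags Optional output of [classify_shared_specific()]; when
#'   given, extra rows per stratum are reported.
#' @return A `tfgate_eval` tibble: `cell_type`, `stratum`, `n_pos`, `n_neg`,
#'   `auroc`, plus macro rows (`cell_type = "macro"`).
#' @export
evaluate_auroc <- function(fit, dataset, split = "test",
                           stratum_tags = NULL) {
  stopifnot(inherits(fit, "tfgate_fit"), inherits(dataset, "tfgate_dataset"))
  idx <- eval_indices(dataset, split)
  pr <- predict(fit, dataset, indices = idx)
  labs <- label_matrix(dataset)[idx, , drop = FALSE]
  rows <- list()
  for (k in seq_along(fit$cell_types)) {
    ct <- fit$cell_types[k]
    scores <- pr[[ct]]
    strata <- list(all = rep(TRUE, length(idx)))
    if (!is.null(stratum_tags)) {
      tags_k <- stratum_tags[stratum_tags$cell_type == ct, ]
      for (tg in c("shared", "specific")) {
        keep_ids <- tags_k$id[tags_k$tag == tg]
        strata[[tg]] <- labs[, k] == 0 | dataset$id[idx] %in% keep_ids
      }
    }
    for (st in names(strata)) {
      sel <- strata[[st]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_type = ct, stratum = st,
        n_pos = sum(labs[sel, k] == 1), n_neg = sum(labs[sel, k] == 0),
        auroc = auroc(scores[sel], labs[sel, k]))
    }
  }
  out <- dplyr::bind_rows(rows)
  macro <- out |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(cell_type = "macro", n_pos = sum(.data$n_pos),
                     n_neg = sum(.data$n_neg),
                     auroc = mean(.data$auroc, na.rm = TRUE), .groups = "drop")
  out <- dplyr::bind_rows(out, macro[, names(out)])
  class(out) <- c("tfgate_eval", class(out))
  attr(out, "split") <- split
  out
}

eval_indices <- function(dataset, split) {
  sp <- attr(dataset, "split")
  if (identical(split, "all") || is.null(sp)) return(seq_len(nrow(dataset)))
  if (!split %in% names(sp)) abort("`split` must be test, valid, train or all.")
  sp[[split]]
}

#' Macro-average auROC of an evaluation table
#' @param eval_tbl A `tfgate_eval` tibble.
#' @param stratum Stratum to average (default `"all"`).
#' @return The macro-average auROC.
#' @export
macro_auroc <- function(eval_tbl, stratum = "all") {
  eval_tbl$auroc[eval_tbl$cell_type == "macro" &
                   eval_tbl$stratum == stratum]
}

#' Cross-factor transfer evaluation
#'
#' Applies a frozen model trained on one TF's dataset to another TF's test
#' split, measuring whether the learned higher-order dependencies transfer
#' across factors in the same cellular environments.
#'
#' @param fit A `tfgate_fit` trained on TF A.
#' @param dataset_b TF B's `tfgate_dataset` (same cell-type list and window
#'   size).
#' @param split Split of `dataset_b` to score (default `"test"`).
#' @return A `tfgate_eval` tibble with a `provenance` attribute.
#' @export
cross_factor_eval <- function(fit, dataset_b, split = "test") {
  if (!identical(attr(dataset_b, "cell_types"), fit$cell_types)) {
    abort("datasets must share the same cell-type list.")
  }
  if (attr(dataset_b, "window_size") != fit$config$window_size) {
    abort("datasets must share the window size.")
  }
  out <- evaluate_auroc(fit, dataset_b, split = split)
  attr(out, "provenance") <- list(model = "frozen", eval_split = split)
  out
}

#' Feature-combination and leave-one-track-out ablations
#'
#' Retrains the model for each requested feature configuration (excluded
#' inputs are zeroed so the encoder is bypassed) and reports test auROC and
#' its change relative to the full model trained under identical control
#' settings. `subsets` ablates whole feature streams; `leave_out_tracks`
#' drops one named shape feature or histone mark at a time.
#'
#' @param dataset A split `tfgate_dataset`.
#' @param config Base [tfgate_config()].
#' @param subsets List of feature-stream subsets, e.g.
#'   `list("kmer", c("kmer", "shape"))`.
#' @param leave_out_tracks Character vector of shape-feature or histone-mark
#'   names to leave out one at a time.
#' @param shape_table,control Passed to [tfgate_fit()].
#' @return A tibble: `variant`, `cell_type`, `auroc`, `delta_auroc`
#'   (full minus variant; positive means the removed input helped).
#' @export
ablate_features <- function(dataset, config = NULL, subsets = NULL,
                            leave_out_tracks = NULL,
                            shape_table = make_shape_table(),
                            control = tfgate_train_control()) {
  if (is.null(subsets) && is.null(leave_out_tracks)) {
    abort("supply `subsets` and/or `leave_out_tracks`.")
  }
  if (is.null(config)) {
    config <- tfgate_config(n_cells = length(attr(dataset, "cell_types")),
                            window_size = attr(dataset, "window_size"))
  }
  variants <- list(full = config)
  for (ss in subsets %||% list()) {
    v <- config
    v$features <- match.arg(ss, stream_names(), several.ok = TRUE)
    variants[[paste(v$features, collapse = "+")]] <- v
  }
  for (tr in leave_out_tracks %||% character(0)) {
    v <- config
    if (tr %in% shape_features()) v$drop_shape_rows <- union(v$drop_shape_rows, tr)
    else if (tr %in% histone_marks()) {
      v$drop_histone_rows <- union(v$drop_histone_rows, tr)
    } else abort(sprintf("unknown track '%s'.", tr))
    variants[[paste0("minus_", tr)]] <- v
  }
  res <- purrr::imap_dfr(variants, function(v, nm) {
    f <- tfgate_fit(dataset, v, shape_table = shape_table, control = control)
    ev <- evaluate_auroc(f, dataset, split = "test")
    ev <- ev[ev$stratum == "all", c("cell_type", "auroc")]
    dplyr::mutate(ev, variant = nm, .before = 1)
  })
  full <- res[res$variant == "full", ]
  res$delta_auroc <- full$auroc[match(res$cell_type, full$cell_type)] -
    res$auroc
  res
}

#' k-mer order sweep
#'
#' Retrains the model for each k-mer order with everything else fixed and
#' reports test auROC per cell type plus the macro average.
#'
#' @param dataset A split `tfgate_dataset`.
#' @param orders Integer orders to evaluate (subset of 1:4).
#' @param config Base [tfgate_config()].
#' @param shape_table,control Passed to [tfgate_fit()].
#' @return A tibble: `order`, `cell_type`, `auroc`.
#' @export
sweep_kmer_order <- function(dataset, orders = 1:4, config = NULL,
                             shape_table = make_shape_table(),
                             control = tfgate_train_control()) {
  if (!length(orders)) abort("`orders` must be non-empty.")
  if (is.null(config)) {
    config <- tfgate_config(n_cells = length(attr(dataset, "cell_types")),
                            window_size = attr(dataset, "window_size"))
  }
  purrr::map_dfr(orders, function(h) {
    v <- config
    v$kmer_order <- as.integer(h)
    f <- tfgate_fit(dataset, v, shape_table = shape_table, control = control)
    ev <- evaluate_auroc(f, dataset, split = "test")
    ev <- ev[ev$stratum == "all", c("cell_type", "auroc")]
    dplyr::mutate(ev, order = as.integer(h), .before = 1)
  })
}
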