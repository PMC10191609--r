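#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x A `tfgate_fit`.
#' @param ... Unused.
#' @return A long tibble: `epoch`, `metric` (`train_loss`,
#'   `valid_macro_auroc`), `value`.
#' @method tidy tfgate_fit
#' @export
tidy.tfgate_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a fitted model
#'
#' @param x A `tfgate_fit`.
#' @param ... Unused.
#' @return A tibble with `n_cells`, `n_parameters`, `epochs_trained`,
#'   `best_epoch`, `best_valid_macro_auroc`, `final_train_loss`.
#' @export
glance.tfgate_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_cells = x$config$n_cells,
    n_parameters = n_parameters(x),
    epochs_trained = nrow(h),
    best_epoch = x$best_epoch,
    best_valid_macro_auroc = if (all(is.na(h$valid_macro_auroc))) NA_real_
      else max(h$valid_macro_auroc, na.rm = TRUE),
    final_train_loss = h$train_loss[nrow(h)])
}

#' @method tidy tfgate_eval
#' @export
tidy.tfgate_eval <- function(x, ...) tibble::as_tibble(x)

#' Training-history curves
#' @param object A `tfgate_fit`.
#' @param ... Unused.
#' @return A ggplot with one panel per metric.
#' @method autoplot tfgate_fit
#' @export
autoplot.tfgate_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-cell-type auROC bars
#' @param object A `tfgate_eval` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tfgate_eval
#' @export
autoplot.tfgate_eval <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$cell_type != "macro", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_type, y = .data$auroc,
                                  fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "auROC") +
    ggplot2::theme_minimal()
}

#' Gate-utilization bars
#' @param object A `tfgate_gate_utilization` tibble.
#' @param ... Unused.
#' @return A ggplot, one panel per cell type.
#' @method autoplot tfgate_gate_utilization
#' @export
autoplot.tfgate_gate_utilization <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sub_expert, y = .data$utilization,
                               fill = .data$sub_expert)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = NULL, y = "mean gate weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
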