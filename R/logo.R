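# Sequence-logo rendering from simple letter polygons. Letters are drawn as
# filled polygons in the unit box and scaled per column to the information
# contribution p * IC of each base.

letter_polygons <- local({
  arc <- function(a0, a1, r_out = 0.5, r_in = 0.3, n = 24) {
    th <- seq(a0, a1, length.out = n) * pi / 180
    data.frame(
      x = 0.5 + c(r_out * cos(th), rev(r_in * cos(th))),
      y = 0.5 + c(r_out * sin(th), rev(r_in * sin(th))))
  }
  rect <- function(x0, y0, x1, y1) {
    data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  quad <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(x = m[, 1], y = m[, 2])
  }
  list(
    A = list(quad(0, 0, 0.17, 0, 0.57, 1, 0.43, 1),
             quad(0.83, 0, 1, 0, 0.57, 1, 0.43, 1),
             rect(0.22, 0.27, 0.78, 0.42)),
    C = list(arc(35, 325)),
    G = list(arc(35, 325), rect(0.55, 0.28, 1, 0.43), rect(0.85, 0.28, 1, 0.5)),
    T = list(rect(0, 0.85, 1, 1), rect(0.41, 0, 0.59, 0.85))
  )
})

logo_data <- function(pwm, scale_ic = TRUE) {
  p <- unclass(pwm)
  rownames(p) <- dna_bases()
  ic <- if (scale_ic) pwm_information(p) else rep(1, ncol(p))
  out <- list()
  for (i in seq_len(ncol(p))) {
    heights <- p[, i] * ic[i]
    ord <- order(heights) # small letters at the bottom
    y0 <- 0
    for (b in dna_bases()[ord]) {
      h <- heights[b]
      if (h <= 1e-9) next
      for (pg in seq_along(letter_polygons[[b]])) {
        poly <- letter_polygons[[b]][[pg]]
        out[[length(out) + 1L]] <- data.frame(
          x = i - 0.45 + poly$x * 0.9, y = y0 + poly$y * h, base = b,
          group = sprintf("c%d_%s_%d", i, b, pg))
      }
      y0 <- y0 + h
    }
  }
  do.call(rbind, out)
}

#' Information-content-scaled sequence logo of a PWM
#'
#' @param pwm A 4-row column-stochastic matrix (`tfgate_pwm`).
#' @param scale_ic Scale column heights by information content in bits
#'   (default TRUE); a uniform PWM then draws a flat, zero-height logo.
#' @return A ggplot.
#' @export
plot_logo <- function(pwm, scale_ic = TRUE) {
  d <- logo_data(pwm, scale_ic)
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  gg <- ggplot2::ggplot() +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(pwm))) +
    ggplot2::labs(x = "position",
                  y = if (scale_ic) "bits" else "probability") +
    ggplot2::theme_minimal()
  if (!is.null(d)) {
    gg <- gg + ggplot2::geom_polygon(
      data = d, ggplot2::aes(x = .data$x, y = .data$y, group = .data$group,
                             fill = .data$base), show.legend = FALSE) +
      ggplot2::scale_fill_manual(values = cols)
  }
  if (scale_ic) gg <- gg + ggplot2::coord_cartesian(ylim = c(0, 2))
  gg
}

#' @method autoplot tfgate_pwm
#' @export
autoplot.tfgate_pwm <- function(object, ...) plot_logo(object)

#' Export a motif as a logo image and a MEME-format record
#'
#' @param pwm A `tfgate_pwm`.
#' @param path_prefix Files `<prefix>.png` (or `.svg`) and `<prefix>.meme`
#'   are written.
#' @param device `"png"` or `"svg"`.
#' @return The two paths, invisibly.
#' @export
export_logo <- function(pwm, path_prefix, device = c("png", "svg")) {
  device <- match.arg(device)
  if (!is.matrix(pwm) || nrow(pwm) != 4 ||
      any(abs(colSums(unclass(pwm)) - 1) > 1e-6) || any(pwm < 0)) {
    abort("malformed PWM: need a 4-row column-stochastic matrix.")
  }
  img <- paste0(path_prefix, ".", device)
  ggplot2::ggsave(img, plot_logo(pwm), width = 1 + 0.4 * ncol(pwm),
                  height = 2, dpi = 150)
  meme <- paste0(path_prefix, ".meme")
  write_meme(pwm, meme)
  invisible(c(img, meme))
}
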