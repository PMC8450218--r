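# ggplot2 views of fascicle architectures and comparisons.

#' Plot fascicle polylines projected onto a muscle plane
#'
#' @param points Fascicle point tibble.
#' @param frame Optional [compute_frame()] result (computed when `NULL`).
#' @param plane `"length-height"` (e1-e2, the classic pennation view),
#'   `"length-width"` (e1-e3, top view) or `"width-height"` (e3-e2, cross
#'   section).
#' @return A ggplot object.
#' @export
plot_fascicles <- function(points, frame = NULL,
                           plane = c("length-height", "length-width",
                                     "width-height")) {
  plane <- match.arg(plane)
  if (is.null(frame)) frame <- compute_frame(points)
  m <- all_coords(points)
  fc <- frame_coords(m, frame)
  ax <- switch(plane,
               "length-height" = list(i = 1, j = 2, x = "e1 (length, mm)", y = "e2 (height, mm)"),
               "length-width" = list(i = 1, j = 3, x = "e1 (length, mm)", y = "e3 (width, mm)"),
               "width-height" = list(i = 3, j = 2, x = "e3 (width, mm)", y = "e2 (height, mm)"))
  df <- tibble::tibble(
    fascicle_id = points$fascicle_id,
    u = fc[, ax$i], v = fc[, ax$j]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   group = .data$fascicle_id)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = ax$x, y = ax$y) +
    ggplot2::theme_minimal()
}

#' @rdname measure_architecture
#' @param object A `muscle_architecture` object.
#' @param type `"fascicles"` (projected polyline view is not available from the
#'   summary; uses per-fascicle length histogram), `"lengths"` or `"angles"`.
#' @method autoplot muscle_architecture
#' @export
autoplot.muscle_architecture <- function(object, type = c("lengths", "angles"),
                                         ...) {
  type <- match.arg(type)
  pf <- object$per_fascicle
  if (type == "lengths") {
    ggplot2::ggplot(pf, ggplot2::aes(x = .data$length_mm)) +
      ggplot2::geom_histogram(bins = 20, fill = "grey40", colour = "white") +
      ggplot2::labs(x = "fascicle length (mm)", y = "count") +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(pf[, c("fascicle_id", "alpha_deg", "beta_deg")],
                                cols = c("alpha_deg", "beta_deg"),
                                names_to = "angle", values_to = "deg")
    long$angle <- ifelse(long$angle == "beta_deg", "pennation beta",
                         "transversal alpha")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$angle, y = .data$deg)) +
      ggplot2::geom_boxplot(fill = "grey80") +
      ggplot2::labs(x = NULL, y = "angle (deg)") +
      ggplot2::theme_minimal()
  }
}

#' @rdname compare_architecture
#' @param object An `architecture_comparison` tibble.
#' @param ... Unused.
#' @method autoplot architecture_comparison
#' @export
autoplot.architecture_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$metric, y = .data$error_pct)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "relative error (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
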