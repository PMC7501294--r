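# ggplot2 views of the per-fibre results: 2Dmito scatter with the control
# band, theta stripcharts, KDE curves and spatial fibre maps.

#' 2Dmito plot: target versus mitochondrial mass with the control band
#'
#' Scatter of patient fibres on the band's working scale with the control
#' regression line (solid) and predictive interval (dashed). Points are
#' coloured by call; the above/below counts appear in the subtitle, as in
#' the conventional presentation of these panels.
#'
#' @param calls Result of [classify_2dmito()].
#' @param band The [regression_band()] used for the calls.
#' @param controls Optional control fibre table drawn in grey underneath.
#' @return A ggplot object.
#' @export
plot_2dmito <- function(calls, band, controls = NULL) {
  stopifnot(inherits(band, "regression_band"))
  grid <- seq(min(calls$.x), max(calls$.x), length.out = 200)
  bb <- band_bounds(band, grid)
  cnt <- call_counts(calls)
  p <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$.x, y = .data$.y))
  if (!is.null(controls)) {
    ctrl <- tibble(.x = scale_values(controls[[band$reference]], band$scale),
                   .y = scale_values(controls[[band$channel]], band$scale))
    p <- p + ggplot2::geom_point(data = ctrl, colour = "grey70", size = 0.8)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call), size = 0.9) +
    ggplot2::geom_line(data = bb, ggplot2::aes(.data$x, .data$fit),
                       colour = "grey40") +
    ggplot2::geom_line(data = bb, ggplot2::aes(.data$x, .data$lwr),
                       colour = "grey40", linetype = "dashed") +
    ggplot2::geom_line(data = bb, ggplot2::aes(.data$x, .data$upr),
                       colour = "grey40", linetype = "dashed") +
    ggplot2::labs(
      x = paste0(band$scale, " ", band$reference),
      y = paste0(band$scale, " ", band$channel),
      colour = NULL,
      subtitle = sprintf("above: %d  below: %d", cnt["above"], cnt["below"])) +
    ggplot2::theme_minimal()
}

#' @method autoplot regression_band
#' @export
autoplot.regression_band <- function(object, ...) {
  grid <- seq(object$xbar - 3 * sqrt(object$sxx / object$n_control),
              object$xbar + 3 * sqrt(object$sxx / object$n_control),
              length.out = 200)
  bb <- band_bounds(object, grid)
  ggplot2::ggplot(bb, ggplot2::aes(.data$x, .data$fit)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::labs(x = object$reference, y = object$channel,
                  title = sprintf("%d%% predictive band",
                                  round(100 * object$level))) +
    ggplot2::theme_minimal()
}

#' @method autoplot pdf_estimate
#' @export
autoplot.pdf_estimate <- function(object, ...) {
  ggplot2::ggplot(tibble(x = object$x, y = object$y),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "theta (degrees)", y = "density",
                  title = if (is.na(object$source)) NULL else object$source) +
    ggplot2::theme_minimal()
}

#' Theta stripchart across channels
#'
#' One strip per channel showing per-fibre theta values, patient coloured
#' over control grey, the view used to compare relative expression of all
#' targets at once.
#'
#' @param long Long-format table from [export_long()] (or any tibble with
#'   `channel`, `theta`, `control` columns).
#' @return A ggplot object.
#' @export
plot_theta_strip <- function(long) {
  ggplot2::ggplot(long, ggplot2::aes(x = .data$channel, y = .data$theta)) +
    ggplot2::geom_jitter(data = dplyr::filter(long, .data$control),
                         colour = "grey70", width = 0.25, size = 0.7) +
    ggplot2::geom_jitter(data = dplyr::filter(long, !.data$control),
                         ggplot2::aes(colour = .data$theta),
                         width = 0.25, size = 0.7) +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = NULL, y = "theta (degrees)") +
    ggplot2::theme_minimal()
}

#' Spatial fibre map of deficiency and neighbourhoods
#'
#' Redraws the section as circles at fibre centroids with area
#' proportional to fibre area, highlighting deficient fibres and their
#' neighbour set from a [neighbourhood_enrichment()] result.
#'
#' @param fibres Fibre table with `x`, `y`, `area`.
#' @param enrichment An `enrichment_result`.
#' @param deficient Logical deficiency flags aligned with `fibres`.
#' @return A ggplot object.
#' @export
plot_fibre_map <- function(fibres, enrichment, deficient) {
  stopifnot(inherits(enrichment, "enrichment_result"))
  status <- rep("other", nrow(fibres))
  status[enrichment$neighbour_set] <- "neighbour"
  status[deficient] <- "deficient"
  df <- dplyr::mutate(as_tibble(fibres), status = status)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$area,
                                     colour = .data$status), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(deficient = "gold2",
                                            neighbour = "steelblue",
                                            other = "grey75")) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  subtitle = sprintf("enrichment p = %.3g", enrichment$p)) +
    ggplot2::theme_minimal()
}

#' @method autoplot neighbour_graph
#' @export
autoplot.neighbour_graph <- function(object, ...) {
  edges <- tidy(object)
  nodes <- tibble(id = object$id, x = object$x, y = object$y)
  seg <- dplyr::left_join(edges, nodes, by = c(from = "id"))
  seg <- dplyr::left_join(seg, nodes, by = c(to = "id"),
                          suffix = c("", "_to"))
  ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$x_to, yend = .data$y_to),
                          colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
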