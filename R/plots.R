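# ggplot2 visualisations of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   labs scale_x_log10 scale_y_log10 geom_hline geom_raster
#'   scale_fill_viridis_c coord_equal theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a chlorophyll-distance gradient fit
#'
#' Band means against band-midpoint distance on log-log axes with the fitted
#' power law.
#'
#' @param object An `ime_gradient_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ime_gradient_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble::tibble(
    mid_deg = seq(min(d$mid_deg), max(d$mid_deg), length.out = 50))
  curve$mean_value <- object$a * curve$mid_deg^object$b
  ggplot(d, aes(x = .data$mid_deg, y = .data$mean_value)) +
    geom_line(data = curve, colour = "steelblue") +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "Distance to 30-m isobath (degrees)",
         y = "Sector-mean chlorophyll-a",
         title = sprintf("%s: b = %.3f (p = %.3g, r2 = %.2f)",
                         object$location_id, object$b, object$p_slope,
                         object$r2)) +
    theme_minimal()
}

#' Plot a cross-shore transect fit
#'
#' Depth-integrated chlorophyll anomalies (centred at 30 km) against
#' distance from shore with the fitted exponential decay.
#'
#' @param object An `ime_transect_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ime_transect_fit <- function(object, ...) {
  s <- object$stations
  xs <- seq(min(s$distance_km), max(s$distance_km), length.out = 80)
  curve <- tibble::tibble(
    distance_km = xs,
    delta_fitted = vapply(xs, object$fitted_at, 0) - object$reference)
  ggplot(s, aes(x = .data$distance_km, y = .data$delta_chl_int)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line(data = curve, aes(y = .data$delta_fitted), colour = "steelblue") +
    geom_point() +
    labs(x = "Distance from shore (km)",
         y = expression(Delta * Chl[int] ~ (mg ~ m^-2))) +
    theme_minimal()
}

#' Plot hierarchical-partitioning contributions
#'
#' @param object An `ime_partition`.
#' @param ... Unused.
#' @return A ggplot (bar chart of percent independent contributions).
#' @exportS3Method ggplot2::autoplot
autoplot.ime_partition <- function(object, ...) {
  d <- object$contributions
  ggplot(d, aes(x = stats::reorder(.data$predictor, -.data$percent),
                y = .data$percent)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Independent contribution to explained deviance (%)") +
    theme_minimal()
}

#' Map a scene grid
#'
#' Raster map of one of a scene's grids (chlorophyll by default) with the
#' land mask blanked.
#'
#' @param scene An `ime_ocean_scene` or `ime_multi_scene`.
#' @param layer One of `"chl"`, `"k490"`, `"depth"`.
#' @return A ggplot.
#' @export
plot_scene <- function(scene, layer = c("chl", "k490", "depth")) {
  layer <- match.arg(layer)
  grid <- expand.grid(lat = scene$lat, lon = scene$lon, KEEP.OUT.ATTRS = FALSE)
  grid$value <- as.vector(scene[[layer]])
  ggplot(grid, aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey85") +
    coord_equal() +
    labs(fill = layer, x = "Longitude", y = "Latitude") +
    theme_minimal()
}

#' Bar chart of per-location standing-stock enhancements
#'
#' @param enhancements Tibble from a run report (`location_id`,
#'   `percent_increase`).
#' @return A ggplot.
#' @export
plot_enhancement <- function(enhancements) {
  d <- dplyr::arrange(enhancements, dplyr::desc(.data$percent_increase))
  d$location_id <- factor(d$location_id, levels = d$location_id)
  ggplot(d, aes(x = .data$location_id, y = .data$percent_increase)) +
    geom_col(fill = "seagreen") +
    labs(x = NULL, y = "Total phytoplankton increase over offshore (%)") +
    theme_minimal()
}
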