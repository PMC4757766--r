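# Standing stock: depth-integrated chlorophyll (Sigma-Chl = chl / k490) and
# the total nearshore phytoplankton enhancement over the sector-8 offshore
# baseline, in kg and percent.

#' Depth-integrated chlorophyll field
#'
#' The depth of light penetration seen by the ocean-colour sensor is the
#' reciprocal of the diffuse attenuation k490; depth-integrated chlorophyll
#' (Sigma-Chl, mg m^-2) is the chlorophyll concentration times that depth,
#' pixelwise. The result is missing wherever either input is missing.
#'
#' @param chl Chlorophyll grid (mg m^-3) or an `ime_ocean_scene` (in which
#'   case `k490` is taken from the scene).
#' @param k490 Diffuse-attenuation grid (m^-1), co-registered with `chl`.
#' @return An `ime_stock_field`: list with `sigma_chl` and `light_depth`
#'   matrices.
#' @export
depth_integrated_chl <- function(chl, k490 = NULL) {
  if (inherits(chl, "ime_ocean_scene")) {
    k490 <- chl$k490
    chl <- chl$chl
  }
  stopifnot(is.matrix(chl), is.matrix(k490), all(dim(chl) == dim(k490)))
  bad <- which(!is.na(k490) & k490 <= 0)
  if (length(bad)) {
    stop_ime("k490 <= 0 at pixel(s) ", paste(head(bad, 5), collapse = ", "),
             if (length(bad) > 5) " ..." else "",
             ": light-penetration depth undefined.")
  }
  light_depth <- 1 / k490
  sigma <- chl * light_depth
  sigma[is.na(chl) | is.na(k490)] <- NA_real_
  structure(list(sigma_chl = sigma, light_depth = light_depth),
            class = "ime_stock_field")
}

#' Per-band sector areas
#'
#' Sums pixel areas over each band's members. A pixel's area is
#' `(dlat * 111.195 km) * (dlon * 111.195 * cos(lat) km)`, i.e. the
#' latitude-dependent shrinking of longitude is accounted for.
#'
#' @param sector_set An `ime_sector_set`.
#' @param lat Pixel-centre latitude axis (defaults to the one stored on the
#'   sector set).
#' @param grid_spacing Pixel edge length in degrees; defaults to the latitude
#'   axis step.
#' @return Tibble with `band`, `area_m2`.
#' @export
sector_area <- function(sector_set, lat = sector_set$lat,
                        grid_spacing = NULL) {
  stopifnot(inherits(sector_set, "ime_sector_set"))
  if (is.null(grid_spacing)) grid_spacing <- diff(lat[1:2])
  nr <- sector_set$dim[1]
  pixel_area_m2 <- function(pixels) {
    if (length(pixels) == 0) return(0)
    row <- ((pixels - 1) %% nr) + 1
    platlen <- grid_spacing * .km_per_deg
    plonlen <- grid_spacing * .km_per_deg * cos(lat[row] * pi / 180)
    sum(platlen * plonlen) * 1e6
  }
  tibble::tibble(
    band = sector_set$bands$band,
    area_m2 = vapply(sector_set$bands$pixels, pixel_area_m2, 0)
  )
}

#' Total nearshore standing-stock enhancement
#'
#' Sector 8 (the farthest band) represents offshore oceanic conditions. For
#' each more proximate band k = 1..7 the enhancement is `delta_sigma(k) =
#' mean Sigma-Chl(k) - mean Sigma-Chl(8)`; multiplying by the band area and
#' converting mg to kg gives the added phytoplankton mass per band, and the
#' sum over bands 1-7 the total added mass. The percent increase is that
#' total over the baseline mass the same area would hold at the offshore
#' Sigma-Chl. A location is only quantified when its Sigma-Chl gradient fit
#' is significantly negative (the inclusion rule); otherwise an
#' excluded-with-reason result is returned.
#'
#' @param sigma_series Sector series of Sigma-Chl from [sector_means()]
#'   applied to the `sigma_chl` grid.
#' @param areas Tibble from [sector_area()].
#' @param gradient_fit `ime_gradient_fit` of the Sigma-Chl series (the
#'   significance gate).
#' @param alpha Significance level of the gate.
#' @param floor_deltas If `TRUE`, bands whose mean delta is negative
#'   contribute zero mass; the default keeps them (they reduce the total).
#' @param use_fitted If `TRUE`, deltas are computed from the fitted power law
#'   at band midpoints instead of the observed band means.
#' @param sigma_grid,sector_set Optionally, the Sigma-Chl grid and the
#'   `ime_sector_set` the series came from. When supplied, each band's added
#'   mass is the exact pixel sum `sum((sigma(px) - reference) * area(px))`
#'   over the band's valid pixels, so band totals are exactly additive with
#'   a pixelwise computation (band areas and band means otherwise disagree
#'   slightly when pixels are missing or pixel areas vary with latitude).
#'   The reported `delta_sigma` is still the band-mean delta.
#' @return An `ime_enhancement`: list with `status` (`"quantified"` or
#'   `"excluded"`), `reference_sigma`, a per-band `sectors` tibble
#'   (`band`, `delta_sigma`, `area_m2`, `added_mass_kg`), `total_added_kg`,
#'   `baseline_mass_kg` and `percent_increase`.
#' @export
enhancement <- function(sigma_series, areas, gradient_fit, alpha = 0.05,
                        floor_deltas = FALSE, use_fitted = FALSE,
                        sigma_grid = NULL, sector_set = NULL) {
  stopifnot(inherits(gradient_fit, "ime_gradient_fit"))
  loc <- sigma_series$location_id[1]
  if (classify_ime(gradient_fit, alpha) != "enhanced") {
    return(structure(list(
      location_id = loc, status = "excluded",
      reason = sprintf("Sigma-Chl gradient not significantly negative (b = %.3g, p = %.3g)",
                       gradient_fit$b, gradient_fit$p_slope)
    ), class = "ime_enhancement"))
  }
  s <- dplyr::arrange(sigma_series, .data$band)
  if (nrow(s) < 8 || any(is.na(s$mean_value))) {
    stop_ime("All 8 band means are required (band ",
             paste(s$band[is.na(s$mean_value)], collapse = ", "),
             " missing).")
  }
  ref <- s$mean_value[s$band == 8]
  means <- if (use_fitted) {
    gradient_fit$a * s$mid_deg[s$band <= 7]^gradient_fit$b
  } else {
    s$mean_value[s$band <= 7]
  }
  delta <- means - ref
  area7 <- areas$area_m2[match(1:7, areas$band)]
  pixelwise <- !use_fitted && !is.null(sigma_grid) && !is.null(sector_set)
  if (pixelwise) {
    nr <- sector_set$dim[1]
    lats <- sector_set$lat
    gs <- abs(diff(lats[1:2]))
    added <- vapply(1:7, function(k) {
      px <- sector_set$bands$pixels[[match(k, sector_set$bands$band)]]
      px <- px[!is.na(sigma_grid[px])]
      row <- ((px - 1) %% nr) + 1
      a <- (gs * .km_per_deg) * (gs * .km_per_deg * cos(lats[row] * pi / 180)) * 1e6
      sum((sigma_grid[px] - ref) * a) * 1e-6
    }, 0)
  } else {
    added <- delta * area7 * 1e-6 # mg -> kg
  }
  if (floor_deltas) {
    added[delta < 0] <- 0
    delta <- pmax(delta, 0)
  }
  baseline <- ref * sum(area7) * 1e-6
  structure(list(
    location_id = loc, status = "quantified", reference_sigma = ref,
    sectors = tibble::tibble(band = 1:7, delta_sigma = delta,
                             area_m2 = area7, added_mass_kg = added),
    total_added_kg = sum(added), baseline_mass_kg = baseline,
    percent_increase = 100 * sum(added) / baseline,
    conventions = list(
      deltas = if (use_fitted) "fitted power law at band midpoints" else "observed band means",
      masses = if (pixelwise) "exact pixel sums over valid band pixels" else
        "band-mean delta times band area",
      floor_deltas = floor_deltas,
      baseline = "sector-8 mean Sigma-Chl spread over the area of bands 1-7"
    )
  ), class = "ime_enhancement")
}

#' @export
print.ime_enhancement <- function(x, ...) {
  if (x$status == "excluded") {
    cat("<ime_enhancement>", x$location_id, "- excluded:", x$reason, "\n")
  } else {
    cat("<ime_enhancement>", x$location_id, "- total",
        signif(x$total_added_kg, 4), "kg (+",
        signif(x$percent_increase, 4), "% over offshore baseline)\n")
  }
  invisible(x)
}
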