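# Synthetic ocean-colour scenes with known ground truth: a parametric island
# or atoll, radially growing bathymetry, a power-law nearshore chlorophyll
# enhancement decaying to an offshore baseline, mean-preserving lognormal
# noise and missing pixels.

#' Configuration for a synthetic ocean scene
#'
#' Describes one island/atoll and the chlorophyll field around it. The
#' nearshore enhancement follows `chl(d) = offshore_chl + a * d^b`, where `d`
#' is the distance to the 30-m isobath in degrees-equivalent, `a =
#' ime_amplitude` and `b = ime_exponent` (b < 0 for enhancement decaying
#' offshore).
#'
#' @param grid_spacing Pixel size in degrees (default 0.0417, the
#'   ocean-colour grid).
#' @param domain_extent Width/height of the square domain in degrees.
#' @param island_center `c(lat, lon)` of the island centre.
#' @param geomorphic_type `"island"` or `"atoll"` (metadata; atolls get a
#'   shallow lagoon dimple in the bathymetry).
#' @param reef_radius_30m Radius of the 30-m isobath, degrees.
#' @param bathy_slope Seafloor slope beyond the isobath, degrees (30-300 m
#'   range and beyond).
#' @param offshore_chl Offshore baseline chlorophyll, mg m^-3.
#' @param ime_amplitude Power-law amplitude `a` (mg m^-3 at d = 1 degree).
#' @param ime_exponent Power-law exponent `b` (<= 0 for enhancement).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (mean-preserving); 0 disables noise.
#' @param missing_fraction Fraction of ocean pixels masked as missing.
#' @param k490_offshore Offshore diffuse attenuation, m^-1 (light penetration
#'   depth is its reciprocal).
#' @param elongation East-west stretch factor of the island (1 = circular);
#'   values > 1 produce non-circular isobaths.
#' @param seed Integer seed making the scene reproducible.
#' @return A validated `ime_scene_config` list.
#' @export
scene_config <- function(grid_spacing = 0.0417, domain_extent = 1.0,
                         island_center = c(lat = 0, lon = 0),
                         geomorphic_type = c("island", "atoll"),
                         reef_radius_30m = 0.10, bathy_slope = 10,
                         offshore_chl = 0.1, ime_amplitude = 0.5,
                         ime_exponent = -0.3, noise_cv = 0.1,
                         missing_fraction = 0.02, k490_offshore = 0.04,
                         elongation = 1, seed = 1L) {
  geomorphic_type <- match.arg(geomorphic_type)
  cfg <- list(
    grid_spacing = grid_spacing, domain_extent = domain_extent,
    island_center = c(lat = unname(island_center[1]), lon = unname(island_center[2])),
    geomorphic_type = geomorphic_type, reef_radius_30m = reef_radius_30m,
    bathy_slope = bathy_slope, offshore_chl = offshore_chl,
    ime_amplitude = ime_amplitude, ime_exponent = ime_exponent,
    noise_cv = noise_cv, missing_fraction = missing_fraction,
    k490_offshore = k490_offshore, elongation = elongation,
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  if (cfg$grid_spacing <= 0) stop_ime("grid_spacing must be > 0")
  if (cfg$offshore_chl <= 0) stop_ime("offshore_chl must be > 0")
  if (cfg$k490_offshore <= 0) stop_ime("k490_offshore must be > 0")
  if (cfg$noise_cv < 0) stop_ime("noise_cv must be >= 0")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    stop_ime("missing_fraction must lie in [0, 1)")
  }
  if (cfg$reef_radius_30m <= 0) stop_ime("reef_radius_30m must be > 0")
  if (cfg$bathy_slope <= 0 || cfg$bathy_slope >= 90) {
    stop_ime("bathy_slope must lie in (0, 90) degrees")
  }
  w <- sector_width(cfg$grid_spacing)
  need <- cfg$reef_radius_30m * max(1, cfg$elongation) + 9 * w
  if (cfg$domain_extent / 2 < need) {
    stop_ime("Domain too small: half-extent ", cfg$domain_extent / 2,
             " deg cannot contain 9 sector widths (", 9 * w,
             " deg) offshore of the 30-m isobath (radius ",
             cfg$reef_radius_30m, " deg); need >= ", signif(need, 4), " deg.",
             class = "ime_domain_too_small")
  }
  structure(cfg, class = "ime_scene_config")
}

# Radial bathymetry profile: 30 m exactly at reef_radius, linear in radius on
# the reef flat, then deepening at bathy_slope beyond; atolls get a lagoon.
scene_depth <- function(cfg, r_deg) {
  depth <- matrix(NA_real_, nrow(r_deg), ncol(r_deg))
  inside <- r_deg <= cfg$reef_radius_30m
  depth[inside] <- 30 * r_deg[inside] / cfg$reef_radius_30m
  drop_m_per_deg <- tan(cfg$bathy_slope * pi / 180) * .km_per_deg * 1000
  depth[!inside] <- pmin(6000, 30 + (r_deg[!inside] - cfg$reef_radius_30m) * drop_m_per_deg)
  land <- r_deg < 0.15 * cfg$reef_radius_30m
  if (cfg$geomorphic_type == "atoll") {
    # emergent rim with a shallow enclosed lagoon
    lagoon <- r_deg < 0.6 * cfg$reef_radius_30m & !land
    depth[lagoon] <- pmin(depth[lagoon], 15)
    rim <- r_deg >= 0.78 * cfg$reef_radius_30m & r_deg < 0.95 * cfg$reef_radius_30m
    land <- land | rim
  }
  depth[land] <- NA_real_
  list(depth = depth, land = land)
}

#' Generate a synthetic ocean scene
#'
#' Builds co-registered chlorophyll, k490 and bathymetry grids around a
#' parametric island or atoll. The chlorophyll field is
#' `offshore_chl + ime_amplitude * d^ime_exponent` at every ocean pixel (d =
#' distance to the 30-m isobath in degrees-equivalent, floored at half a
#' pixel so the field stays finite on the contour itself), multiplied by
#' mean-preserving lognormal noise with the configured CV; a random subset of
#' ocean pixels is masked as missing. Identical configurations and seeds give
#' bit-identical scenes.
#'
#' @param config An `ime_scene_config` from [scene_config()].
#' @return An `ime_ocean_scene`: list with `lat`, `lon` axes, `chl`, `k490`,
#'   `depth` matrices, `land_mask`, the `isobath`, the distance field
#'   `dist_deg`, and `truth` (the config).
#' @export
generate_scene <- function(config) {
  cfg <- validate_scene_config(config)
  n <- round(cfg$domain_extent / cfg$grid_spacing)
  offs <- (seq_len(n) - (n + 1) / 2) * cfg$grid_spacing
  lat <- cfg$island_center["lat"] + offs
  lon <- cfg$island_center["lon"] + offs
  clat0 <- cos(cfg$island_center["lat"] * pi / 180)
  r_deg <- sqrt(outer(lat - cfg$island_center["lat"], rep(1, n))^2 +
                outer(rep(1, n), (lon - cfg$island_center["lon"]) * clat0 /
                        cfg$elongation)^2)
  bathy <- scene_depth(cfg, r_deg)
  contour <- extract_isobath(bathy$depth, lat, lon, level = 30)
  dfield <- distance_field(lat, lon, contour)
  d <- pmax(dfield$dist_deg, cfg$grid_spacing / 2)
  chl <- cfg$offshore_chl + cfg$ime_amplitude * d^cfg$ime_exponent
  k490 <- matrix(cfg$k490_offshore, n, n)
  ocean <- !bathy$land
  with_seed(cfg$seed, {
    if (cfg$noise_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$noise_cv^2))
      chl <- chl * exp(rnorm(n * n, -sdlog^2 / 2, sdlog))
      k490 <- k490 * exp(rnorm(n * n, -sdlog^2 / 2, sdlog))
    }
    if (cfg$missing_fraction > 0) {
      miss <- ocean & matrix(runif(n * n) < cfg$missing_fraction, n, n)
      chl[miss] <- NA_real_
      k490[miss] <- NA_real_
    }
  })
  chl[!ocean] <- NA_real_
  k490[!ocean] <- NA_real_
  structure(list(
    lat = as.numeric(lat), lon = as.numeric(lon), chl = chl, k490 = k490,
    depth = bathy$depth, land_mask = bathy$land, isobath = contour,
    dist_deg = dfield$dist_deg, truth = cfg
  ), class = "ime_ocean_scene")
}

#' @export
print.ime_ocean_scene <- function(x, ...) {
  cat("<ime_ocean_scene>", length(x$lat), "x", length(x$lon), "pixels;",
      x$truth$geomorphic_type, "at (", x$truth$island_center["lat"], ",",
      x$truth$island_center["lon"], "); b_true =", x$truth$ime_exponent, "\n")
  invisible(x)
}

#' Default sector set for a scene
#'
#' Convenience wrapper: takes the scene's own isobath distance field and
#' builds the eight bands with the half-pixel-diagonal width, excluding land,
#' inside-isobath and missing-eligibility rules as in [build_sectors()].
#'
#' @param scene An `ime_ocean_scene`.
#' @param location_id Identifier for the sector set.
#' @return An `ime_sector_set`.
#' @export
scene_sectors <- function(scene, location_id = "loc") {
  w <- sector_width(scene$truth$grid_spacing)
  dfield <- structure(list(lat = scene$lat, lon = scene$lon,
                           dist_deg = scene$dist_deg, level = 30),
                      class = "ime_distance_field")
  build_sectors(dfield, w, land_mask = scene$land_mask,
                ocean_mask = !is.na(scene$depth) & scene$depth > 30,
                location_id = location_id)
}
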