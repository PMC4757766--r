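# Brute-force oracles and small fixture builders, kept deliberately naive
# and independent of the package's vectorized implementations.

km_per_deg <- 111.195

# cone island: depth increases linearly with radius, 30-m isobath at 0.3 * R
cone_depth <- function(n = 40, spacing = 0.02, R = 0.3) {
  offs <- (seq_len(n) - (n + 1) / 2) * spacing
  r <- sqrt(outer(offs, rep(1, n))^2 + outer(rep(1, n), offs)^2)
  list(depth = 100 * r / R, lat = offs, lon = offs, R = R)
}

# naive haversine in km (scalar formula, loop-friendly)
hav_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# brute-force minimum distance (degrees-equivalent) from each grid pixel to a
# densified set of contour points
brute_distance_deg <- function(lat, lon, pts) {
  out <- matrix(NA_real_, length(lat), length(lon))
  for (i in seq_along(lat)) for (j in seq_along(lon)) {
    out[i, j] <- min(hav_km(lat[i], lon[j], pts[, 1], pts[, 2])) / km_per_deg
  }
  out
}

# dense circle (lat0-centred, planar degrees with cos(lat0) longitude
# scaling), n vertices
circle_points <- function(R, lat0 = 0, lon0 = 0, n = 1e4) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(lat0 + R * sin(th), lon0 + R * cos(th) / cos(lat0 * pi / 180))
}

# linear interpolation along a polyline's vertices to ~n points
densify_polyline <- function(lat, lon, n = 1e4) {
  t0 <- seq_along(lat)
  t1 <- seq(1, length(lat), length.out = n)
  cbind(approx(t0, lat, xout = t1)$y, approx(t0, lon, xout = t1)$y)
}

# brute-force band membership by per-pixel interval test
brute_membership <- function(dist_deg, w, k, eligible) {
  which(eligible & dist_deg >= k * w & dist_deg < (k + 1) * w)
}

# brute-force per-band mean by explicit loop over member pixels
brute_band_mean <- function(grid, pixels) {
  tot <- 0; n <- 0
  for (p in pixels) {
    v <- grid[p]
    if (!is.na(v)) { tot <- tot + v; n <- n + 1 }
  }
  if (n == 0) NA_real_ else tot / n
}

# brute-force pixel area (m^2) for matrix linear indices
brute_pixel_area <- function(pixels, lat, nrow_grid, spacing) {
  row <- ((pixels - 1) %% nrow_grid) + 1
  (spacing * km_per_deg) * (spacing * km_per_deg * cos(lat[row] * pi / 180)) * 1e6
}

# hierarchical partitioning by full enumeration of predictor orderings
orderings_partition <- function(response, table, predictors) {
  d2_of <- function(terms) {
    fml <- if (length(terms)) stats::reformulate(terms) else ~1
    fit_gamma_glm(response, table, fml)$d2
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  k <- length(predictors)
  indep <- stats::setNames(numeric(k), predictors)
  all_orders <- perms(predictors)
  for (ord in all_orders) {
    for (pos in seq_along(ord)) {
      before <- ord[seq_len(pos - 1)]
      gain <- d2_of(c(before, ord[pos])) - d2_of(before)
      indep[ord[pos]] <- indep[ord[pos]] + gain / length(all_orders)
    }
  }
  indep
}

# small gamma-GLM dataset with independent predictors
make_glm_data <- function(n = 40, seed = 1, beta = c(0.5, 0.6, -0.4, 0.3),
                          shape = 15) {
  withr::with_seed(seed, {
    tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    mu <- exp(beta[1] + beta[2] * tab$x1 + beta[3] * tab$x2 + beta[4] * tab$x3)
    list(table = tab, response = rgamma(n, shape = shape, scale = mu / shape))
  })
}

fast_cfg <- function(...) {
  scene_config(reef_radius_30m = 0.08, domain_extent = 0.8, ...)
}
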