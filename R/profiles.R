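# In-situ profiles: trapezoidal depth integration of fluorometer casts over
# 5-300 m and the cross-shore exponential-decay fit of depth-integrated
# chlorophyll, centred to zero at 30 km.

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Depth-integrate a chlorophyll profile
#'
#' Trapezoidal integration of a fluorometer cast over the upper water column
#' (5-300 m by default). Samples are clipped to the integration bounds with
#' linear interpolation at the endpoints when sampling straddles a bound.
#' Profiles covering less than half of the depth range are rejected.
#'
#' @param profile Data frame with `depth_m` (strictly increasing) and `chl`
#'   (mg m^-3) columns.
#' @param zmin,zmax Integration bounds in metres (default 5 and 300).
#' @return One-row tibble: `chl_int` (mg m^-2), `n_samples`, `coverage`
#'   (fraction of `[zmin, zmax]` spanned by the samples).
#' @export
integrate_profile <- function(profile, zmin = 5, zmax = 300) {
  stopifnot(all(c("depth_m", "chl") %in% names(profile)))
  z <- profile$depth_m
  y <- profile$chl
  ok <- !is.na(z) & !is.na(y)
  z <- z[ok]; y <- y[ok]
  if (length(z) < 2) stop_ime("Profile has fewer than 2 usable samples.")
  if (any(diff(z) <= 0)) {
    stop_ime("Profile depths must be strictly increasing (duplicate or ",
             "unsorted depths).")
  }
  lo <- max(zmin, min(z)); hi <- min(zmax, max(z))
  coverage <- max(0, hi - lo) / (zmax - zmin)
  if (coverage < 0.5) {
    stop_ime("Profile covers only ", round(100 * coverage), "% of the ",
             zmin, "-", zmax, " m range (< 50%): rejected.",
             class = "ime_coverage")
  }
  keep <- z >= lo & z <= hi
  zi <- z[keep]; yi <- y[keep]
  if (lo > min(z) && zi[1] > lo) { # interpolate onto the lower bound
    yi <- c(approx(z, y, xout = lo)$y, yi); zi <- c(lo, zi)
  }
  if (hi < max(z) && zi[length(zi)] < hi) {
    yi <- c(yi, approx(z, y, xout = hi)$y); zi <- c(zi, hi)
  }
  tibble::tibble(chl_int = trapz(zi, yi), n_samples = sum(keep),
                 coverage = coverage)
}

#' Depth-integrate every station of a survey
#'
#' @param survey An `ime_profile_survey` (or a tibble with `distance_km` and
#'   a `profile` list-column).
#' @inheritParams integrate_profile
#' @return Tibble: `distance_km`, `chl_int`, `n_samples`, `coverage`.
#' @export
integrate_survey <- function(survey, zmin = 5, zmax = 300) {
  stations <- if (inherits(survey, "ime_profile_survey")) survey$stations else survey
  dplyr::bind_cols(
    tibble::tibble(distance_km = stations$distance_km),
    dplyr::bind_rows(lapply(stations$profile, integrate_profile,
                            zmin = zmin, zmax = zmax))
  )
}

#' Fit the cross-shore trend in depth-integrated chlorophyll
#'
#' Nonlinear least squares of `chl_int ~ c0 + A * exp(-distance/lambda)` (an
#' exponential decay toward the offshore background). When the nonlinear fit
#' does not converge, a log-linear fallback `log(chl_int) ~ distance` is
#' used with a logged notice. Per-station anomalies `delta_chl_int` are
#' centred by subtracting the fitted value at 30 km, so the fitted curve is
#' exactly zero there. The shoreward increase is significant when the
#' amplitude `A` is positive with Wald p < 0.05.
#'
#' @param integrations Tibble from [integrate_survey()] (`distance_km`,
#'   `chl_int`).
#' @param center_km Centring distance (default 30 km, the offshore extent of
#'   the satellite analysis).
#' @return An `ime_transect_fit`: list with `params` (`c0`, `A`,
#'   `lambda_km`), `p`, `significant`, `stations` (with `delta_chl_int`),
#'   `form`, `fallback`.
#' @export
fit_transect <- function(integrations, center_km = 30) {
  x <- integrations$distance_km
  y <- integrations$chl_int
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) {
    stop_ime("Transect fit needs >= 4 stations; got ", length(x), ".",
             class = "ime_insufficient_data")
  }
  if (diff(range(x)) < 10) {
    stop_ime("Stations must span >= 10 km; got ", signif(diff(range(x)), 3),
             " km.", class = "ime_insufficient_data")
  }
  dat <- data.frame(x = x, y = y)
  start <- list(c0 = min(y), A = max(max(y) - min(y), 1e-8),
                lambda = max(diff(range(x)) / 3, 1))
  fit <- tryCatch(
    nls(y ~ c0 + A * exp(-x / lambda), data = dat, start = start,
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = identity
  )
  fallback <- FALSE
  if (inherits(fit, "error")) {
    # flat or ill-conditioned transects: log-linear decay as a fallback
    fallback <- TRUE
    lf <- lm(log(pmax(y, 1e-12)) ~ x)
    slope <- unname(coef(lf)[2])
    params <- c(c0 = 0, A = exp(unname(coef(lf)[1])),
                lambda_km = if (slope < 0) -1 / slope else Inf)
    p <- summary(lf)$coefficients[2, 4]
    sig <- slope < 0 && p < 0.05
    fitted_at <- function(d) params[["A"]] * exp(-d / params[["lambda_km"]])
  } else {
    cf <- summary(fit)$coefficients
    params <- c(c0 = unname(cf["c0", 1]), A = unname(cf["A", 1]),
                lambda_km = unname(cf["lambda", 1]))
    p <- unname(cf["A", 4])
    sig <- params[["A"]] > 0 && p < 0.05
    fitted_at <- function(d) {
      params[["c0"]] + params[["A"]] * exp(-d / params[["lambda_km"]])
    }
  }
  ref <- fitted_at(center_km)
  stations <- tibble::tibble(
    distance_km = x, chl_int = y,
    fitted = vapply(x, fitted_at, 0),
    delta_chl_int = y - ref,
    delta_fitted = vapply(x, fitted_at, 0) - ref
  )
  structure(list(
    params = params, p = p, significant = sig, stations = stations,
    center_km = center_km, reference = ref,
    form = "chl_int ~ c0 + A * exp(-distance/lambda)",
    fallback = fallback, fitted_at = fitted_at
  ), class = "ime_transect_fit")
}

#' @export
print.ime_transect_fit <- function(x, ...) {
  cat("<ime_transect_fit> c0 =", signif(x$params[["c0"]], 4),
      ", A =", signif(x$params[["A"]], 4),
      ", lambda =", signif(x$params[["lambda_km"]], 4), "km; p =",
      signif(x$p, 3), if (x$significant) "(significant shoreward increase)"
      else "(not significant)",
      if (x$fallback) "[log-linear fallback]" else "", "\n")
  invisible(x)
}
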