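# Gradient analysis: sector-mean chlorophyll, power-law (log-log OLS) fits of
# chlorophyll vs distance to the 30-m isobath, the IME presence gate, and the
# ANCOVA comparison of slopes among locations.

#' Sector-mean values
#'
#' Averages a co-registered grid over each band's member pixels (unweighted
#' arithmetic mean; missing pixels are skipped and `n_pixels` counts only the
#' pixels actually averaged).
#'
#' @param value_grid Matrix co-registered with the sector set's grid.
#' @param sector_set An `ime_sector_set`.
#' @return A tibble (one row per band): `location_id`, `band`, `inner`,
#'   `outer`, `mid_deg`, `mid_km`, `mean_value`, `n_pixels`, `empty`.
#' @export
sector_means <- function(value_grid, sector_set) {
  stopifnot(inherits(sector_set, "ime_sector_set"))
  if (!all(dim(value_grid) == sector_set$dim)) {
    stop_ime("value_grid dimensions ", paste(dim(value_grid), collapse = "x"),
             " do not match the sector set's grid ",
             paste(sector_set$dim, collapse = "x"), ".")
  }
  b <- sector_set$bands
  vals <- lapply(b$pixels, function(p) value_grid[p])
  tibble::tibble(
    location_id = sector_set$location_id,
    band = b$band, inner = b$inner, outer = b$outer,
    mid_deg = (b$inner + b$outer) / 2,
    mid_km = deg_to_km((b$inner + b$outer) / 2),
    mean_value = vapply(vals, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, 0),
    n_pixels = vapply(vals, function(v) sum(!is.na(v)), 0L)
  ) |>
    dplyr::mutate(empty = .data$n_pixels == 0L)
}

#' Fit the chlorophyll-distance power law
#'
#' Ordinary least squares of `log(mean_value)` on `log(mid_deg)`: the slope
#' `b` is the IME index (more negative = stronger nearshore enhancement) and
#' `a = exp(intercept)` the power-law coefficient. `b`, its p-value and r^2
#' are invariant to the log base and to rescaling of either axis; `a` is not.
#'
#' @param series Sector-series tibble from [sector_means()].
#' @param distance_col Column used as the fit abscissa (default `"mid_deg"`,
#'   the band midpoint in degrees).
#' @return An `ime_gradient_fit`: list with `a`, `b`, `se_b`, `p_slope`,
#'   `r2`, `n`, the underlying `lm`, and metadata (`abscissa`, `log_base`).
#' @export
fit_gradient <- function(series, distance_col = "mid_deg") {
  use <- series[!series$empty & !is.na(series$mean_value), ]
  if (nrow(use) < 3) {
    stop_ime("Need >= 3 non-empty bands to fit a gradient; got ", nrow(use), ".",
             class = "ime_insufficient_data")
  }
  if (any(use$mean_value <= 0)) {
    bad <- use$band[use$mean_value <= 0]
    stop_ime("Non-positive sector mean in band ", paste(bad, collapse = ", "),
             ": log-log fit undefined.", class = "ime_nonpositive_mean")
  }
  df <- data.frame(logy = log(use$mean_value), logx = log(use[[distance_col]]))
  fit <- lm(logy ~ logx, data = df)
  sm <- suppressWarnings(summary(fit))
  b <- unname(coef(fit)[2])
  p_slope <- unname(sm$coefficients[2, 4])
  # numerically exact series (zero residual variance): an exactly constant
  # series carries no evidence of a gradient, an exact power law full evidence
  if (!is.finite(p_slope) || sm$sigma < 1e-10 * max(1, abs(mean(df$logy)))) {
    p_slope <- if (abs(b) < 1e-8) 1 else 0
  }
  structure(list(
    location_id = use$location_id[1],
    a = exp(unname(coef(fit)[1])), b = b,
    se_b = unname(sm$coefficients[2, 2]),
    p_slope = p_slope,
    r2 = sm$r.squared, n = nrow(use), lm = fit,
    abscissa = paste0("band midpoint (", distance_col, ")"),
    log_base = "natural", data = use
  ), class = "ime_gradient_fit")
}

#' @export
print.ime_gradient_fit <- function(x, ...) {
  cat("<ime_gradient_fit>", x$location_id, ": b =", signif(x$b, 4),
      "(p =", signif(x$p_slope, 3), ", r2 =", signif(x$r2, 3),
      ", n =", x$n, "bands)\n")
  invisible(x)
}

#' Classify IME presence
#'
#' A location displays an Island Mass Effect when chlorophyll increases
#' significantly toward shore: slope `b < 0` with `p < alpha`.
#'
#' @param fit An `ime_gradient_fit`.
#' @param alpha Significance level (default 0.05).
#' @return `"enhanced"` or `"not_enhanced"`.
#' @export
classify_ime <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "ime_gradient_fit"))
  if (fit$b < 0 && fit$p_slope < alpha) "enhanced" else "not_enhanced"
}

#' Compare gradient slopes among locations (ANCOVA)
#'
#' Pools the per-band log-log data of several locations and tests for
#' heterogeneity of the chlorophyll-distance slopes via the
#' `log(d) : location` interaction of `lm(log(mean) ~ log(d) * location)`.
#'
#' @param series_list List of sector-series tibbles (or one tibble holding
#'   several `location_id`s).
#' @return An `ime_ancova`: list with `F`, `df_num`, `df_den`, `p`, the
#'   per-location `slopes` tibble and the pooled `lm`.
#' @export
compare_slopes <- function(series_list) {
  if (is.data.frame(series_list)) series_list <- list(series_list)
  pooled <- dplyr::bind_rows(series_list)
  pooled <- pooled[!pooled$empty & !is.na(pooled$mean_value), ]
  if (length(unique(pooled$location_id)) < 2) {
    stop_ime("ANCOVA needs >= 2 locations.", class = "ime_insufficient_data")
  }
  if (any(pooled$mean_value <= 0)) stop_ime("Non-positive sector means.")
  df <- data.frame(logy = log(pooled$mean_value),
                   logx = log(pooled$mid_deg),
                   location = factor(pooled$location_id))
  fit <- lm(logy ~ logx * location, data = df)
  av <- suppressWarnings(anova(fit))
  row <- which(rownames(av) == "logx:location")
  Fval <- av$`F value`[row]
  pval <- av$`Pr(>F)`[row]
  # exactly collinear data (e.g. noise-free identical power laws): the
  # interaction sum of squares is roundoff noise -> no heterogeneity
  if (!is.finite(Fval) || av$`Sum Sq`[row] <= 1e-16 * max(av$`Sum Sq`)) {
    Fval <- 0; pval <- 1
  }
  slopes <- df |>
    dplyr::group_by(.data$location) |>
    dplyr::group_modify(~ {
      m <- lm(logy ~ logx, data = .x)
      tibble::tibble(b = unname(coef(m)[2]))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(location_id = "location")
  structure(list(
    F = Fval, df_num = av$Df[row],
    df_den = av$Df[nrow(av)], p = pval,
    slopes = slopes, lm = fit
  ), class = "ime_ancova")
}

#' @export
print.ime_ancova <- function(x, ...) {
  cat("<ime_ancova> slope heterogeneity: F(", x$df_num, ",", x$df_den, ") =",
      signif(x$F, 4), ", p =", signif(x$p, 3), "\n")
  invisible(x)
}
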