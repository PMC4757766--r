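# broom-style tidiers so every fitted object drops into a tidyverse
# workflow: tidy() gives one row per estimated quantity, glance() one row of
# fit-level summaries.

#' @exportS3Method generics::tidy
tidy.ime_gradient_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log_a", "b"),
    estimate = c(log(x$a), x$b),
    std.error = c(summary(x$lm)$coefficients[1, 2], x$se_b),
    p.value = c(summary(x$lm)$coefficients[1, 4], x$p_slope)
  )
}

#' @exportS3Method generics::glance
glance.ime_gradient_fit <- function(x, ...) {
  tibble::tibble(location_id = x$location_id, a = x$a, b = x$b,
                 p.value = x$p_slope, r.squared = x$r2, nobs = x$n)
}

#' @exportS3Method generics::tidy
tidy.ime_ancova <- function(x, ...) {
  x$slopes
}

#' @exportS3Method generics::glance
glance.ime_ancova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df = x$df_num, df.residual = x$df_den,
                 p.value = x$p)
}

#' @exportS3Method generics::tidy
tidy.ime_glm <- function(x, ...) {
  cf <- summary(x)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4])
}

#' @exportS3Method generics::glance
glance.ime_glm <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, null.deviance = x$null.deviance,
                 d.squared = x$d2, AICc = x$aicc, nobs = stats::nobs(x),
                 k = x$k)
}

#' @exportS3Method generics::tidy
tidy.ime_ranking <- function(x, ...) {
  x$models
}

#' @exportS3Method generics::glance
glance.ime_ranking <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$models),
                 n_candidates = sum(x$models$candidate),
                 best_formula = x$models$formula[1],
                 best_aicc = x$models$aicc[1])
}

#' @exportS3Method generics::tidy
tidy.ime_partition <- function(x, ...) {
  x$contributions
}

#' @exportS3Method generics::glance
glance.ime_partition <- function(x, ...) {
  tibble::tibble(total = x$total, metric = x$metric,
                 n_predictors = nrow(x$contributions))
}

#' @exportS3Method generics::tidy
tidy.ime_transect_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @exportS3Method generics::glance
glance.ime_transect_fit <- function(x, ...) {
  tibble::tibble(p.value = x$p, significant = x$significant,
                 fallback = x$fallback, nobs = nrow(x$stations))
}

#' @exportS3Method generics::tidy
tidy.ime_enhancement <- function(x, ...) {
  if (x$status == "excluded") {
    return(tibble::tibble(band = integer(), delta_sigma = numeric(),
                          area_m2 = numeric(), added_mass_kg = numeric()))
  }
  x$sectors
}

#' @exportS3Method generics::glance
glance.ime_enhancement <- function(x, ...) {
  if (x$status == "excluded") {
    return(tibble::tibble(location_id = x$location_id, status = x$status,
                          total_added_kg = NA_real_,
                          percent_increase = NA_real_))
  }
  tibble::tibble(location_id = x$location_id, status = x$status,
                 reference_sigma = x$reference_sigma,
                 total_added_kg = x$total_added_kg,
                 percent_increase = x$percent_increase)
}

#' @exportS3Method generics::tidy
tidy.ime_vif_report <- function(x, ...) {
  dplyr::select(x$iterations, "step", "removed", "vif")
}
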