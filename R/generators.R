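# Synthetic predictor tables (with gamma-distributed IME-strength responses
# from a known log-link linear predictor) and synthetic ship-based
# fluorometer surveys with a deep chlorophyll maximum.

#' Ground truth for the synthetic driver model
#'
#' Defines the data-generating model for IME strength: responses |b| are
#' gamma-distributed with mean `exp(X beta)` where the design X comes from
#' `formula` applied to a generated predictor table, and a shape parameter
#' fixed across locations (the GLM assumption). The default truth mirrors
#' the field's expectation: atolls and populated locations have stronger
#' enhancement, gentler bathymetric slopes and larger reefs strengthen it,
#' and reef area interacts with geomorphic type.
#'
#' @param formula RHS formula over the generated predictor columns.
#' @param coefficients Named vector on the log-link scale; names must match
#'   `colnames(model.matrix(formula, table))`.
#' @param gamma_shape Gamma shape (> 0); response CV is `1/sqrt(shape)`.
#' @param n_locations Number of locations (>= number of coefficients + 2).
#' @return An `ime_driver_truth` list.
#' @export
driver_truth <- function(
    formula = ~ geomorphic_type + reef_area + bathy_slope +
      population_status + reef_area:geomorphic_type,
    coefficients = c(
      "(Intercept)" = -1.4,
      "geomorphic_typeisland" = -0.8,
      "reef_area" = 0.0012,
      "bathy_slope" = -0.045,
      "population_statuspopulated" = 0.7,
      "geomorphic_typeisland:reef_area" = 0.0015
    ),
    gamma_shape = 20, n_locations = 28) {
  if (gamma_shape <= 0) stop_ime("gamma_shape must be > 0")
  if (n_locations < length(coefficients) + 2) {
    stop_ime("n_locations must be >= number of coefficients + 2")
  }
  structure(list(formula = formula, coefficients = coefficients,
                 gamma_shape = gamma_shape, n_locations = n_locations),
            class = "ime_driver_truth")
}

#' Generate a synthetic predictor table with known IME responses
#'
#' Draws plausible biogeophysical predictor marginals for `n_locations`
#' islands/atolls (reef and land area log-uniform, balanced geomorphic
#' types, no populated atolls -- reproducing the real-world confounding that
#' removes the type:population interaction) and gamma-distributed responses
#' |b| with mean `exp(X beta)` from the truth's coefficients.
#'
#' @param truth An `ime_driver_truth`.
#' @param seed Integer seed.
#' @return List with `table` (tibble of location predictors), `response`
#'   (|b| per location) and `truth`.
#' @export
generate_predictor_table <- function(truth = driver_truth(), seed = 1L) {
  stopifnot(inherits(truth, "ime_driver_truth"))
  n <- truth$n_locations
  with_seed(seed, {
    n_atoll <- floor(n / 2)
    type <- factor(sample(c(rep("atoll", n_atoll), rep("island", n - n_atoll))),
                   levels = c("atoll", "island"))
    pop <- ifelse(type == "island" & runif(n) < 0.5, "populated", "unpopulated")
    table <- tibble::tibble(
      location_id = sprintf("LOC%02d", seq_len(n)),
      latitude = runif(n, -20, 25),
      geomorphic_type = type,
      population_status = factor(pop, levels = c("unpopulated", "populated")),
      reef_area = 10^runif(n, 0.5, 3),
      land_area = ifelse(type == "atoll", 10^runif(n, -1, 1), 10^runif(n, 0, 2.5)),
      bathy_slope = runif(n, 1, 30),
      elevation = ifelse(type == "atoll", runif(n, 2, 10), 10^runif(n, 1, 3.2)),
      sst_mean = runif(n, 24, 29),
      sst_sd = runif(n, 0.4, 1.6),
      precip_mean = runif(n, 500, 3500),
      precip_sd = runif(n, 50, 400),
      current_mean = runif(n, 0.05, 0.6),
      current_sd = runif(n, 0.02, 0.2)
    )
    X <- model.matrix(truth$formula, data = table)
    missing <- setdiff(names(truth$coefficients), colnames(X))
    if (length(missing)) {
      stop_ime("Truth coefficient(s) ", paste(missing, collapse = ", "),
               " name predictors not generated by the table (design columns: ",
               paste(colnames(X), collapse = ", "), ").")
    }
    eta <- as.numeric(X[, names(truth$coefficients), drop = FALSE] %*%
                        truth$coefficients)
    mu <- exp(eta)
    response <- rgamma(n, shape = truth$gamma_shape,
                       scale = mu / truth$gamma_shape)
    list(table = table, response = response, truth = truth, mu = mu)
  })
}

#' Generate a synthetic ship-based fluorometer survey
#'
#' Stations span 2-30 km from shore; each vertical profile is a Gaussian
#' deep-chlorophyll-maximum whose analytic depth integral over 5-300 m
#' equals `offset + amplitude * exp(-distance/lambda_km)` (an exponential
#' decay toward the offshore background), before multiplicative lognormal
#' sample noise.
#'
#' @param offset Offshore background depth-integrated chlorophyll, mg m^-2.
#' @param amplitude Nearshore excess at distance 0, mg m^-2; 0 gives a flat
#'   transect.
#' @param lambda_km Decay length scale of the excess, km.
#' @param dcm_depth Depth of the chlorophyll maximum, m (in (5, 300)).
#' @param dcm_width Gaussian width of the maximum, m.
#' @param n_stations Number of stations (default 10).
#' @param depth_step Vertical sampling interval, m (default 2).
#' @param noise_cv CV of multiplicative lognormal noise per sample.
#' @param location_id,survey_year Metadata.
#' @param seed Integer seed.
#' @return An `ime_profile_survey`: list with `stations` (tibble
#'   `distance_km`, `profile` list-column of tibbles `depth_m`, `chl`),
#'   metadata, and `truth` (the arguments, including the analytic
#'   station-integral function).
#' @export
generate_profile_survey <- function(offset = 20, amplitude = 50,
                                    lambda_km = 8, dcm_depth = 80,
                                    dcm_width = 30, n_stations = 10,
                                    depth_step = 2, noise_cv = 0.05,
                                    location_id = "loc", survey_year = 2010,
                                    seed = 1L) {
  if (dcm_depth <= 5 || dcm_depth >= 300) {
    stop_ime("dcm_depth must lie in (5, 300) m.")
  }
  if (dcm_width <= 0) stop_ime("dcm_width must be > 0.")
  distances <- seq(2, 30, length.out = n_stations)
  # analytic integral over [5, 300] of exp(-(z - mu)^2 / (2 w^2))
  gauss_norm <- dcm_width * sqrt(2 * pi) *
    (pnorm((300 - dcm_depth) / dcm_width) - pnorm((5 - dcm_depth) / dcm_width))
  target <- function(x) offset + amplitude * exp(-x / lambda_km)
  depths <- seq(0, 300, by = depth_step)
  with_seed(seed, {
    profiles <- lapply(distances, function(x) {
      peak <- target(x) / gauss_norm
      chl <- peak * exp(-(depths - dcm_depth)^2 / (2 * dcm_width^2))
      if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        chl <- chl * exp(rnorm(length(chl), -sdlog^2 / 2, sdlog))
      }
      tibble::tibble(depth_m = depths, chl = chl)
    })
    structure(list(
      location_id = location_id, survey_year = survey_year,
      stations = tibble::tibble(distance_km = distances, profile = profiles),
      truth = list(offset = offset, amplitude = amplitude,
                   lambda_km = lambda_km, dcm_depth = dcm_depth,
                   dcm_width = dcm_width, noise_cv = noise_cv,
                   integral_fn = target)
    ), class = "ime_profile_survey")
  })
}

#' @export
print.ime_profile_survey <- function(x, ...) {
  cat("<ime_profile_survey>", x$location_id, x$survey_year, "-",
      nrow(x$stations), "stations,",
      signif(min(x$stations$distance_km), 3), "-",
      signif(max(x$stations$distance_km), 3), "km from shore\n")
  invisible(x)
}
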