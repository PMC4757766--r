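# Pipeline orchestration: synthetic universe -> sectors -> gradients ->
# standing-stock enhancement -> driver model -> report; plus deterministic
# fixture bundles for multi-island geometry cases.

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

reef_radius_from_area <- function(reef_area_km2, lo = 0.06, hi = 0.16) {
  r <- km_to_deg(sqrt(reef_area_km2 / pi))
  pmin(hi, pmax(lo, r))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. The synthetic universe
#' is defined by a [driver_truth()]: each location gets a scene whose true
#' gradient exponent is minus its gamma-drawn IME strength, with geomorphic
#' type, reef area (mapped to the 30-m isobath radius) and bathymetric slope
#' taken from the generated predictor table.
#'
#' @param truth An `ime_driver_truth` for the synthetic universe.
#' @param grid_spacing,domain_extent,offshore_chl,ime_amplitude,noise_cv,missing_fraction,k490_offshore
#'   Scene parameters shared by all locations (see [scene_config()]).
#' @param alpha Significance level for the IME gate.
#' @param vif_threshold VIF pruning threshold.
#' @param selection_predictors Main effects entering all-subsets selection
#'   (at most 8).
#' @param partition_predictors Main effects entering hierarchical
#'   partitioning (at most 6).
#' @param interactions Include two-way interactions in selection.
#' @param floor_deltas,use_fitted Standing-stock switches (see
#'   [enhancement()]).
#' @param seed Master seed; all per-location seeds derive from it.
#' @param output_dir Optional directory for stage outputs (CSV/JSON).
#' @return An `ime_run_config` list.
#' @export
pipeline_config <- function(truth = driver_truth(),
                            grid_spacing = 0.0417, domain_extent = 1.0,
                            offshore_chl = 0.1, ime_amplitude = 0.5,
                            noise_cv = 0.1, missing_fraction = 0.02,
                            k490_offshore = 0.04, alpha = 0.05,
                            vif_threshold = 3,
                            selection_predictors = c(
                              "geomorphic_type", "reef_area", "bathy_slope",
                              "population_status", "current_mean"),
                            partition_predictors = c(
                              "geomorphic_type", "reef_area", "bathy_slope",
                              "population_status"),
                            interactions = TRUE,
                            floor_deltas = FALSE, use_fitted = FALSE,
                            seed = 1L, output_dir = NULL) {
  structure(as.list(environment()), class = "ime_run_config")
}

#' Run the full IME analysis pipeline
#'
#' Generates the synthetic universe from the configured driver truth, then
#' for every location: builds the sector bands off the 30-m isobath, fits
#' the chlorophyll-distance power law, classifies IME presence, computes the
#' depth-integrated standing-stock enhancement, and finally models |b| of
#' the enhanced locations against the biogeophysical predictors (VIF
#' pruning, AICc all-subsets selection with interactions, hierarchical
#' partitioning). Deterministic for a fixed config and seed.
#'
#' @param config An `ime_run_config` from [pipeline_config()].
#' @return An `ime_run_report`: list with `gradients` (per-location tibble),
#'   `n_locations`, `n_enhanced`, `pct_enhanced`, `ancova`, `enhancements`
#'   tibble, `combined_total_kg`, `combined_percent`, `vif`, `ranking`,
#'   `best_fit`, `partition`, `predictor_table` and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ime_run_config"))
  gen <- generate_predictor_table(config$truth, seed = config$seed)
  tab <- gen$table
  n <- nrow(tab)
  grad_rows <- vector("list", n)
  chl_series <- vector("list", n)
  enh <- vector("list", n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- scene_config(
      grid_spacing = config$grid_spacing,
      domain_extent = config$domain_extent,
      island_center = c(lat = tab$latitude[i], lon = 0),
      geomorphic_type = as.character(tab$geomorphic_type[i]),
      reef_radius_30m = reef_radius_from_area(tab$reef_area[i]),
      bathy_slope = tab$bathy_slope[i],
      offshore_chl = config$offshore_chl,
      ime_amplitude = config$ime_amplitude,
      ime_exponent = -gen$response[i],
      noise_cv = config$noise_cv,
      missing_fraction = config$missing_fraction,
      k490_offshore = config$k490_offshore,
      seed = derive_seed(config$seed, i)
    )
    loc <- tab$location_id[i]
    res <- tryCatch({
      scene <- generate_scene(cfg)
      sectors <- scene_sectors(scene, location_id = loc)
      series <- sector_means(scene$chl, sectors)
      fit <- fit_gradient(series)
      stock <- depth_integrated_chl(scene)
      sig_series <- sector_means(stock$sigma_chl, sectors)
      sig_fit <- fit_gradient(sig_series)
      areas <- sector_area(sectors)
      list(series = series, fit = fit,
           enh = enhancement(sig_series, areas, sig_fit,
                             alpha = config$alpha,
                             floor_deltas = config$floor_deltas,
                             use_fitted = config$use_fitted,
                             sigma_grid = stock$sigma_chl,
                             sector_set = sectors))
    }, error = function(e) {
      stop_ime("Pipeline stage failed for location ", loc, ": ",
               conditionMessage(e))
    })
    chl_series[[i]] <- res$series
    fits[[i]] <- res$fit
    enh[[i]] <- res$enh
    grad_rows[[i]] <- tibble::tibble(
      location_id = loc, b_true = -gen$response[i],
      a = res$fit$a, b = res$fit$b, p = res$fit$p_slope, r2 = res$fit$r2,
      classification = classify_ime(res$fit, config$alpha)
    )
  }
  gradients <- dplyr::bind_rows(grad_rows)
  n_enh <- sum(gradients$classification == "enhanced")
  anc <- if (n >= 2) compare_slopes(chl_series) else NULL

  quant <- purrr::keep(enh, ~ .x$status == "quantified")
  enh_tbl <- dplyr::bind_rows(
    tibble::tibble(location_id = character(), reference_sigma = numeric(),
                   total_added_kg = numeric(), baseline_mass_kg = numeric(),
                   percent_increase = numeric()),
    purrr::map_dfr(quant, ~ tibble::tibble(
      location_id = .x$location_id, reference_sigma = .x$reference_sigma,
      total_added_kg = .x$total_added_kg,
      baseline_mass_kg = .x$baseline_mass_kg,
      percent_increase = .x$percent_increase
    )))
  combined_total <- sum(enh_tbl$total_added_kg)
  combined_pct <- if (nrow(enh_tbl)) {
    100 * combined_total / sum(enh_tbl$baseline_mass_kg)
  } else NA_real_

  driver_notice <- NULL
  vif <- ranking <- best_fit <- part <- NULL
  keep <- gradients$classification == "enhanced"
  resp <- abs(gradients$b[keep])
  dtab <- tab[keep, ]
  min_n <- length(config$selection_predictors) + 3
  if (sum(keep) < min_n) {
    driver_notice <- paste0(
      "Driver model under-determined: only ", sum(keep),
      " enhanced locations for ", length(config$selection_predictors),
      " candidate predictors; model stage skipped.")
  } else {
    all_preds <- c("latitude", "geomorphic_type", "population_status",
                   "reef_area", "land_area", "bathy_slope", "elevation",
                   "sst_mean", "sst_sd", "precip_mean", "precip_sd",
                   "current_mean", "current_sd")
    vif <- if (nrow(dtab) > length(all_preds) + 1) {
      vif_prune(dtab, all_preds, threshold = config$vif_threshold,
                keep = config$selection_predictors)
    } # else too few locations for the full-set VIF; selection set is forced
    ranking <- all_subsets_selection(resp, dtab, config$selection_predictors,
                                     interactions = config$interactions)
    best_fit <- ranking$best_fit
    part <- hierarchical_partition(resp, dtab, config$partition_predictors)
  }

  report <- structure(list(
    gradients = gradients, n_locations = n, n_enhanced = n_enh,
    pct_enhanced = 100 * n_enh / n, ancova = anc,
    enhancements = enh_tbl, enhancement_details = enh,
    combined_total_kg = combined_total, combined_percent = combined_pct,
    vif = vif, ranking = ranking, best_fit = best_fit, partition = part,
    driver_notice = driver_notice, predictor_table = tab,
    response = gen$response,
    provenance = list(config = config, seed = config$seed,
                      package_version = as.character(utils::packageVersion("imeffect")))
  ), class = "ime_run_report")
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.ime_run_report <- function(x, ...) {
  cat("<ime_run_report>\n")
  cat(sprintf("  locations enhanced: %d / %d (%.1f%%)\n",
              x$n_enhanced, x$n_locations, x$pct_enhanced))
  if (!is.null(x$ancova)) {
    cat(sprintf("  slope heterogeneity: F(%d,%d) = %.2f, p = %.3g\n",
                x$ancova$df_num, x$ancova$df_den, x$ancova$F, x$ancova$p))
  }
  if (nrow(x$enhancements)) {
    cat(sprintf("  standing-stock enhancement: %.3g kg combined (+%.1f%%) over %d locations\n",
                x$combined_total_kg, x$combined_percent, nrow(x$enhancements)))
  }
  if (!is.null(x$driver_notice)) {
    cat(" ", x$driver_notice, "\n")
  } else if (!is.null(x$best_fit)) {
    cat("  best driver model:", deparse1(stats::formula(x$best_fit)[-2]),
        sprintf("(D2 = %.2f, AICc = %.1f)\n", x$best_fit$d2, x$best_fit$aicc))
    if (!is.null(x$partition)) {
      pc <- x$partition$contributions
      cat("  partition:", paste(sprintf("%s %.0f%%", pc$predictor, pc$percent),
                                collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Write the stage outputs of a run report
#'
#' Writes per-location gradient fits and enhancements as CSV, the model
#' ranking and partition as CSV, and a JSON report (counts, combined totals,
#' conventions, config echo) sufficient to resume downstream analysis
#' without recomputation.
#'
#' @param report An `ime_run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$gradients, file.path(dir, "gradients.csv"))
  if (nrow(report$enhancements)) {
    readr::write_csv(report$enhancements, file.path(dir, "enhancements.csv"))
  }
  if (!is.null(report$ranking)) {
    readr::write_csv(dplyr::select(report$ranking$models, -dplyr::any_of("fit")),
                     file.path(dir, "model_ranking.csv"))
  }
  if (!is.null(report$partition)) {
    readr::write_csv(report$partition$contributions,
                     file.path(dir, "partition.csv"))
  }
  cfg <- report$provenance$config
  cfg$truth <- list(coefficients = as.list(cfg$truth$coefficients),
                    formula = deparse1(cfg$truth$formula),
                    gamma_shape = cfg$truth$gamma_shape,
                    n_locations = cfg$truth$n_locations)
  summary <- list(
    n_locations = report$n_locations, n_enhanced = report$n_enhanced,
    pct_enhanced = report$pct_enhanced,
    combined_total_kg = report$combined_total_kg,
    combined_percent = report$combined_percent,
    ancova = if (!is.null(report$ancova)) report$ancova[c("F", "df_num", "df_den", "p")],
    best_formula = if (!is.null(report$best_fit))
      deparse1(stats::formula(report$best_fit)[-2]),
    driver_notice = report$driver_notice,
    conventions = list(
      distance = "great-circle km / 111.195 per degree, cos(lat) on longitude",
      deltas = "observed band means vs sector-8 reference",
      percent_baseline = "sector-8 mean Sigma-Chl over area of bands 1-7"
    ),
    config = cfg[setdiff(names(cfg), "output_dir")],
    package_version = report$provenance$package_version
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Synthetic scene with several islands on one grid
#'
#' Overlays multiple parametric islands on a shared grid: the chlorophyll
#' field is the offshore baseline plus the sum of each island's power-law
#' enhancement, the combined bathymetry is the pixelwise minimum (shallowest)
#' of the per-island bathymetries, and each island keeps its own depth grid
#' so per-location sectors and complex merging can be exercised.
#'
#' @param centers List of `c(lat, lon)` island centres.
#' @param reef_radii Numeric vector of 30-m isobath radii (degrees).
#' @param amplitudes,exponents Per-island power-law parameters.
#' @param bathy_slope,grid_spacing,domain_extent,offshore_chl,noise_cv,missing_fraction,k490_offshore,seed
#'   As in [scene_config()]; the domain is centred on the mean of `centers`.
#' @return An `ime_multi_scene`: list with shared axes and `chl`, `k490`
#'   grids, combined `depth`, per-island `depth_list`, `land_mask`, and the
#'   per-island `sector_sets` built off each island's own isobath.
#' @export
multi_island_scene <- function(centers, reef_radii,
                               amplitudes = 0.5, exponents = -0.3,
                               bathy_slope = 10, grid_spacing = 0.0417,
                               domain_extent = 1.2, offshore_chl = 0.1,
                               noise_cv = 0, missing_fraction = 0,
                               k490_offshore = 0.04, seed = 1L) {
  m <- length(centers)
  amplitudes <- rep_len(amplitudes, m)
  exponents <- rep_len(exponents, m)
  reef_radii <- rep_len(reef_radii, m)
  ctr <- colMeans(do.call(rbind, centers))
  n <- round(domain_extent / grid_spacing)
  offs <- (seq_len(n) - (n + 1) / 2) * grid_spacing
  lat <- ctr[1] + offs
  lon <- ctr[2] + offs
  depth_list <- list()
  land <- matrix(FALSE, n, n)
  chl <- matrix(offshore_chl, n, n)
  sector_sets <- list()
  w <- sector_width(grid_spacing)
  for (i in seq_len(m)) {
    cfg <- list(grid_spacing = grid_spacing, reef_radius_30m = reef_radii[i],
                bathy_slope = bathy_slope, geomorphic_type = "island",
                elongation = 1)
    clat0 <- cos(centers[[i]][1] * pi / 180)
    r <- sqrt(outer(lat - centers[[i]][1], rep(1, n))^2 +
              outer(rep(1, n), (lon - centers[[i]][2]) * clat0)^2)
    b <- scene_depth(cfg, r)
    depth_list[[i]] <- b$depth
    land <- land | b$land
    contour <- extract_isobath(b$depth, lat, lon, level = 30)
    dfield <- distance_field(lat, lon, contour)
    d <- pmax(dfield$dist_deg, grid_spacing / 2)
    chl <- chl + amplitudes[i] * d^exponents[i]
    sector_sets[[i]] <- list(contour = contour, dfield = dfield)
  }
  names(depth_list) <- names(centers) %||%
    paste0("island", seq_len(m))
  depth <- Reduce(function(a, b) {
    out <- pmin(a, b, na.rm = TRUE); out[is.na(a) & is.na(b)] <- NA; out
  }, depth_list)
  k490 <- matrix(k490_offshore, n, n)
  ocean <- !land
  with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      chl <- chl * exp(rnorm(n * n, -sdlog^2 / 2, sdlog))
      k490 <- k490 * exp(rnorm(n * n, -sdlog^2 / 2, sdlog))
    }
    if (missing_fraction > 0) {
      miss <- ocean & matrix(runif(n * n) < missing_fraction, n, n)
      chl[miss] <- NA_real_; k490[miss] <- NA_real_
    }
  })
  chl[land] <- NA_real_; k490[land] <- NA_real_
  sets <- lapply(seq_len(m), function(i) {
    build_sectors(sector_sets[[i]]$dfield, w, land_mask = land,
                  ocean_mask = !is.na(depth) & depth > 30,
                  location_id = names(depth_list)[i])
  })
  names(sets) <- names(depth_list)
  structure(list(lat = lat, lon = lon, chl = chl, k490 = k490, depth = depth,
                 depth_list = depth_list, land_mask = land,
                 sector_sets = sets, width = w),
            class = "ime_multi_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic fixture bundles
#'
#' Writes the small synthetic inputs used by the test suite to `dir`:
#' `"null-ime"` (three zero-enhancement scenes), `"two-island-overlap"`
#' (two islands close enough to share sector pixels) and
#' `"maui-nui-style-merge"` (a four-island chain whose pairwise shared
#' fractions exceed 50%, so they merge into one complex). Re-running with
#' the same preset and seed reproduces every file byte-identically.
#'
#' @param preset One of the preset names above.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
make_fixtures <- function(preset = c("null-ime", "two-island-overlap",
                                     "maui-nui-style-merge"),
                          seed = 1L, dir = tempfile("fixtures")) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (preset == "null-ime") {
    for (i in 1:3) {
      sc <- generate_scene(scene_config(
        ime_amplitude = 0, noise_cv = 0, missing_fraction = 0,
        reef_radius_30m = 0.08, domain_extent = 0.8,
        seed = derive_seed(seed, i)))
      p <- file.path(dir, sprintf("null_scene_%d.csv", i))
      write_scene_csv(sc, p)
      paths <- c(paths, p)
    }
  } else {
    sep <- if (preset == "two-island-overlap") 0.30 else 0.18
    k <- if (preset == "two-island-overlap") 2 else 4
    centers <- lapply(seq_len(k) - (k + 1) / 2, function(o) c(0, o * sep))
    names(centers) <- paste0("isl", seq_len(k))
    ms <- multi_island_scene(centers, reef_radii = 0.07,
                             domain_extent = 0.7 + (k - 1) * sep,
                             noise_cv = 0.05, seed = derive_seed(seed, 99))
    grid <- expand.grid(lat = ms$lat, lon = ms$lon, KEEP.OUT.ATTRS = FALSE)
    df <- tibble::tibble(lat = grid$lat, lon = grid$lon,
                         chl = as.vector(ms$chl), k490 = as.vector(ms$k490))
    for (nm in names(ms$depth_list)) {
      df[[paste0("depth_", nm)]] <- as.vector(ms$depth_list[[nm]])
    }
    p <- file.path(dir, paste0(gsub("-", "_", preset), ".csv"))
    readr::write_csv(df, p)
    paths <- p
    for (nm in names(ms$sector_sets)) {
      sp <- file.path(dir, paste0("sectors_", nm, ".json"))
      write_sector_set_json(ms$sector_sets[[nm]], sp)
      paths <- c(paths, sp)
    }
  }
  invisible(paths)
}
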