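# Plain-text serialization: scenes as long-format CSV, sector sets as JSON
# (band edges + member-pixel indices, for audit), tables as CSV, profile
# surveys as long-format CSV.

#' Write / read a scene as long-format CSV
#'
#' One row per pixel: `lat`, `lon`, `chl`, `k490`, `depth`, `land`. Axes are
#' recovered from the unique coordinate values on read.
#'
#' @param scene An `ime_ocean_scene`.
#' @param path Output CSV path.
#' @return `write_scene_csv` returns `path` invisibly; `read_scene_csv`
#'   returns an `ime_ocean_scene` (without ground truth).
#' @export
write_scene_csv <- function(scene, path) {
  grid <- expand.grid(lat = scene$lat, lon = scene$lon, KEEP.OUT.ATTRS = FALSE)
  df <- tibble::tibble(
    lat = grid$lat, lon = grid$lon,
    chl = as.vector(scene$chl), k490 = as.vector(scene$k490),
    depth = as.vector(scene$depth), land = as.vector(scene$land_mask)
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  shape <- function(col) {
    m <- matrix(NA_real_, length(lat), length(lon))
    m[cbind(match(df$lat, lat), match(df$lon, lon))] <- col
    m
  }
  land <- shape(as.numeric(df$land)) > 0.5
  structure(list(lat = lat, lon = lon, chl = shape(df$chl),
                 k490 = shape(df$k490), depth = shape(df$depth),
                 land_mask = land, isobath = NULL, dist_deg = NULL,
                 truth = NULL),
            class = "ime_ocean_scene")
}

#' Write / read a sector set as JSON
#'
#' Serializes band edges and member-pixel indices (1-based matrix linear
#' indices) for audit and pipeline restarts.
#'
#' @param sector_set An `ime_sector_set`.
#' @param path Output JSON path.
#' @export
write_sector_set_json <- function(sector_set, path) {
  obj <- list(
    location_id = sector_set$location_id, width = sector_set$width,
    dim = sector_set$dim, lat = sector_set$lat, lon = sector_set$lon,
    warnings = sector_set$warnings,
    buffer_excluded = sector_set$buffer_excluded,
    bands = lapply(seq_len(nrow(sector_set$bands)), function(i) {
      list(band = sector_set$bands$band[i],
           inner = sector_set$bands$inner[i],
           outer = sector_set$bands$outer[i],
           pixels = sector_set$bands$pixels[[i]])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sector_set_json
#' @export
read_sector_set_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  bands <- tibble::tibble(
    band = vapply(obj$bands, function(b) as.integer(b$band), 0L),
    inner = vapply(obj$bands, function(b) b$inner, 0),
    outer = vapply(obj$bands, function(b) b$outer, 0),
    pixels = lapply(obj$bands, function(b) as.integer(unlist(b$pixels)))
  )
  bands$n_pixels <- vapply(bands$pixels, length, 0L)
  structure(list(
    location_id = obj$location_id, width = obj$width, bands = bands,
    buffer_excluded = as.integer(unlist(obj$buffer_excluded)),
    dim = as.integer(unlist(obj$dim)),
    lat = as.numeric(unlist(obj$lat)), lon = as.numeric(unlist(obj$lon)),
    warnings = as.character(unlist(obj$warnings))
  ), class = "ime_sector_set")
}

#' Write / read a profile survey as long-format CSV
#'
#' Columns: `location_id`, `survey_year`, `distance_km`, `depth_m`, `chl`.
#'
#' @param survey An `ime_profile_survey`.
#' @param path Output CSV path.
#' @export
write_survey_csv <- function(survey, path) {
  rows <- purrr::pmap(survey$stations, function(distance_km, profile) {
    tibble::tibble(location_id = survey$location_id,
                   survey_year = survey$survey_year,
                   distance_km = distance_km,
                   depth_m = profile$depth_m, chl = profile$chl)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stations <- df |>
    dplyr::group_by(.data$distance_km) |>
    dplyr::group_modify(~ tibble::tibble(
      profile = list(tibble::tibble(depth_m = .x$depth_m, chl = .x$chl)))) |>
    dplyr::ungroup()
  structure(list(location_id = df$location_id[1],
                 survey_year = df$survey_year[1],
                 stations = stations, truth = NULL),
            class = "ime_profile_survey")
}
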