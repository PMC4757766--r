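# Sector geometry: isobath extraction, distance-to-isobath fields, the eight
# offshore distance bands, pixel deduplication between neighbouring locations
# and merging of locations into island complexes.

#' Sector width from satellite pixel size
#'
#' The offshore analysis bands are as wide as half the diagonal of a satellite
#' pixel, rounded to four decimal places: at the 0.0417-degree resolution of
#' the ocean-colour grid this gives the 0.0295-degree (~3.27 km) band width
#' used throughout.
#'
#' @param pixel_size Pixel edge length in degrees (> 0).
#' @return Band width in degrees.
#' @export
#' @examples
#' sector_width(0.0417) # 0.0295
sector_width <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    stop_ime("`pixel_size` must be a single positive number.")
  }
  round(pixel_size * sqrt(2) / 2, 4)
}

#' Extract an isobath contour from a depth grid
#'
#' Traces the contour at `level` metres (sub-pixel, by linear interpolation
#' between pixel centres) from a bathymetry grid. Land pixels (`NA` depth) are
#' treated as depth 0 so the contour closes around emergent land.
#'
#' @param depth Matrix of depths in metres, positive down, rows indexed by
#'   `lat`, columns by `lon`; `NA` on land.
#' @param lat,lon Increasing pixel-centre coordinate vectors.
#' @param level Contour depth in metres (default 30).
#' @return An `ime_isobath`: list with `level` and `lines`, a list of
#'   data frames with `lat`, `lon` vertex columns.
#' @export
extract_isobath <- function(depth, lat, lon, level = 30) {
  stopifnot(is.matrix(depth), length(lat) == nrow(depth), length(lon) == ncol(depth))
  z <- depth
  z[is.na(z)] <- 0
  rng <- range(z)
  if (level <= rng[1] || level >= rng[2]) {
    stop_ime("Depth grid does not straddle the ", level, " m level (range ",
             signif(rng[1], 4), "-", signif(rng[2], 4), " m): no contour.",
             class = "ime_no_contour")
  }
  cl <- grDevices::contourLines(x = lat, y = lon, z = z, levels = level)
  if (length(cl) == 0) {
    stop_ime("No ", level, " m contour found.", class = "ime_no_contour")
  }
  lines <- lapply(cl, function(l) data.frame(lat = l$x, lon = l$y))
  structure(list(level = level, lines = lines), class = "ime_isobath")
}

#' @export
print.ime_isobath <- function(x, ...) {
  cat("<ime_isobath> level:", x$level, "m;", length(x$lines), "polyline(s),",
      sum(vapply(x$lines, nrow, 0L)), "vertices\n")
  invisible(x)
}

# Resample contour polylines at (approximately) `spacing` degrees-equivalent
# so point-wise minimum distances approximate distance-to-polyline.
densify_isobath <- function(contour, spacing) {
  pts <- lapply(contour$lines, function(l) {
    n <- nrow(l)
    if (n < 2) return(cbind(lat = l$lat, lon = l$lon))
    clat <- cos(mean(l$lat) * pi / 180)
    seg <- sqrt(diff(l$lat)^2 + (diff(l$lon) * clat)^2)
    out <- vector("list", n - 1)
    for (i in seq_len(n - 1)) {
      m <- max(1L, ceiling(seg[i] / spacing))
      t <- seq(0, 1, length.out = m + 1)[-(m + 1)]
      out[[i]] <- cbind(lat = l$lat[i] + t * (l$lat[i + 1] - l$lat[i]),
                        lon = l$lon[i] + t * (l$lon[i + 1] - l$lon[i]))
    }
    rbind(do.call(rbind, out), cbind(lat = l$lat[n], lon = l$lon[n]))
  })
  do.call(rbind, pts)
}

#' Distance-to-isobath field
#'
#' Assigns every pixel centre its minimum great-circle distance to the
#' isobath, in degrees-equivalent (km / 111.195). The contour is densified to
#' a fine vertex spacing before the point-wise minimum so the result
#' approximates true distance-to-polyline.
#'
#' @inheritParams extract_isobath
#' @param contour An `ime_isobath` from [extract_isobath()].
#' @param densify Vertex spacing used to resample the contour, in degrees;
#'   defaults to 2e-4 (a few metres of polyline resolution).
#' @param buffer Optional buffer width in degrees; when given, the returned
#'   object carries an `excluded` logical matrix flagging pixels with
#'   distance < `buffer` (the nearshore exclusion zone).
#' @return An `ime_distance_field`: list with `dist_deg` matrix, axes, and
#'   optionally `excluded`.
#' @export
distance_field <- function(lat, lon, contour, densify = 2e-4, buffer = NULL) {
  stopifnot(inherits(contour, "ime_isobath"))
  pts <- densify_isobath(contour, densify)
  if (nrow(pts) == 0) stop_ime("Empty contour.")
  grid <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  dmin <- rep(Inf, n)
  # chunk the contour to bound the outer-product memory
  idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / 4000))
  for (ii in idx) {
    dk <- haversine_km(
      matrix(grid$lat, n, length(ii)),
      matrix(grid$lon, n, length(ii)),
      matrix(pts[ii, "lat"], n, length(ii), byrow = TRUE),
      matrix(pts[ii, "lon"], n, length(ii), byrow = TRUE)
    )
    dmin <- pmin(dmin, apply(matrix(dk, n), 1, min))
  }
  dist_deg <- matrix(km_to_deg(dmin), nrow = length(lat), ncol = length(lon))
  out <- list(lat = lat, lon = lon, dist_deg = dist_deg, level = contour$level)
  if (!is.null(buffer)) out$excluded <- dist_deg < buffer
  structure(out, class = "ime_distance_field")
}

#' Build the eight offshore sector bands
#'
#' Band `k` (k = 1..`n_bands`) collects the pixels whose distance `d` to the
#' isobath satisfies `k*w <= d < (k+1)*w` (half-open, so a pixel exactly at a
#' band edge joins the outer band). Pixels with `d < w` form the nearshore
#' exclusion buffer; land and inside-isobath pixels are never members.
#'
#' @param dfield An `ime_distance_field`.
#' @param w Band width in degrees (see [sector_width()]).
#' @param n_bands Number of bands (default 8).
#' @param land_mask Optional logical matrix; `TRUE` pixels are excluded.
#' @param ocean_mask Optional logical matrix restricting membership to pixels
#'   outside the isobath (e.g. `depth > level`); when `NULL`, all non-land
#'   pixels are eligible.
#' @param location_id Identifier stored on the set.
#' @return An `ime_sector_set`: list with `location_id`, `width`, a `bands`
#'   tibble (`band`, `inner`, `outer`, and a `pixels` list-column of 1-based
#'   matrix linear indices), `buffer_excluded` indices, grid `dim`, and any
#'   empty-band `warnings`.
#' @export
build_sectors <- function(dfield, w, n_bands = 8, land_mask = NULL,
                          ocean_mask = NULL, location_id = "loc") {
  stopifnot(inherits(dfield, "ime_distance_field"))
  if (w <= 0) stop_ime("Band width must be positive.")
  d <- dfield$dist_deg
  eligible <- !is.na(d)
  if (!is.null(land_mask)) eligible <- eligible & !land_mask
  if (!is.null(ocean_mask)) eligible <- eligible & ocean_mask
  band_of <- floor(d / w)
  bands <- tibble::tibble(
    band = seq_len(n_bands),
    inner = seq_len(n_bands) * w,
    outer = (seq_len(n_bands) + 1) * w,
    pixels = lapply(seq_len(n_bands), function(k) {
      which(eligible & band_of == k)
    })
  )
  bands$n_pixels <- vapply(bands$pixels, length, 0L)
  warn <- character()
  if (any(bands$n_pixels == 0)) {
    warn <- paste0("band ", bands$band[bands$n_pixels == 0],
                   " has no member pixels")
  }
  structure(list(
    location_id = location_id, width = w, bands = bands,
    buffer_excluded = which(eligible & band_of == 0),
    dim = dim(d), lat = dfield$lat, lon = dfield$lon, warnings = warn
  ), class = "ime_sector_set")
}

#' @export
print.ime_sector_set <- function(x, ...) {
  cat("<ime_sector_set>", x$location_id, "- width", x$width, "deg;",
      nrow(x$bands), "bands;", sum(x$bands$n_pixels), "member pixels\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

all_member_pixels <- function(sector_set) {
  sort(unique(unlist(sector_set$bands$pixels)))
}

#' Remove pixels shared between neighbouring locations
#'
#' A satellite pixel that falls in the sector sets of two or more locations
#' would let one location's nearshore signal bleed into another's, so every
#' such pixel is removed from all locations before averaging. The pairwise
#' shared fraction (|shared| / |pixels of the smaller location|, computed
#' before removal) is returned so heavily overlapping locations can be merged
#' into an island complex.
#'
#' @param sector_sets List of `ime_sector_set` on a common grid.
#' @return List with `sets` (cleaned sector sets) and `shared_fraction`
#'   (symmetric matrix, locations in input order).
#' @export
deduplicate_pixels <- function(sector_sets) {
  stopifnot(length(sector_sets) >= 1)
  ids <- vapply(sector_sets, function(s) s$location_id, "")
  members <- lapply(sector_sets, all_member_pixels)
  n <- length(sector_sets)
  frac <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      shared <- length(intersect(members[[i]], members[[j]]))
      denom <- min(length(members[[i]]), length(members[[j]]))
      frac[i, j] <- frac[j, i] <- if (denom == 0) 0 else shared / denom
    }
  }
  counts <- table(unlist(members))
  dup <- as.integer(names(counts)[counts >= 2])
  sets <- lapply(sector_sets, function(s) {
    s$bands$pixels <- lapply(s$bands$pixels, function(p) setdiff(p, dup))
    s$bands$n_pixels <- vapply(s$bands$pixels, length, 0L)
    if (any(s$bands$n_pixels == 0)) {
      s$warnings <- union(s$warnings, paste0(
        "band ", s$bands$band[s$bands$n_pixels == 0],
        " has no member pixels after deduplication"))
    }
    s
  })
  list(sets = sets, shared_fraction = frac,
       shared_fraction_denominator = "smaller location's pixel count")
}

# Transitive closure of the "shares > threshold" relation via union-find.
union_find_components <- function(adjacency) {
  n <- nrow(adjacency)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && adjacency[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Merge heavily overlapping locations into island complexes
#'
#' Locations linked (transitively) by any pairwise shared-pixel fraction above
#' `threshold` are combined: their bathymetry grids are merged pixelwise
#' (minimum depth, i.e. the shallowest of the members) and the sectors are
#' rebuilt off the combined 30-m isobath of each complex.
#'
#' @param depth_grids Named list of per-location depth matrices on a common
#'   grid (`NA` on land).
#' @param lat,lon Shared pixel-centre axes.
#' @param shared_fraction Symmetric matrix from [deduplicate_pixels()].
#' @param threshold Merge threshold on the shared fraction (default 0.5).
#' @param w Band width in degrees for the rebuilt sectors.
#' @param level Isobath level in metres (default 30).
#' @param n_bands Number of bands (default 8).
#' @return List with `assignment` (tibble `location_id`, `complex_id`),
#'   `sector_sets` (one per complex, rebuilt off the merged isobath) and
#'   `depth_grids` (merged, one per complex).
#' @export
merge_complexes <- function(depth_grids, lat, lon, shared_fraction,
                            threshold = 0.5, w, level = 30, n_bands = 8) {
  ids <- names(depth_grids)
  stopifnot(!is.null(ids), all(rownames(shared_fraction) == ids))
  adj <- shared_fraction > threshold
  comp <- union_find_components(adj)
  comp_ids <- vapply(split(ids, comp), function(g) paste(g, collapse = "+"), "")
  assignment <- tibble::tibble(
    location_id = ids,
    complex_id = comp_ids[as.character(comp)]
  )
  sector_sets <- list()
  merged_depth <- list()
  for (cid in unique(assignment$complex_id)) {
    group <- assignment$location_id[assignment$complex_id == cid]
    depth <- Reduce(function(a, b) {
      out <- pmin(a, b, na.rm = TRUE)
      out[is.na(a) & is.na(b)] <- NA
      out
    }, depth_grids[group])
    contour <- extract_isobath(depth, lat, lon, level = level)
    dfield <- distance_field(lat, lon, contour)
    land <- is.na(depth)
    sector_sets[[cid]] <- build_sectors(
      dfield, w, n_bands = n_bands, land_mask = land,
      ocean_mask = !is.na(depth) & depth > level, location_id = cid
    )
    merged_depth[[cid]] <- depth
  }
  list(assignment = assignment, sector_sets = sector_sets,
       depth_grids = merged_depth)
}
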