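# Sector geometry: band width constant, isobath extraction, distance fields
# versus brute-force oracles, band membership, deduplication and complex
# merging.

test_that("sector width is half the pixel diagonal, rounded to 4 decimals", {
  expect_identical(sector_width(0.0417), 0.0295)
  expect_identical(sector_width(0.02), 0.0141)
  expect_error(sector_width(0), "positive")
  expect_error(sector_width(-1), "positive")
})

test_that("cone-island isobath is a circle at the analytic radius", {
  cone <- cone_depth(n = 40, spacing = 0.02, R = 0.3)
  iso <- extract_isobath(cone$depth, cone$lat, cone$lon, level = 30)
  verts <- do.call(rbind, iso$lines)
  r <- sqrt(verts$lat^2 + verts$lon^2)
  expect_lt(max(abs(r - 0.3 * cone$R)), 0.02) # within one grid spacing
})

test_that("halving the grid spacing at least halves the max contour error", {
  err_at <- function(n, spacing) {
    cone <- cone_depth(n = n, spacing = spacing, R = 0.3)
    iso <- extract_isobath(cone$depth, cone$lat, cone$lon, level = 30)
    verts <- do.call(rbind, iso$lines)
    max(abs(sqrt(verts$lat^2 + verts$lon^2) - 0.3 * cone$R))
  }
  e1 <- err_at(40, 0.02)
  e2 <- err_at(80, 0.01)
  expect_lt(e2, e1 / 2 + 1e-12)
})

test_that("the synthetic scene's 30-m contour sits at the configured reef radius", {
  sc <- generate_scene(scene_config(reef_radius_30m = 0.1, domain_extent = 1.0,
                                    noise_cv = 0, missing_fraction = 0))
  verts <- do.call(rbind, sc$isobath$lines)
  r <- sqrt(verts$lat^2 + verts$lon^2)
  expect_lt(max(abs(r - 0.1)), 0.0417)
})

test_that("grids not straddling the level give a no-contour error", {
  deep <- matrix(500, 10, 10)
  expect_error(extract_isobath(deep, 1:10, 1:10, 30), class = "ime_no_contour")
})

test_that("distance is zero on the contour and matches the circle oracle", {
  # straight contour through pixel centres
  lat <- seq(0, 0.1, by = 0.01); lon <- lat
  contour <- structure(list(level = 30, lines = list(
    data.frame(lat = c(0.05, 0.05), lon = c(0, 0.1)))), class = "ime_isobath")
  df <- distance_field(lat, lon, contour)
  expect_lt(df$dist_deg[which(lat == 0.05), 3], 1e-9)

  # circular contour: analytic r - R and brute-force densified oracle
  R <- 0.12
  pts <- circle_points(R, n = 400)
  circ <- structure(list(level = 30, lines = list(
    data.frame(lat = c(pts[, 1], pts[1, 1]), lon = c(pts[, 2], pts[1, 2])))),
    class = "ime_isobath")
  lat2 <- seq(-0.3, 0.3, by = 0.05); lon2 <- lat2
  df2 <- distance_field(lat2, lon2, circ, densify = 2e-5)
  oracle <- brute_distance_deg(
    lat2, lon2,
    densify_polyline(circ$lines[[1]]$lat, circ$lines[[1]]$lon, n = 1e4))
  outside <- sqrt(outer(lat2^2, rep(1, length(lon2))) +
                  outer(rep(1, length(lat2)), lon2^2)) > R + 0.03
  expect_lt(max(abs(df2$dist_deg - oracle)[outside]), 1e-6)
  r <- sqrt(outer(lat2^2, rep(1, length(lon2))) +
            outer(rep(1, length(lat2)), lon2^2))
  expect_lt(max(abs(df2$dist_deg - (r - R))[outside]), 5e-5)
})

test_that("the nearshore exclusion flag marks exactly d < 0.0295 degrees", {
  cone <- cone_depth(n = 40, spacing = 0.02, R = 0.3)
  iso <- extract_isobath(cone$depth, cone$lat, cone$lon, level = 30)
  df <- distance_field(cone$lat, cone$lon, iso, buffer = 0.0295)
  expect_identical(df$excluded, df$dist_deg < 0.0295)
})

test_that("band 8 spans [0.2360, 0.2655) and edge ties go outward", {
  w <- sector_width(0.0417)
  d <- matrix(c(0.05, 2 * w, 0.24, 0.5), 2, 2)
  dfield <- structure(list(lat = 1:2, lon = 1:2, dist_deg = d, level = 30),
                      class = "ime_distance_field")
  ss <- build_sectors(dfield, w)
  expect_equal(ss$bands$inner[8], 0.2360)
  expect_equal(ss$bands$outer[8], 0.2655)
  # a pixel exactly at 2w belongs to band 2, not band 1
  expect_true(2L %in% ss$bands$pixels[[2]])
  expect_false(2L %in% ss$bands$pixels[[1]])
  expect_true(3L %in% ss$bands$pixels[[8]]) # 0.24 in [0.2360, 0.2655)
})

test_that("band membership matches the brute-force interval test on a 50x50 grid", {
  withr::with_seed(5, {
    n <- 50
    lat <- seq(0, by = 0.02, length.out = n); lon <- lat
    d <- matrix(runif(n * n, 0, 0.4), n, n)
    land <- matrix(runif(n * n) < 0.05, n, n)
  })
  dfield <- structure(list(lat = lat, lon = lon, dist_deg = d, level = 30),
                      class = "ime_distance_field")
  w <- 0.0295
  ss <- build_sectors(dfield, w, land_mask = land)
  for (k in 1:8) {
    expect_identical(sort(ss$bands$pixels[[k]]),
                     sort(brute_membership(d, w, k, !land)))
  }
  expect_identical(sort(ss$buffer_excluded),
                   sort(brute_membership(d, w, 0, !land)))
})

test_that("bands partition the offshore zone: disjoint, none within the buffer", {
  sc <- generate_scene(fast_cfg(seed = 2))
  ss <- scene_sectors(sc)
  all_px <- unlist(ss$bands$pixels)
  expect_identical(anyDuplicated(all_px), 0L)
  expect_true(all(sc$dist_deg[all_px] >= ss$width))
  for (k in 1:8) {
    dk <- sc$dist_deg[ss$bands$pixels[[k]]]
    expect_true(all(dk >= ss$bands$inner[k] & dk < ss$bands$outer[k]))
  }
})

test_that("an empty band is recorded as a warning on the sector set", {
  d <- matrix(c(0.05, 0.07, 0.4, 0.5), 2, 2) # nothing in bands 2..7
  dfield <- structure(list(lat = 1:2, lon = 1:2, dist_deg = d, level = 30),
                      class = "ime_distance_field")
  ss <- build_sectors(dfield, 0.0295)
  expect_gt(length(ss$warnings), 0)
})

test_that("distant locations share no pixels and sets pass through unchanged", {
  ms <- multi_island_scene(list(A = c(0, -0.35), B = c(0, 0.35)),
                           reef_radii = 0.06, domain_extent = 1.3,
                           noise_cv = 0, missing_fraction = 0)
  dd <- deduplicate_pixels(ms$sector_sets)
  expect_equal(dd$shared_fraction["A", "B"], 0)
  expect_identical(dd$sets[[1]]$bands$pixels, ms$sector_sets[[1]]$bands$pixels)
})

test_that("deduplication removes exactly the brute-force intersection", {
  ms <- multi_island_scene(list(A = c(0, -0.14), B = c(0, 0.14)),
                           reef_radii = 0.06, domain_extent = 1.1,
                           noise_cv = 0, missing_fraction = 0)
  before <- lapply(ms$sector_sets, function(s) sort(unique(unlist(s$bands$pixels))))
  shared <- intersect(before$A, before$B)
  expect_gt(length(shared), 0)
  dd <- deduplicate_pixels(ms$sector_sets)
  after <- lapply(dd$sets, function(s) sort(unique(unlist(s$bands$pixels))))
  expect_identical(setdiff(before$A, after$A), shared)
  expect_identical(setdiff(before$B, after$B), shared)
  expect_equal(dd$shared_fraction["A", "B"],
               length(shared) / min(length(before$A), length(before$B)))
  # after deduplication no pixel appears twice across locations
  expect_identical(anyDuplicated(unlist(after)), 0L)
})

test_that("locations sharing most of their pixels report a fraction above 0.5", {
  ms <- multi_island_scene(list(A = c(0, -0.07), B = c(0, 0.07)),
                           reef_radii = 0.06, domain_extent = 1.1,
                           noise_cv = 0, missing_fraction = 0)
  dd <- deduplicate_pixels(ms$sector_sets)
  expect_gt(dd$shared_fraction["A", "B"], 0.5)
})

test_that("complex merging is the transitive closure of the >threshold relation", {
  n <- 12
  depth <- matrix(100, n, n); depth[5:8, 5:8] <- 10; depth[6:7, 6:7] <- NA
  grids <- list(A = depth, B = depth, C = depth, D = depth)
  lat <- seq(0, by = 0.05, length.out = n); lon <- lat
  frac <- matrix(0, 4, 4, dimnames = list(names(grids), names(grids)))
  frac["A", "B"] <- frac["B", "A"] <- 0.8
  frac["B", "C"] <- frac["C", "B"] <- 0.6
  # A-C stays below threshold; D is isolated
  res <- merge_complexes(grids, lat, lon, frac, threshold = 0.5, w = 0.0295)
  cx <- res$assignment$complex_id
  expect_equal(cx[1], cx[2])
  expect_equal(cx[2], cx[3])
  expect_false(cx[4] == cx[1])
  expect_equal(length(unique(cx)), 2)
})

test_that("all fractions at or below threshold give the identity assignment", {
  n <- 12
  depth <- matrix(100, n, n); depth[5:8, 5:8] <- 10; depth[6:7, 6:7] <- NA
  grids <- list(A = depth, B = depth)
  lat <- seq(0, by = 0.05, length.out = n)
  frac <- matrix(0.5, 2, 2, dimnames = list(names(grids), names(grids)))
  diag(frac) <- 0
  res <- merge_complexes(grids, lat, lat, frac, threshold = 0.5, w = 0.0295)
  expect_equal(length(unique(res$assignment$complex_id)), 2)
})

test_that("a four-member chain merges into a single complex with rebuilt sectors", {
  ms <- multi_island_scene(
    list(A = c(0, -0.27), B = c(0, -0.09), C = c(0, 0.09), D = c(0, 0.27)),
    reef_radii = 0.07, domain_extent = 1.35, noise_cv = 0, missing_fraction = 0)
  dd <- deduplicate_pixels(ms$sector_sets)
  res <- merge_complexes(ms$depth_list, ms$lat, ms$lon, dd$shared_fraction,
                         threshold = 0.5, w = ms$width)
  expect_equal(length(unique(res$assignment$complex_id)), 1)
  combined <- res$sector_sets[[1]]
  expect_s3_class(combined, "ime_sector_set")
  expect_gt(sum(combined$bands$n_pixels), 0)
})
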