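test_that("haversine distance matches closed-form arcs on the reference sphere", {
  expect_identical(haversine_km(0, 0, 0, 0), 0)
  # equatorial degree and quarter meridian, radius 6371.0088 km
  expect_equal(haversine_km(0, 0, 1, 0), 6371.0088 * pi / 180,
               tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 0, 90), 6371.0088 * pi / 2,
               tolerance = 1e-9)
  # symmetry
  expect_equal(haversine_km(14.2, 40.8, 14.5, 40.6),
               haversine_km(14.5, 40.6, 14.2, 40.8))
  expect_error(haversine_km(181, 0, 0, 0), "longitude")
  expect_error(haversine_km(0, 95, 0, 0), "latitude")
})

test_that("occurrence validation rejects bad records", {
  occ <- make_occurrences(c(14.1, 14.2), c(40.1, 40.2))
  expect_s3_class(occ, "occurrence_records")
  bad <- as.data.frame(occ); bad$elevation_m[1] <- -500
  expect_error(occurrence_records(bad), "-430")
  dup <- as.data.frame(occ); dup$site_id <- c("a", "a")
  expect_error(occurrence_records(dup), "duplicated")
})

test_that("dragnet score equals the brute-force summation oracle", {
  set.seed(42)
  for (gsize in c(5, 12, 20)) {
    grid <- small_grid(gsize, cell = 0.015)
    occ <- make_occurrences(runif(3, grid$min_lon, grid$max_lon),
                            runif(3, grid$min_lat, grid$max_lat))
    surf <- dragnet_score(occ, grid)
    expect_lt(max(abs(surf$scores - oracle_dragnet(occ, grid))), 1e-12)
    # unnormalised variant too
    surf0 <- dragnet_score(occ, grid, dragnet_params(normalize_by = "none"))
    expect_lt(max(abs(surf0$scores -
                        oracle_dragnet(occ, grid, normalize = FALSE))),
              1e-12)
  }
})

test_that("single-occurrence score decays monotonically with distance, no buffer", {
  grid <- small_grid(9, cell = 0.02)
  occ <- make_occurrences(14.05, 40.05)
  surf <- dragnet_score(occ, grid, dragnet_params(normalize_by = "none"))
  cc <- cell_centres(grid)
  d <- haversine_km(as.vector(cc$lon_mat), as.vector(cc$lat_mat),
                    occ$longitude, occ$latitude)
  ord <- order(d)
  s <- as.vector(surf$scores)[ord]
  # strictly decreasing wherever distance strictly increases (equidistant
  # cells tie exactly)
  incr <- diff(d[ord]) > 1e-12
  expect_true(all(diff(s)[incr] < 0))
  expect_true(all(abs(diff(s)[!incr]) < 1e-12))
  # nearest cell is the maximum (maximum contribution at d = 0)
  expect_equal(which.max(surf$scores), which.min(
    matrix(d, grid$n_rows, grid$n_cols)))
})

test_that("symmetric occurrences give a mirror-symmetric surface", {
  grid <- small_grid(10, cell = 0.02)
  mid <- (grid$min_lon + grid$max_lon) / 2
  occ <- make_occurrences(c(mid - 0.05, mid + 0.05), c(40.1, 40.1))
  surf <- dragnet_score(occ, grid)
  expect_equal(surf$scores, surf$scores[, ncol(surf$scores):1],
               tolerance = 1e-9)
})

test_that("surface is invariant to occurrence order", {
  grid <- small_grid(6)
  set.seed(3)
  occ <- make_occurrences(runif(5, 14, 14.1), runif(5, 40, 40.1))
  a <- dragnet_score(occ, grid)
  b <- dragnet_score(occ[sample(5), ], grid)
  expect_equal(a$scores, b$scores)
})

test_that("degenerate configurations error informatively", {
  grid <- small_grid(4)
  expect_error(dragnet_score(data.frame(longitude = numeric(0),
                                        latitude = numeric(0)), grid),
               "empty")
  same <- make_occurrences(c(14.05, 14.05), c(40.05, 40.05))
  expect_error(dragnet_score(same, grid), "degenerate")
  one <- make_occurrences(14.05, 40.05)
  expect_error(dragnet_score(one, grid), ">= 2")
  expect_silent(dragnet_score(one, grid, dragnet_params(normalize_by = "none")))
})

test_that("bootstrap at fraction 1.0 reproduces the rescaled deterministic surface", {
  grid <- small_grid(8)
  set.seed(11)
  occ <- make_occurrences(runif(6, 14, 14.16), runif(6, 40, 40.16))
  full <- rescale_surface(dragnet_score(occ, grid))
  # power-of-two replicate count keeps the identical-replicate mean exact
  boot <- bootstrap_profile(occ, grid,
                            boot = bootstrap_params(4, 1.0, 1.0, seed = 9))
  expect_identical(boot$scores, full$scores)
  expect_identical(boot$provenance, "bootstrap-mean")
})

test_that("bootstrap surfaces are seed-reproducible and seed-sensitive", {
  grid <- small_grid(6)
  set.seed(12)
  occ <- make_occurrences(runif(8, 14, 14.12), runif(8, 40, 40.12))
  a <- bootstrap_profile(occ, grid, boot = bootstrap_params(6, seed = 5))
  b <- bootstrap_profile(occ, grid, boot = bootstrap_params(6, seed = 5))
  c <- bootstrap_profile(occ, grid, boot = bootstrap_params(6, seed = 6))
  expect_identical(a$scores, b$scores)
  expect_false(identical(a$scores, c$scores))
  expect_true(all(a$scores >= 0 & a$scores <= 1))
  expect_error(bootstrap_profile(occ[1:2, ], grid), ">= 3")
})

test_that("elevation mask removes exactly the out-of-band cells and preserves scores", {
  grid <- small_grid(6)
  set.seed(13)
  occ <- make_occurrences(runif(4, 14, 14.12), runif(4, 40, 40.12))
  surf <- dragnet_score(occ, grid)

  flat700 <- raster_grid(grid, matrix(700, 6, 6))
  all_masked <- apply_elevation_mask(surf, flat700)
  expect_false(any(all_masked$mask))
  expect_equal(nrow(extract_source_areas(all_masked)), 0L)

  flat100 <- raster_grid(grid, matrix(100, 6, 6))
  noop <- apply_elevation_mask(surf, flat100)
  expect_true(all(noop$mask))
  expect_equal(noop$scores, surf$scores)

  # boundary: 600 m stays, 601 m goes (band is 0-600 inclusive)
  elev <- matrix(100, 6, 6); elev[1, 1] <- 601; elev[1, 2] <- 600
  elev[2, 1] <- -5
  masked <- apply_elevation_mask(surf, raster_grid(grid, elev))
  expect_false(masked$mask[1, 1])
  expect_true(masked$mask[1, 2])
  expect_false(masked$mask[2, 1])
  expect_equal(sum(!masked$mask), sum(elev > 600 | elev < 0))
  expect_equal(masked$scores[masked$mask], surf$scores[masked$mask])

  wrong <- raster_grid(small_grid(5), matrix(100, 5, 5))
  expect_error(apply_elevation_mask(surf, wrong), "match")
})

test_that("source-area extraction finds, merges and ranks peaks", {
  grid <- small_grid(9, cell = 0.05)  # ~5.5 km cells: peaks stay distinct
  s <- matrix(0.1, 9, 9)
  s[3, 3] <- 1.0
  surf <- score_surface <- structure(
    list(grid = grid, scores = s, mask = matrix(TRUE, 9, 9),
         provenance = "single-run"), class = "score_surface")
  one <- extract_source_areas(surf, quantile_threshold = 0.95)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$peak_row, one$peak_col), c(3L, 3L))

  # two identical far-apart peaks: tie broken by (row, col) order
  s2 <- matrix(0.1, 9, 9); s2[2, 2] <- 1; s2[8, 8] <- 1
  surf$scores <- s2
  two <- extract_source_areas(surf, quantile_threshold = 0.99,
                              merge_radius_km = 3)
  expect_equal(nrow(two), 2L)
  expect_equal(two$peak_row, c(2L, 8L))
  expect_equal(two$rank, 1:2)

  # the same two peaks merge into one area with a huge merge radius
  merged <- extract_source_areas(surf, quantile_threshold = 0.99,
                                 merge_radius_km = 100)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_cells, 2L)
})

test_that("argmax of the bootstrap mean approaches the true source as n grows", {
  grid <- grid_spec(14.0, 14.6, 40.4, 41.0, 0.01)
  src <- data.frame(lon = 14.3, lat = 40.7)
  err_for <- function(n, seed) {
    occ <- gen_occurrences(n, src, "exponential", scale_km = 8, seed = seed)
    surf <- bootstrap_profile(occ, grid,
                              boot = bootstrap_params(10, seed = seed))
    pk <- which(surf$scores == max(surf$scores), arr.ind = TRUE)[1, ]
    cc <- cell_centres(grid)
    haversine_km(cc$lon[pk[2]], cc$lat[pk[1]], src$lon, src$lat)
  }
  seeds <- 1:8
  err_small <- vapply(seeds, function(s) err_for(10, s), numeric(1))
  err_large <- vapply(seeds, function(s) err_for(200, s + 100), numeric(1))
  expect_lt(mean(err_large), mean(err_small))
})
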