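# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

small_grid <- function(n = 5, cell = 0.02, lon0 = 14.0, lat0 = 40.0) {
  grid_spec(lon0, lon0 + n * cell, lat0, lat0 + n * cell, cell)
}

make_occurrences <- function(lon, lat, ids = NULL) {
  n <- length(lon)
  occurrence_records(data.frame(
    site_id = if (is.null(ids)) sprintf("S%02d", seq_len(n)) else ids,
    longitude = lon, latitude = lat, elevation_m = 100,
    site_type = "orchard", year = 2019L, infested = TRUE,
    stringsAsFactors = FALSE))
}

# Independent brute-force oracle for the distance-decay score: plain
# double loop over cells and occurrences, its own haversine from the
# textbook formula (no geosphere).
oracle_dragnet <- function(occ, grid, beta = 1, normalize = TRUE) {
  hav <- function(lon1, lat1, lon2, lat2) {
    rad <- pi / 180
    dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
    a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
    2 * 6371.0088 * asin(pmin(1, sqrt(a)))
  }
  n <- nrow(occ)
  sigma <- 1
  if (normalize) {
    ds <- c()
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
      ds <- c(ds, hav(occ$longitude[i], occ$latitude[i],
                      occ$longitude[j], occ$latitude[j]))
    sigma <- mean(ds)
  }
  out <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      clat <- grid$max_lat - (r - 0.5) * grid$cell_size
      clon <- grid$min_lon + (c - 0.5) * grid$cell_size
      s <- 0
      for (i in seq_len(n))
        s <- s + exp(-beta * hav(clon, clat, occ$longitude[i],
                                 occ$latitude[i]) / sigma)
      out[r, c] <- s / n
    }
  }
  out
}

make_fruit <- function(fruit_id = "f1", site_id = "s1", year = 2019L,
                       category = "sorted", adults = 0L, larvae = 0L,
                       moth = FALSE, silk = FALSE, frass = NA_real_,
                       kernel = FALSE, crack = FALSE) {
  data.frame(fruit_id = fruit_id, site_id = site_id, year = year,
             category = category, sap_beetle_adults = adults,
             sap_beetle_larvae = larvae, moth_stages_present = moth,
             silk_threads = silk, frass_diameter_mm = frass,
             kernel_damaged = kernel, sheath_crack = crack,
             stringsAsFactors = FALSE)
}
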