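# Distance-decay geographic profiling of occurrence points.
#
# Each infested site contributes a negative-exponential distance-decay kernel
# with no buffer zone (maximum contribution at zero distance), the Dragnet
# family of geographic-profiling scores. Distances are great-circle
# (haversine) on a sphere of radius 6371.0088 km.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' coordinates (recycled as usual).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in WGS84 decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)  # one equatorial degree, ~111.19 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Validate occurrence (infested-site) records
#'
#' One row per georeferenced site. Profiling treats each site as one point
#' regardless of how many specimens it yielded.
#'
#' @param df A data.frame with columns `site_id`, `longitude`, `latitude`,
#'   `elevation_m`, `site_type` (one of `warehouse`, `orchard`, `farm`),
#'   `year`, `infested` (logical).
#' @return The validated data.frame, invisibly classed `occurrence_records`.
#' @export
occurrence_records <- function(df) {
  req <- c("site_id", "longitude", "latitude", "elevation_m",
           "site_type", "year", "infested")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing occurrence columns: ", paste(miss, collapse = ", "))
  check_lonlat(df$longitude, df$latitude)
  if (any(df$elevation_m < -430))
    stop("elevation below -430 m a.s.l. (lowest land): ",
         paste(df$site_id[df$elevation_m < -430], collapse = ", "))
  if (anyDuplicated(df$site_id))
    stop("duplicated site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  bad_type <- setdiff(unique(df$site_type), c("warehouse", "orchard", "farm"))
  if (length(bad_type))
    stop("unknown site_type: ", paste(bad_type, collapse = ", "))
  if (!is.logical(df$infested)) stop("infested must be logical")
  class(df) <- c("occurrence_records", class(df))
  df
}

#' Scoring-kernel parameters
#'
#' @param decay_coefficient Dimensionless decay rate of the exponential
#'   kernel (> 0). With distance normalisation this is scale-free.
#' @param normalize_by Either `"mean_pairwise_distance"` (default; distances
#'   are divided by the mean pairwise distance among the occurrences) or
#'   `"none"` (distances in km, i.e. a 1-km scale).
#' @return A list of class `dragnet_params`.
#' @export
dragnet_params <- function(decay_coefficient = 1.0,
                           normalize_by = c("mean_pairwise_distance", "none")) {
  normalize_by <- match.arg(normalize_by)
  if (!is.numeric(decay_coefficient) || decay_coefficient <= 0)
    stop("decay_coefficient must be > 0")
  structure(list(decay_coefficient = decay_coefficient,
                 normalize_by = normalize_by),
            class = "dragnet_params")
}

#' Bootstrap-aggregation parameters
#'
#' Defaults follow the study design: 30 replicates, each scoring a random
#' subsample of between 25% and 75% of the occurrence set.
#'
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param fraction_low,fraction_high Subsample fraction bounds, with
#'   `0 < fraction_low <= fraction_high <= 1`.
#' @param seed Root seed; each replicate uses a deterministic child seed.
#' @return A list of class `bootstrap_params`.
#' @export
bootstrap_params <- function(n_replicates = 30L, fraction_low = 0.25,
                             fraction_high = 0.75, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!(fraction_low > 0 && fraction_low <= fraction_high &&
        fraction_high <= 1))
    stop("need 0 < fraction_low <= fraction_high <= 1")
  structure(list(n_replicates = as.integer(n_replicates),
                 fraction_low = fraction_low, fraction_high = fraction_high,
                 seed = as.integer(seed)),
            class = "bootstrap_params")
}

score_surface <- function(grid, scores, mask = NULL, provenance = "single-run") {
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  stopifnot(all(dim(scores) == c(grid$n_rows, grid$n_cols)),
            all(dim(mask) == dim(scores)))
  structure(list(grid = grid, scores = scores, mask = mask,
                 provenance = provenance),
            class = "score_surface")
}

#' @export
print.score_surface <- function(x, ...) {
  v <- x$scores[x$mask]
  cat(sprintf("score_surface (%s): %d x %d, %d valid cells, scores [%g, %g]\n",
              x$provenance, x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

mean_pairwise_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(0)
  pts <- cbind(lon, lat)
  d <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM))
  mean(d[upper.tri(d)])
}

#' Score a grid by distance decay from occurrence points
#'
#' The score of a cell with centre c is
#' \deqn{s(c) = \frac{1}{N}\sum_{i=1}^{N} \exp\{-\beta\, d(c, x_i)/\sigma\}}
#' where d is the haversine distance to occurrence i, \eqn{\beta} the decay
#' coefficient and \eqn{\sigma} the mean pairwise distance among the
#' occurrences (1 km when normalisation is off). There is no buffer zone:
#' the kernel is maximal at zero distance and strictly decreasing.
#'
#' @param occurrences An [occurrence_records()] data.frame (or any data.frame
#'   with `longitude`/`latitude`).
#' @param grid A [grid_spec()].
#' @param params A [dragnet_params()].
#' @return A `score_surface` (provenance `"single-run"`).
#' @export
dragnet_score <- function(occurrences, grid, params = dragnet_params()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "dragnet_params"))
  n <- nrow(occurrences)
  if (is.null(n) || n == 0) stop("empty occurrence list")
  lon <- occurrences$longitude; lat <- occurrences$latitude
  check_lonlat(lon, lat)
  if (params$normalize_by == "mean_pairwise_distance") {
    if (n < 2)
      stop("mean-pairwise-distance normalisation needs >= 2 occurrences")
    sigma <- mean_pairwise_km(lon, lat)
    if (sigma == 0)
      stop("degenerate configuration: all occurrences at one point, ",
           "mean pairwise distance is zero")
  } else {
    sigma <- 1.0
  }
  cc <- cell_centres(grid)
  clon <- as.vector(cc$lon_mat); clat <- as.vector(cc$lat_mat)
  acc <- numeric(length(clon))
  beta <- params$decay_coefficient
  for (i in seq_len(n)) {
    d <- geosphere::distHaversine(cbind(clon, clat), c(lon[i], lat[i]),
                                  r = EARTH_RADIUS_KM)
    acc <- acc + exp(-beta * d / sigma)
  }
  score_surface(grid, matrix(acc / n, grid$n_rows, grid$n_cols))
}

#' Rescale a surface's valid scores to [0, 1]
#'
#' Min-max rescaling over valid cells; a constant surface rescales to all
#' zeros. Masked cells are untouched.
#'
#' @param surface A `score_surface`.
#' @return The rescaled surface.
#' @export
rescale_surface <- function(surface) {
  stopifnot(inherits(surface, "score_surface"))
  v <- surface$scores[surface$mask]
  if (!length(v)) return(surface)
  rng <- range(v)
  s <- surface$scores
  if (rng[2] > rng[1]) {
    s[surface$mask] <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    s[surface$mask] <- 0
  }
  surface$scores <- s
  surface
}

#' Bootstrap-aggregated profile surface
#'
#' Runs [dragnet_score()] on `n_replicates` random subsamples of the
#' occurrence set. Each replicate r draws a fraction u_r uniformly on
#' [`fraction_low`, `fraction_high`], subsamples m_r = max(2, round(u_r N))
#' sites without replacement, scores them, and min-max rescales its surface
#' to [0, 1]; the returned surface is the cell-wise mean over replicates.
#' Rescaling before averaging lets replicates with different subsample sizes
#' contribute comparably. Reproducible for a fixed seed: the root seed
#' deterministically generates one child seed per replicate.
#'
#' @inheritParams dragnet_score
#' @param boot A [bootstrap_params()].
#' @return A `score_surface` (provenance `"bootstrap-mean"`), valid scores
#'   in [0, 1].
#' @export
bootstrap_profile <- function(occurrences, grid, params = dragnet_params(),
                              boot = bootstrap_params()) {
  stopifnot(inherits(boot, "bootstrap_params"))
  n <- nrow(occurrences)
  if (is.null(n) || n < 3)
    stop("bootstrap profiling needs >= 3 occurrences")
  set.seed(boot$seed)
  child_seeds <- sample.int(.Machine$integer.max, boot$n_replicates)
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in seq_len(boot$n_replicates)) {
    set.seed(child_seeds[r])
    u <- stats::runif(1, boot$fraction_low, boot$fraction_high)
    m <- max(2L, as.integer(round(u * n)))
    idx <- sort(sample.int(n, m))  # order-stable: degenerate m = N case
                                   # reproduces the full surface bitwise
    rep_surface <- rescale_surface(
      dragnet_score(occurrences[idx, , drop = FALSE], grid, params))
    acc <- acc + rep_surface$scores
  }
  score_surface(grid, acc / boot$n_replicates,
                provenance = "bootstrap-mean")
}

#' Restrict a surface to an elevation band
#'
#' Cells whose elevation lies outside [0, `max_elevation`] metres a.s.l.
#' (strictly above the ceiling, or below sea level) are marked invalid;
#' surviving scores are unchanged. The study restricted its final mean
#' surface to 0-600 m a.s.l., where all infested sites were found.
#'
#' @param surface A `score_surface`.
#' @param dem A [raster_grid()] of elevations (m), on the same grid, or a
#'   bare matrix of matching shape.
#' @param max_elevation Ceiling in metres (default 600, inclusive).
#' @return The masked surface (provenance `"masked"`).
#' @export
apply_elevation_mask <- function(surface, dem, max_elevation = 600) {
  stopifnot(inherits(surface, "score_surface"))
  if (inherits(dem, "raster_grid")) {
    if (!same_grid(dem$grid, surface$grid))
      stop("DEM grid does not match the surface grid ",
           "(shape or georeference differs)")
    elev <- dem$values
  } else if (is.matrix(dem)) {
    if (!all(dim(dem) == dim(surface$scores)))
      stop("DEM matrix shape does not match the surface grid")
    elev <- dem
  } else stop("dem must be a raster_grid or a matrix")
  keep <- !is.na(elev) & elev >= 0 & elev <= max_elevation
  surface$mask <- surface$mask & keep
  surface$provenance <- "masked"
  surface
}

#' Extract ranked candidate source areas
#'
#' Valid cells scoring at or above the given quantile of valid scores are
#' clustered by 8-connectivity; clusters whose peak cells lie within
#' `merge_radius_km` of each other are merged; areas are ranked by peak
#' score, descending. Ties are broken by (row, col) lexicographic order of
#' the peak cell. The rank-1 area is the most likely area of origin.
#'
#' @param surface A `score_surface` with at least one valid cell (an
#'   all-masked surface yields an empty result, not an error).
#' @param quantile_threshold Score quantile defining hotspot cells
#'   (default 0.95).
#' @param merge_radius_km Peaks closer than this are one area (default 3).
#' @return A data.frame with columns `rank`, `peak_row`, `peak_col`,
#'   `peak_lon`, `peak_lat`, `peak_score`, `n_cells`, and a list-column
#'   `cells` of member (row, col) matrices.
#' @export
extract_source_areas <- function(surface, quantile_threshold = 0.95,
                                 merge_radius_km = 3.0) {
  stopifnot(inherits(surface, "score_surface"))
  empty <- data.frame(rank = integer(), peak_row = integer(),
                      peak_col = integer(), peak_lon = numeric(),
                      peak_lat = numeric(), peak_score = numeric(),
                      n_cells = integer())
  empty$cells <- list()
  valid <- surface$mask
  if (!any(valid)) return(empty)
  vscores <- surface$scores[valid]
  thr <- stats::quantile(vscores, quantile_threshold, names = FALSE)
  hot <- valid & surface$scores >= thr
  if (!any(hot)) return(empty)

  labels <- connected_components8(hot)
  comp_ids <- sort(unique(labels[labels > 0]))
  cc <- cell_centres(surface$grid)

  peak_of <- function(cells) {
    # cells: matrix (row, col); peak = max score, ties by (row, col)
    sc <- surface$scores[cells]
    best <- max(sc)
    cand <- cells[sc == best, , drop = FALSE]
    ord <- order(cand[, 1], cand[, 2])
    list(cell = cand[ord[1], ], score = best)
  }

  comps <- lapply(comp_ids, function(id) {
    cells <- which(labels == id, arr.ind = TRUE)
    colnames(cells) <- c("row", "col")
    pk <- peak_of(cells)
    list(cells = cells, peak = pk$cell, score = pk$score)
  })

  # single-linkage merge of clusters whose peaks are within merge_radius_km
  repeat {
    k <- length(comps)
    if (k < 2) break
    merged <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        pi <- comps[[i]]$peak; pj <- comps[[j]]$peak
        d <- haversine_km(cc$lon[pi[2]], cc$lat[pi[1]],
                          cc$lon[pj[2]], cc$lat[pj[1]])
        if (d <= merge_radius_km) {
          cells <- rbind(comps[[i]]$cells, comps[[j]]$cells)
          pk <- peak_of(cells)
          comps[[i]] <- list(cells = cells, peak = pk$cell, score = pk$score)
          comps[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  scores <- vapply(comps, function(a) a$score, numeric(1))
  rows <- vapply(comps, function(a) a$peak[1], numeric(1))
  cols <- vapply(comps, function(a) a$peak[2], numeric(1))
  ord <- order(-scores, rows, cols)
  comps <- comps[ord]
  out <- data.frame(
    rank = seq_along(comps),
    peak_row = vapply(comps, function(a) as.integer(a$peak[1]), integer(1)),
    peak_col = vapply(comps, function(a) as.integer(a$peak[2]), integer(1)),
    peak_score = vapply(comps, function(a) a$score, numeric(1)),
    n_cells = vapply(comps, function(a) nrow(a$cells), integer(1))
  )
  out$peak_lon <- cc$lon[out$peak_col]
  out$peak_lat <- cc$lat[out$peak_row]
  out$cells <- lapply(comps, function(a) a$cells)
  out[, c("rank", "peak_row", "peak_col", "peak_lon", "peak_lat",
          "peak_score", "n_cells", "cells")]
}

# 8-connected component labelling of a logical matrix (flood fill).
connected_components8 <- function(hot) {
  nr <- nrow(hot); nc <- ncol(hot)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(hot)) {
    if (labels[start] > 0L) next
    current <- current + 1L
    stack <- start
    labels[start] <- current
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cell - 1L) %% nr) + 1L
      c <- ((cell - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        nb <- (cc - 1L) * nr + rr
        if (hot[nb] && labels[nb] == 0L) {
          labels[nb] <- current
          stack <- c(stack, nb)
        }
      }
    }
  }
  labels
}
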