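# Seeded synthetic-data generators. These emulate the statistical structure
# the analysis chain assumes — occurrence points dispersed from one or more
# introduction sources over an elevation surface, haplotype samples drawn
# from fixed frequencies, aligned sequence groups at controlled divergences,
# and fruit inspections with category-specific infestation probabilities —
# so every pipeline stage is testable without field data. Every generator
# is a pure function of its arguments and seed.

#' Generate a synthetic elevation raster
#'
#' Deterministic surface: a flat base plus an optional west-to-east linear
#' ramp and an optional sinusoidal ridge running north-south. With a ramp
#' alone the fraction of cells above any elevation threshold has a closed
#' form, which makes mask bookkeeping exactly checkable.
#'
#' @param grid A [grid_spec()].
#' @param base_elevation Elevation of the western edge (m, default 100).
#' @param ramp_amplitude Total west-to-east linear rise (m, default 0).
#' @param ridge_amplitude Peak height of a sinusoidal north-south ridge
#'   added on top (m, default 0); the ridge crests at the grid's central
#'   column.
#' @return A [raster_grid()] of elevations (all >= 0 provided the inputs
#'   are non-negative).
#' @export
gen_dem <- function(grid, base_elevation = 100, ramp_amplitude = 0,
                    ridge_amplitude = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  xfrac <- (seq_len(grid$n_cols) - 0.5) / grid$n_cols
  profile <- base_elevation + ramp_amplitude * xfrac +
    ridge_amplitude * sin(pi * xfrac)
  raster_grid(grid, matrix(profile, grid$n_rows, grid$n_cols, byrow = TRUE))
}

#' Simulate occurrence points dispersing from source locations
#'
#' Each point picks a source by weight, a uniform bearing, and a dispersal
#' distance from the chosen kernel (`exponential`: mean = `scale_km`;
#' `gaussian`: half-normal with sd = `scale_km`), then is displaced along
#' the great circle. When a DEM is supplied, points are assigned the
#' elevation of their cell, and points landing outside the grid or above
#' `max_elevation` are resampled, keeping n exact (the surveyed population
#' was never found above 600 m a.s.l.).
#'
#' @param n Number of occurrence records.
#' @param sources Data.frame with `lon`, `lat` and optional `weight`.
#' @param kernel `"exponential"` or `"gaussian"`.
#' @param scale_km Kernel scale in kilometres.
#' @param dem Optional [raster_grid()] of elevations.
#' @param max_elevation Resampling ceiling when a DEM is present (default
#'   600 m).
#' @param year Survey year stamped on the records.
#' @param seed RNG seed.
#' @return An [occurrence_records()] data.frame of `n` infested sites.
#' @export
gen_occurrences <- function(n, sources, kernel = c("exponential", "gaussian"),
                            scale_km = 5, dem = NULL, max_elevation = 600,
                            year = 2019L, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(n >= 1, all(c("lon", "lat") %in% names(sources)))
  w <- if ("weight" %in% names(sources)) sources$weight
       else rep(1, nrow(sources))
  set.seed(seed)
  lon <- numeric(n); lat <- numeric(n); elev <- numeric(n)
  draw <- function() {
    s <- sample.int(nrow(sources), 1, prob = w)
    b <- stats::runif(1, 0, 360)
    d <- switch(kernel,
                exponential = stats::rexp(1, rate = 1 / scale_km),
                gaussian = abs(stats::rnorm(1, 0, scale_km)))
    p <- geosphere::destPoint(c(sources$lon[s], sources$lat[s]), b,
                              d * 1000, r = EARTH_RADIUS_KM * 1000)
    c(p[1], p[2])
  }
  for (i in seq_len(n)) {
    repeat {
      p <- draw()
      if (is.null(dem)) { lon[i] <- p[1]; lat[i] <- p[2]; elev[i] <- 0; break }
      idx <- cell_index(dem$grid, p[1], p[2])
      if (is.na(idx[1])) next
      e <- dem$values[idx[1], idx[2]]
      if (is.na(e) || e > max_elevation || e < 0) next
      lon[i] <- p[1]; lat[i] <- p[2]; elev[i] <- e
      break
    }
  }
  occurrence_records(data.frame(
    site_id = sprintf("SYN%04d", seq_len(n)),
    longitude = lon, latitude = lat, elevation_m = elev,
    site_type = sample(c("warehouse", "orchard", "farm"), n, replace = TRUE),
    year = year, infested = TRUE, stringsAsFactors = FALSE))
}

#' Draw an ordered stream of haplotype labels
#'
#' Multinomial sampling at fixed frequencies; the default emulates a
#' two-haplotype population at 53.8% / 46.2%.
#'
#' @param n Number of samples (0 returns an empty vector).
#' @param freqs Named vector of haplotype frequencies summing to 1.
#' @param seed RNG seed.
#' @return Character vector of haplotype labels in sampling order.
#' @export
gen_haplotype_samples <- function(n, freqs = c(A = 0.538, B = 0.462),
                                  seed = 1L) {
  stopifnot(n >= 0, !is.null(names(freqs)))
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (n == 0) return(character(0))
  set.seed(seed)
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

substitute_sites <- function(seq_vec, sites) {
  bases <- c("A", "C", "G", "T")
  for (s in sites) {
    seq_vec[s] <- sample(setdiff(bases, seq_vec[s]), 1)
  }
  seq_vec
}

#' Generate grouped alignments at controlled divergences
#'
#' One random ancestral sequence is drawn; each group's ancestor derives
#' from it by substitutions at `round(between_divergence/2 * length)` sites,
#' with site sets disjoint across groups, so any two group ancestors differ
#' at almost exactly `between_divergence` of sites. Within each group,
#' `n_variants` haplotypes derive from the group ancestor by
#' `round(within_divergence/2 * length)` substitutions each (variant 1 is
#' the ancestor itself), and individuals are assigned to variants
#' round-robin. Zero divergences yield identical sequences.
#'
#' @param length Alignment length in bp (default 1448, the extended COI
#'   region).
#' @param groups Data.frame with columns `name`, `n_seqs`, `n_variants`,
#'   `within_divergence` (proportion).
#' @param between_divergence Target between-group p-distance (proportion,
#'   <= 0.25).
#' @param seed RNG seed.
#' @return An [aligned_sequences()] data.frame with `group` filled in.
#' @export
gen_alignment <- function(length = 1448L, groups, between_divergence = 0.13,
                          seed = 1L) {
  stopifnot(all(c("name", "n_seqs", "n_variants", "within_divergence")
                %in% names(groups)),
            between_divergence >= 0, between_divergence <= 0.25)
  set.seed(seed)
  k <- nrow(groups)
  root <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  per_group_subs <- round(between_divergence / 2 * length)
  if (k * per_group_subs > length)
    stop("alignment too short for the requested between-group divergence")
  site_pool <- sample.int(length)  # disjoint site allocation across groups

  ids <- character(0); seqs <- character(0); grp <- character(0)
  for (g in seq_len(k)) {
    take <- if (per_group_subs > 0)
      site_pool[seq.int((g - 1) * per_group_subs + 1, g * per_group_subs)]
    else integer(0)
    anc <- substitute_sites(root, take)
    w_subs <- round(groups$within_divergence[g] / 2 * length)
    variants <- vector("list", groups$n_variants[g])
    variants[[1]] <- anc
    if (groups$n_variants[g] > 1)
      for (v in seq.int(2, groups$n_variants[g]))
        variants[[v]] <- substitute_sites(anc, sample.int(length, w_subs))
    assign_v <- rep_len(seq_len(groups$n_variants[g]), groups$n_seqs[g])
    for (i in seq_len(groups$n_seqs[g])) {
      ids <- c(ids, sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", groups$name[g]), i))
      seqs <- c(seqs, paste(variants[[assign_v[i]]], collapse = ""))
      grp <- c(grp, groups$name[g])
    }
  }
  aligned_sequences(ids, seqs, group = grp)
}

#' Generate fruit inspection records
#'
#' Per category: `n_sites` sites with `fruits_per_site` fruits each; each
#' fruit is sap-beetle infested with the category's probability. Infested
#' fruits carry a zero-truncated geometric beetle count (mean
#' `beetle_mean`), fine frass (<= 0.1 mm) and kernel damage, and a sheath
#' crack with probability 0.8; with probability `moth_coinfestation`
#' (default 0.03, the co-infestation rate the surveillance observed) they
#' additionally carry live moth stages and silk.
#'
#' @param category_probs Named vector of infestation probabilities, names
#'   among `sorted`, `unsorted`, `discarded`, `ground`.
#' @param n_sites Sites per category.
#' @param fruits_per_site Fruits inspected per site.
#' @param beetle_mean Mean of the zero-truncated geometric beetle count.
#' @param moth_coinfestation Probability an infested fruit also hosts moths.
#' @param year Survey year.
#' @param seed RNG seed.
#' @return A [fruit_records()] data.frame.
#' @export
gen_fruit_records <- function(category_probs = c(sorted = 0.10,
                                                 unsorted = 0.16,
                                                 discarded = 0.32,
                                                 ground = 0.22),
                              n_sites = 5L, fruits_per_site = 20L,
                              beetle_mean = 3, moth_coinfestation = 0.03,
                              year = 2019L, seed = 1L) {
  bad <- setdiff(names(category_probs), FRUIT_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  stopifnot(all(category_probs >= 0 & category_probs <= 1),
            beetle_mean >= 1)
  set.seed(seed)
  rows <- list()
  for (cat in names(category_probs)) {
    p <- category_probs[[cat]]
    for (s in seq_len(n_sites)) {
      site <- sprintf("%s_site%02d", cat, s)
      for (f in seq_len(fruits_per_site)) {
        infested <- stats::runif(1) < p
        if (infested) {
          total <- stats::rgeom(1, prob = 1 / beetle_mean) + 1L
          adults <- stats::rbinom(1, total, 0.3)
          larvae <- total - adults
          if (adults + larvae == 0L) larvae <- 1L
          moth <- stats::runif(1) < moth_coinfestation
          rows[[length(rows) + 1L]] <- data.frame(
            fruit_id = sprintf("%s_f%03d", site, f), site_id = site,
            year = year, category = cat,
            sap_beetle_adults = adults, sap_beetle_larvae = larvae,
            moth_stages_present = moth, silk_threads = moth,
            frass_diameter_mm = stats::runif(1, 0.02, 0.1),
            kernel_damaged = TRUE,
            sheath_crack = stats::runif(1) < 0.8)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            fruit_id = sprintf("%s_f%03d", site, f), site_id = site,
            year = year, category = cat,
            sap_beetle_adults = 0L, sap_beetle_larvae = 0L,
            moth_stages_present = FALSE, silk_threads = FALSE,
            frass_diameter_mm = NA_real_, kernel_damaged = FALSE,
            sheath_crack = FALSE)
        }
      }
    }
  }
  fruit_records(do.call(rbind, rows))
}
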