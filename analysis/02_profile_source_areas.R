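#!/usr/bin/env Rscript
# Stage 2 — geographic profiling of the introduction area.
#
# Scores the grid by bootstrap-aggregated distance decay from the infested
# sites (30 replicates on 25-75% subsamples, per-replicate rescaling, mean
# surface), restricts the mean surface to the 0-600 m a.s.l. band, and
# extracts ranked candidate source areas. With the single-source bundle of
# stage 1, the rank-1 peak should land within a few cells of the true
# source at (14.30, 40.70).

suppressMessages(library(sapsource))

seed <- 20240101L
syn <- "results/synthetic"
dir.create("results", showWarnings = FALSE)

dem <- read_asc_grid(file.path(syn, "dem.asc"))
occ <- read_occurrences(file.path(syn, "occurrences.csv"))

surface <- bootstrap_profile(occ, dem$grid, dragnet_params(1.0),
                             bootstrap_params(30L, 0.25, 0.75,
                                              seed = seed + 10L))
masked <- apply_elevation_mask(surface, dem, max_elevation = 600)
write_asc_grid(masked, "results/profile_masked.asc")

areas <- extract_source_areas(masked, quantile_threshold = 0.95,
                              merge_radius_km = 3.0)
write.csv(areas[, setdiff(names(areas), "cells")],
          "results/source_areas.csv", row.names = FALSE)

err <- haversine_km(areas$peak_lon[1], areas$peak_lat[1], 14.30, 40.70)
cat(sprintf("%d candidate source area(s); rank-1 peak (%.3f, %.3f), score %.3f\n",
            nrow(areas), areas$peak_lon[1], areas$peak_lat[1],
            areas$peak_score[1]))
cat(sprintf("rank-1 peak sits %.2f km from the true simulated source\n", err))
cat(sprintf("masked cells (outside 0-600 m): %d of %d\n",
            sum(!masked$mask), length(masked$mask)))
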