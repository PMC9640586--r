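#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study bundle.
#
# Emulates the field conditions of the walnut sap-beetle outbreak analysis:
# infested sites dispersed from a single introduction point over a coastal
# elevation gradient (the surveyed population was never found above 600 m
# a.s.l.), a two-haplotype COI population near 54/46, a two-group COI
# alignment at a ~12.9% between-group p-distance, and fruit inspections at
# the per-category infestation rates of the surveillance tables.
# Everything downstream reads the files this stage writes.

suppressMessages(library(sapsource))

seed <- 20240101L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

grid <- grid_spec(14.0, 14.6, 40.4, 41.0, cell_size = 0.01)
dem <- gen_dem(grid, base_elevation = 50, ramp_amplitude = 900)
write_asc_grid(dem, file.path(out, "dem.asc"))

source_pt <- data.frame(lon = 14.30, lat = 40.70)
occ <- gen_occurrences(50, source_pt, "exponential", scale_km = 5,
                       dem = dem, max_elevation = 600, seed = seed)
write_occurrences(occ, file.path(out, "occurrences.csv"))

haps <- gen_haplotype_samples(67, c(A = 0.538, B = 0.462), seed = seed + 1L)
writeLines(haps, file.path(out, "haplotype_stream.txt"))

groups <- data.frame(name = c("lineage1", "lineage2"),
                     n_seqs = c(7L, 6L), n_variants = c(2L, 2L),
                     within_divergence = c(0.005, 0.005))
aln <- gen_alignment(1448L, groups, between_divergence = 0.129,
                     seed = seed + 2L)
write_fasta(aln, file.path(out, "alignment.fasta"))
write.table(aln[, c("seq_id", "locality", "group")],
            file.path(out, "alignment_meta.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

fruits <- gen_fruit_records(c(sorted = 0.10, unsorted = 0.16,
                              discarded = 0.32, ground = 0.22),
                            n_sites = 5L, fruits_per_site = 20L,
                            beetle_mean = 3, moth_coinfestation = 0.03,
                            seed = seed + 3L)
write_fruit_records(fruits, file.path(out, "fruits.csv"))

cat(sprintf("wrote %s: DEM %dx%d, %d occurrences (true source %.2f, %.2f),\n",
            out, grid$n_rows, grid$n_cols, nrow(occ),
            source_pt$lon, source_pt$lat))
cat(sprintf("  %d haplotype samples, %d aligned sequences, %d fruit records\n",
            length(haps), nrow(aln), nrow(fruits)))
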