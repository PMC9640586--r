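# End-to-end pipeline driver: generate (or load) inputs, then run damage
# classification, surveillance summaries, haplotype statistics, group
# distances, geographic profiling, elevation masking and hotspot
# extraction, writing outputs and a machine-readable run report.

#' Default pipeline configuration
#'
#' The defaults are the study conditions of the analysis chain: 30
#' bootstrap replicates on 25-75% subsamples, exponential kernel profiling
#' normalised by mean pairwise distance, a 600 m a.s.l. elevation ceiling,
#' a 0.95 hotspot quantile with 3 km peak merging, and two haplotypes near
#' 54/46.
#'
#' @param seed Root seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return A named list, amendable before passing to [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("sapsource_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    grid = grid_spec(14.0, 14.6, 40.4, 41.0, cell_size = 0.01),
    sources = data.frame(lon = 14.3, lat = 40.7, weight = 1),
    n_occurrences = 50L,
    kernel = "exponential",
    kernel_scale_km = 5,
    dem_base = 100, dem_ramp = 700, dem_ridge = 0,
    max_elevation = 600,
    decay_coefficient = 1.0,
    n_replicates = 30L, fraction_low = 0.25, fraction_high = 0.75,
    hotspot_quantile = 0.95, merge_radius_km = 3.0,
    n_haplotype_samples = 67L,
    haplotype_freqs = c(A = 0.538, B = 0.462),
    beta = 0.95,
    alignment_length = 1448L,
    alignment_groups = data.frame(
      name = c("groupA", "groupB"), n_seqs = c(6L, 6L),
      n_variants = c(2L, 2L), within_divergence = c(0.005, 0.005)),
    between_divergence = 0.129,
    distance_boot_reps = 100L,
    fruit_category_probs = c(sorted = 0.10, unsorted = 0.16,
                             discarded = 0.32, ground = 0.22),
    fruit_sites_per_category = 5L, fruits_per_site = 20L,
    beetle_mean = 3, moth_coinfestation = 0.03
  )
}

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Executes, in order: simulate (DEM, occurrences, haplotype stream,
#' alignment, fruit records), classify, summarize, hapstats, pdist,
#' profile, mask, hotspots. Each stage's outputs are written under
#' `config$out_dir`; a JSON run report (inputs, seed, parameters, output
#' MD5 hashes) makes reruns auditable. Any stage error aborts with a
#' message naming the stage.
#'
#' @param config A [pipeline_config()] list.
#' @return The run report, invisibly (list with `stages`, `seed`,
#'   `outputs`, `hashes`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  outputs <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stages <<- c(stages, name)
    res
  }
  emit <- function(path) { outputs <<- c(outputs, path); path }
  out <- function(f) file.path(config$out_dir, f)

  sim <- stage("simulate", {
    dem <- gen_dem(config$grid, config$dem_base, config$dem_ramp,
                   config$dem_ridge)
    occ <- gen_occurrences(config$n_occurrences, config$sources,
                           config$kernel, config$kernel_scale_km,
                           dem = dem, max_elevation = config$max_elevation,
                           seed = config$seed)
    haps <- gen_haplotype_samples(config$n_haplotype_samples,
                                  config$haplotype_freqs,
                                  seed = config$seed + 1L)
    aln <- gen_alignment(config$alignment_length, config$alignment_groups,
                         config$between_divergence, seed = config$seed + 2L)
    fruits <- gen_fruit_records(config$fruit_category_probs,
                                config$fruit_sites_per_category,
                                config$fruits_per_site, config$beetle_mean,
                                config$moth_coinfestation,
                                seed = config$seed + 3L)
    emit(write_asc_grid(dem, out("dem.asc")))
    emit(write_occurrences(occ, out("occurrences.csv")))
    emit(write_fasta(aln, out("alignment.fasta")))
    emit(write_fruit_records(fruits, out("fruits.csv")))
    list(dem = dem, occ = occ, haps = haps, aln = aln, fruits = fruits)
  })

  classified <- stage("classify", classify_damage(sim$fruits))
  utils::write.csv(classified[, c("fruit_id", "site_id", "year", "category",
                                  "label", "rule_fired")],
                   emit(out("damage_labels.csv")), row.names = FALSE)

  summaries <- stage("summarize", {
    s <- site_infestation_summary(classified)
    ct <- category_damage_table(classified)
    utils::write.csv(s$by_year, emit(out("site_summary.csv")),
                     row.names = FALSE)
    utils::write.csv(ct, emit(out("category_table.csv")), row.names = FALSE)
    list(sites = s, categories = ct)
  })

  hapstats <- stage("hapstats", {
    trace <- iterative_sufficiency(sim$haps, beta = config$beta)
    utils::write.csv(as.data.frame(trace), emit(out("sufficiency_trace.csv")),
                     row.names = FALSE)
    trace
  })

  pdist <- stage("pdist", {
    gd <- group_distance_matrix(sim$aln,
                                bootstrap_reps = config$distance_boot_reps,
                                seed = config$seed + 4L)
    utils::write.csv(gd$between, emit(out("between_distances.csv")))
    gd
  })

  profile <- stage("profile", bootstrap_profile(
    sim$occ, config$grid,
    dragnet_params(config$decay_coefficient),
    bootstrap_params(config$n_replicates, config$fraction_low,
                     config$fraction_high, seed = config$seed + 5L)))

  masked <- stage("mask", apply_elevation_mask(profile, sim$dem,
                                               config$max_elevation))
  emit(write_asc_grid(masked, out("profile_masked.asc")))

  hotspots <- stage("hotspots", extract_source_areas(
    masked, config$hotspot_quantile, config$merge_radius_km))
  utils::write.csv(hotspots[, setdiff(names(hotspots), "cells")],
                   emit(out("source_areas.csv")), row.names = FALSE)

  report <- list(
    stages = stages,
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("grid", "sources", "alignment_groups"))],
    outputs = basename(outputs),
    hashes = as.list(tools::md5sum(outputs))
  )
  names(report$hashes) <- basename(outputs)
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(report, list(
    summaries = summaries, hapstats = hapstats, pdist = pdist,
    hotspots = hotspots, surface = masked)))
}
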