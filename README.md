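# sapsource

Source-area profiling and molecular surveillance for sap-beetle invasions.

When an invasive sap beetle (Nitidulidae, *Carpophilus*) erupts across a
region's walnut orchards and warehouses, the first analytical questions
are: where did the spread most likely start, has the molecular survey
sampled enough individuals to capture the population's haplotype
diversity, and which fruit damage is attributable to the beetle rather
than to co-occurring moths. `sapsource` implements that analysis chain as
a tested R package:

* **Geographic profiling** — every infested site adds a no-buffer
  negative-exponential distance-decay kernel; the cell score is
  `s(c) = (1/N) Σ_i exp(−β·d(c, x_i)/σ)` with `d` the haversine distance
  (sphere radius 6371.0088 km) and `σ` the mean pairwise occurrence
  distance. Robustness comes from bootstrap aggregation (30 replicates on
  25–75% subsamples, per-replicate rescaling, cell-wise mean), the final
  surface is restricted to the 0–600 m a.s.l. band, and ranked candidate
  source areas are extracted by quantile thresholding, 8-connectivity
  clustering and 3 km peak merging.
* **Haplotype sufficiency** — the coalescent closed form
  `p = (n−1)/(n+1)` for the probability a sample of `n` contains every
  haplotype, its integer inverse, the detection sample size
  `n = ln(1−β)/ln(1−p)`, and the iterative frequency-updating procedure
  over an ordered sample stream.
* **Genetic distances** — uncorrected p-distance with pairwise deletion,
  group-wise within/between matrices with site-bootstrap SEs, "n.c." for
  singleton groups, and the aggregate summaries barcoding tables quote
  (with truncation-style printing).
* **Damage attribution** — fixed-precedence rules (live stages; silk or
  frass > 0.5 mm → moth; fine frass ≤ 0.1 mm → sap beetle; the uncovered
  (0.1, 0.5] mm gap → undetermined) plus site-level and per-category
  surveillance summaries.
* **Synthetic data** — seeded generators for occurrence points dispersed
  from sources over an elevation raster, haplotype streams, grouped
  alignments at controlled divergences, and fruit inspections, so the
  whole chain runs and is testable without field data.

## Worked example

The numbered scripts under `analysis/` run the full chain on a synthetic
bundle (stage 1 writes it, stages 2–5 read it back through the package's
file readers):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_profile_source_areas.R
Rscript analysis/03_haplotype_sufficiency.R
Rscript analysis/04_genetic_distances.R
Rscript analysis/05_damage_surveillance.R
```

Stage 2 profiles 50 infested sites dispersed from a single source at
(14.30, 40.70) with a 5 km exponential kernel and prints:

```
1 candidate source area(s); rank-1 peak (14.305, 40.695), score 0.994
rank-1 peak sits 0.70 km from the true simulated source
masked cells (outside 0-600 m): 1380 of 3600
```

i.e. the bootstrap-mean argmax lands in the cell containing the true
source (0.70 km is the offset of that cell's centre), and the elevation
mask removed the cells of the synthetic DEM outside the 0–600 m band.
Stage 3 reports the sampling-sufficiency answers:

```
observed haplotype frequencies over 67 samples: A 52.2%, B 47.8%
p(all haplotypes seen | n = 67) = 0.971
samples needed for p = 0.95: 39
iterative detection sample size (beta = 0.95): 4.61 (ceil 5)
```

so 39 samples would have sufficed to see every haplotype with 95%
probability, and about 5 samples per locality exclude the rarer haplotype
at 95% confidence given its running frequency. Stage 4 recovers the
generator's 12.9% between-lineage divergence (13.04 ± 0.94%) and
reproduces the published reference-table aggregates (mean between-species
distance 14.8%, extremes 18.49% and 10.33%, mean within-species 1.39%).

The same operations are available directly:

```r
library(sapsource)
prob_all_haplotypes_sampled(39)        # 0.95
min_detection_sample_size(0.462, 0.95) # 4.83
s <- matrix_summaries(carpophilus_reference_distances())
percent_format(s$mean_between, 1)      # 14.8
```

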