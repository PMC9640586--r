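---
title: "Methods: source-area profiling and molecular surveillance of a sap-beetle invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-area profiling and molecular surveillance of a sap-beetle invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapsource)
```

## The problem

When an invasive insect population surfaces across a region, three questions
drive the first response: *where did it start spreading from*, *has the
molecular survey sampled enough individuals to characterise its genetic
variability*, and *which of the damage seen in the field is actually its
doing*. `sapsource` implements one coherent analysis chain for these
questions, modelled on the surveillance of a nitidulid sap beetle
(*Carpophilus truncatus*) infesting walnut fruits: geographic profiling of
infested sites, haplotype sampling-sufficiency statistics, group-wise
uncorrected p-distances for molecular identification, and fruit-level
damage-attribution rules — plus synthetic-data generators so the whole chain
is testable end to end without field records, which for this kind of study
are typically not published at coordinate precision.

## Geographic profiling

### Model

Each infested site contributes a distance-decay kernel to every grid cell.
The score of a cell with centre $c$ given occurrences $x_1, \dots, x_N$ is

$$ s(c) \;=\; \frac{1}{N} \sum_{i=1}^{N} \exp\!\left(-\beta \,
   \frac{d(c, x_i)}{\sigma}\right), $$

with $d$ the haversine distance on a sphere of radius 6371.0088 km. This is
the no-buffer (Dragnet-style) member of the geographic-profiling family: the
kernel is maximal at zero distance, appropriate for a pest whose spread is
driven by human transport of infested produce rather than by the insect's
own (limited) flight. Algorithms with a buffer zone — a suppressed region
around the origin, as in criminal geographic targeting — are deliberately
out of scope.

The published account of this analysis names the algorithm family but not
its kernel constants, so both are explicit parameters with documented
defaults:

* $\beta$ (`decay_coefficient`, default 1.0) — dimensionless decay rate.
* $\sigma$ — the mean pairwise distance among the occurrences (default),
  which makes $\beta$ scale-free: profiles of a 10 km outbreak and a 100 km
  outbreak are directly comparable. `normalize_by = "none"` fixes
  $\sigma = 1$ km instead.

Each infested *site* contributes one point regardless of how many specimens
it yielded: the method profiles localities, not individuals.

### Bootstrap aggregation

A single profile is sensitive to individual sites. Robustness comes from
bootstrap aggregation: 30 replicates, each scoring a random subsample whose
fraction is drawn uniformly between 25% and 75% of the data (subsample size
$m = \max(2, \mathrm{round}(uN))$; the floor of 2 keeps $\sigma$
computable). Each replicate surface is min–max rescaled to $[0, 1]$ before
averaging so that replicates with different subsample sizes contribute
comparably; the cell-wise mean is the final surface, whose high-score
envelope plays the role of a confidence region around the top-priority
cells. One root seed deterministically spawns one child seed per replicate,
so runs are reproducible and replicates independent.

### Elevation restriction and source areas

Because the surveyed population was never found above 600 m a.s.l., the
*final mean surface* (not the individual replicates) is restricted to the
0–600 m band: cells above the ceiling or below sea level are masked, and
surviving scores are untouched. The band is inclusive at 600 m.

Candidate source areas are the connected components (8-connectivity) of
cells at or above a score quantile (default 0.95) of the valid cells;
components whose peak cells lie within 3 km are merged (single linkage),
and areas are ranked by peak score. Ties are broken by (row, col)
lexicographic order of the peak cell — an explicit, documented rule so that
outputs are deterministic. The rank-1 area is the most likely area of
origin.

### Grid and distance choices

The grid is a regular WGS84 lon/lat raster addressed by cell centres, row 1
northernmost, default cell 0.01° (roughly 0.8–1.1 km at mid-latitudes).
Haversine on a sphere is used throughout; over a ~100 km study extent the
error against an ellipsoidal distance is far below one cell width.

## Haplotype sampling sufficiency

Two closed forms answer the survey-design questions:

1. **Have we seen everything?** Under the standard coalescent, a sample of
   $n$ sequences contains every haplotype segregating in the population with
   probability $p = (n-1)/(n+1)$ (`prob_all_haplotypes_sampled()`); its
   inverse `min_n_for_prob()` returns the smallest $n$ reaching a target
   probability — 39 samples for $p = 0.95$.
2. **How many samples exclude a haplotype?** A haplotype at frequency $p$
   escapes a sample of $n$ with probability $(1-p)^n$, so detecting it with
   confidence $\beta$ needs $n = \ln(1-\beta)/\ln(1-p)$
   (`min_detection_sample_size()`). The value is returned as a real number —
   survey reports quote non-integer values — with a ceiling flag for
   planning an actual sample.

`iterative_sufficiency()` runs the second formula as an accumulating survey
would: after each new sample the observed frequencies are updated, $p$ is
set to the frequency of the *rarest* haplotype seen so far (the conservative
reading of "the frequency of a given haplotype"), and $n$ is re-evaluated.
While only one haplotype has been seen the formula is undefined ($p$ would
be 1) and the trace records the step as not computable. $\beta$ defaults to
0.95; published uses of this procedure do not always state their $\beta$, so
it is an explicit argument.

Haplotype identity is exact string match after uppercasing: a sequence
bearing an ambiguity code is its own haplotype unless identical to another.
This is conservative and reproducible; difference *counts* instead use
pairwise deletion (below), so an N never inflates a distance.

## Genetic distances

`p_distance()` is the uncorrected proportion of differing sites, comparing
only sites where both sequences carry an unambiguous base (pairwise deletion
of gaps and ambiguity codes). `group_distance_matrix()` averages it over all
cross-group pairs (between) and intra-group pairs (within), in percent, with
singleton groups marked not calculable — the "n.c." convention of barcoding
distance tables. Standard errors come from a bootstrap over alignment
columns (default 500 replicates, seeded): resample sites with replacement,
recompute every statistic, report the SD across replicates. SEs are reported
on the same percent scale as the distances; published tables of this kind
sometimes print SEs that appear to be on the proportion scale instead, an
ambiguity worth checking before comparing SE magnitudes.

`matrix_summaries()` reduces a matrix to the aggregates such studies quote:
mean/extremes of the 28 between-group entries (each species pair weighted
equally) and of the computable diagonal. `percent_format()` offers both
truncation and rounding because published aggregates of this table family
are truncated (a mean of 1.3957 printed as 1.39). The package ships the
published reference matrix for the eight-species *Carpophilus* COI group
(`carpophilus_reference_distances()`) so the summary path can be validated
against printed values.

## Damage attribution and surveillance summaries

Fruit-level evidence is attributed by fixed-precedence rules: live stages
decide first (both taxa → `both`, else whichever is present); without live
insects, silk threads or frass coarser than 0.5 mm indicate moths, and fine
frass (≤ 0.1 mm, kernel residue and excrement) indicates sap beetles. Frass
in the (0.1, 0.5] mm gap with no other evidence is labelled `undetermined`
— no stated rule covers it, and the package never silently attributes. The
rule that fired is recorded per fruit.

A site counts as infested when at least one fruit is attributed to the sap
beetle (`sap_beetle` or `both`); the site-level criterion is not defined in
published accounts, and this is the natural presence/absence reading.
Percentages are reported both truncated and rounded to one decimal —
truncation is the default because the surveillance reports this package
mirrors print 10/18 as 55.5%. The category table aggregates site-level
damage percentages as mean ± SE (SD/√sites) with min–max range, and beetle
loads (adults + larvae) over infested fruits only, matching tables whose
ranges start at 1.0 beetle.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with exactly the statistical structure the
chain assumes:

* `gen_dem()` — deterministic elevation surfaces (flat base, west–east
  linear ramp, optional sinusoidal ridge). A ramp gives a closed-form area
  above any threshold, so mask bookkeeping is exactly testable.
* `gen_occurrences()` — points dispersed from weighted sources by an
  isotropic exponential (mean = scale) or half-normal kernel along
  great-circle bearings; points landing above the elevation ceiling are
  resampled rather than truncated, keeping $n$ exact.
* `gen_haplotype_samples()` — multinomial draws at fixed frequencies
  (default 53.8% / 46.2%, the two-haplotype structure of the motivating
  survey).
* `gen_alignment()` — a random ancestor; group ancestors derived by
  substitutions at *disjoint* site sets of size
  $\mathrm{round}(D L / 2)$ each, so two group ancestors differ at almost
  exactly the target fraction $D$ of sites; within-group variants add
  substitutions at random sites. Disjoint placement makes divergence
  round-trips tight at integer resolution.
* `gen_fruit_records()` — per-category Bernoulli infestation, zero-truncated
  geometric beetle counts (mean 3), fine frass on infested fruits, and moth
  co-infestation at a configurable rate (default 3%).

These defaults are the study conditions the tests run under: 50 occurrences
from one source with a 5 km exponential kernel on a 0.01° grid for source
recovery; 1448 bp alignments at a 12.9% between-group target; 67 haplotype
samples at 53.8/46.2. What the generators do *not* emulate: anisotropic or
road-network dispersal, real topography, recombination or multiple-hit
saturation in sequences, and spatial correlation between infestation and
elevation beyond the hard ceiling. Passing tests therefore demonstrate that
the chain recovers the parameters of its own generative assumptions — the
standard simulation check — not that those assumptions hold in any
particular field system.

## Numerical choices and degenerate inputs

* Distances: haversine with radius 6371.0088 km everywhere, including the
  generators' point displacement, so simulated and scored geometry agree.
* A constant replicate surface min–max rescales to all zeros (no spurious
  hotspots from a flat profile).
* Bootstrap subsampling draws indices in sorted order, so the degenerate
  fraction-1.0 bootstrap reproduces the full-data surface bitwise.
* `dragnet_score()` refuses an empty occurrence set, and names the
  degenerate all-points-coincident configuration when normalisation is
  requested ($\sigma = 0$).
* An all-masked surface yields an empty source-area table, not an error.
* `min_n_for_prob()` searches integers upward from the analytic floor
  rather than trusting a floating-point ceiling at exact targets.
* File readers validate and refuse malformed input (missing header keys,
  unequal sequence lengths, unknown categories) naming the offending file
  and field; nothing is silently coerced.

## Problem sizes

The test-suite and example problem sizes — 60×60 grids, 30 bootstrap
replicates, 20 seeded recovery runs, 500-site bootstraps on 13-sequence
alignments — were chosen so the full chain (including the 20-run recovery
experiment) completes in well under a minute while leaving each stochastic
check comfortably powered; they are the package's documented defaults, and
scale linearly if users enlarge grids or replicate counts.

## Known limitations

* The profiling kernel family is fixed to the negative exponential; the
  published analysis this mirrors names no constants, so recovered source
  areas should be read as priority regions, not point estimates.
* With widely separated sources of very unequal weight, the default broad
  kernel can absorb a weak source into a neighbour's envelope; a larger
  `decay_coefficient` sharpens separation (the three-source test uses 4).
* The iterative sufficiency procedure depends on sampling order by design;
  different orders give different traces with the same final value whenever
  final counts agree.
* Damage attribution is rule-based and deterministic; it cannot express
  partial confidence, and the `undetermined` class is irreducible without
  further evidence.
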