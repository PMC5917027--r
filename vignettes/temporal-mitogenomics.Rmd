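---
title: "Temporal mitogenome diversity and serial-coalescent ABC"
author: "mitotempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal mitogenome diversity and serial-coalescent ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotempo)
```

## The problem

Museum collections make it possible to compare the genetic diversity of a
population *before* and *after* a suspected decline. For endangered taxa
such as the eastern gorillas, complete mitochondrial genomes can be
recovered from century-old skins and skulls and compared with genomes from
modern faecal sampling. Two statistical obstacles stand in the way:

1. the historical and modern groups have very different sample sizes, so
   raw diversity comparisons are confounded by sampling depth; and
2. the decline, if any, happened only a few maternal generations ago, so
   classical long-time-scale inference (skyline plots and the like) has
   essentially no resolution and a *serially sampled* (heterochronous)
   model is needed in which museum specimens enter the genealogy at their
   collection ages.

`mitotempo` implements the complete analysis path: alignment hygiene
(D-loop masking, missing-data filtering), haplotype and diversity
statistics, permutation subsampling for unequal sample sizes, minimum
spanning haplotype networks, a heterochronous coalescent simulator for
mitochondrial (female-line, haploid) inheritance, and approximate Bayesian
computation (ABC) for choosing among recent demographic models and
estimating past versus present female effective population size, with
pseudo-observed datasets (PODs) to quantify how much power the design
actually has.

## Diversity statistics

All statistics treat `N` and `-` as missing and resolve pairs of sequences
over the sites resolved in both (pairwise deletion).

* Haplotype (gene) diversity: `Hd = n/(n-1) (1 - sum p_i^2)`, the corrected
  probability that two random sequences carry different haplotypes.
* Mean pairwise differences `k_bar` and per-site nucleotide diversity
  `pi = k_bar / mean pairwise-resolved length`.
* Tajima's D in the standard 1989 form, from total segregating sites `S`
  and `k_bar`; it is reported as undefined (`NA` with a warning) when
  `S = 0` rather than silently 0.
* Hudson's FST, `1 - Hw/Hb`, with `Hw` the average of the two within-group
  mean pairwise differences and `Hb` the between-group mean, all means over
  distinct pairs. This unbiased form gives `-1/(n-1)` (not exactly 0) for
  two groups of identical composition; the package returns the raw value
  and leaves any clipping to the caller.

**Haplotypes with missing data.** Museum genomes contain `N` runs, and an
exact-string definition of "haplotype" would count every distinct
missingness pattern as a new haplotype. The default `compatible` rule
therefore merges a sequence into a haplotype when it has zero differences
over shared resolved sites with *every* current member, seeding each
haplotype with the most complete sequence (deterministic order, ties broken
by id). The source data for such studies do not state which convention was
used, so a `strict` mode (drop every column with any missing data, then
exact match) is available; on complete data the two coincide.

**Variant classification.** Each biallelic segregating site is labelled
transition/transversion, located in its annotation context (coding, rRNA,
tRNA, non-coding), and for coding sites translated with the vertebrate
mitochondrial genetic code against the majority-rule consensus codon;
amino-acid changes are scored with the PAM250 matrix (score >= 0 flagged as
a change commonly observed in nature) and stop gains are flagged
separately. Sites with three or more alleles are reported as
`multiallelic` and excluded from the Ts/Tv tally.

**Networks.** The minimum spanning network is built over resolved-site
distances between haplotype representatives, adding edges one weight class
at a time and keeping *all* edges of a class that connect components
distinct at the start of that class (the epsilon = 0 network drawn by
standard haplotype-network software). Edges are processed in
(weight, label, label) order, so output is deterministic.

## Permutation subsampling

To compare groups of unequal size, each group is repeatedly subsampled
*without replacement* to a common size (default: the smallest group,
`n = 8` in the emulated design; 1000 replicates) and the statistic is
recomputed. Two groups are then compared with Welch's t-test on the
replicate distributions — mirroring common practice — but the replicates
are resamples of the same individuals, not independent observations, so the
label-permutation p-value reported alongside is the preferred inferential
quantity.

## The serial coalescent simulator

Mitochondrial DNA is maternally inherited and effectively haploid, so the
relevant size parameter is the number of breeding females `N_f`. Backward
in time, `k` active lineages coalesce at rate `k(k-1)/2 * 1/N(t)` per
generation; a lineage sampled `a` years before present activates only at
age `a / generation_time`. `N(t)` is piecewise constant with a single
change at `t_change`: `N_present` toward the present, `N_historical`
beyond. Waiting times are redrawn at activation and epoch boundaries,
valid by memorylessness. Calibration facts used as tests: a contemporary
pair coalesces on average `N` generations ago; a pair sampled 500
generations apart at `2N = 2000` averages 1500 generations; and the
two-epoch expectation follows the piecewise-exponential integral.

**Mutation model.** Substitutions are dropped on branches as
`Poisson(length_generations * mu_gen * L)` events, each hitting a uniform
site of the `L`-site sequence (finite sites: repeat hits allowed — at 15 kb
and mitochondrial rates multiple hits are rare but real). An event is a
transition with probability `R/(R+1)` where `R` is the expected
transition:transversion *count* ratio (the source software does not define
its parameterization; this is the natural count-ratio reading), otherwise
one of the two transversions uniformly. Base frequencies are symmetric and
there is no rate heterogeneity ("no gamma"), i.e. a K80-like process. The
default rate `1.28e-8` per site comes from a deep-time (million-year)
calibration and is therefore interpreted per *year* and converted with the
generation time (default 20 y, hence `2.56e-7` per site per generation);
because the units are not stated by the sources, `rate_units =
"per_generation"` disables the conversion.

## ABC

Eight summary statistics compare the temporal groups: haplotype counts,
private-haplotype counts, and genetic diversity for each group, plus mean
pairwise differences and Hudson's FST between groups. "Genetic diversity"
is haplotype diversity by default (`gd = "pi"` switches to nucleotide
diversity); a comparison with no variation within or between groups
reports FST 0 by convention, applied identically to observed and simulated
data so no distance is distorted.

Three demographic models are compared: constant size, a single decline,
and a single expansion, with the change uniformly in `[30, 110]` years
before present. Priors on the two epoch sizes are log-uniform on
`[1e2, 1e5]` females — the sources do not print their size priors, so the
package defaults to a scale-free prior spanning plausible great-ape
matrilineal sizes; both the range and the change-time window are
configurable and echoed into outputs.

The reference table standardizes every statistic by its table-wide SD
(statistics with zero SD are skipped), ranks rows by Euclidean distance to
the observed vector, and accepts the closest `ceiling(p * n)` rows, ties
broken by row index. Model posteriors are accepted-row fractions, reported
across several acceptance proportions as a consistency check (the headline
default mirrors ten log-spaced proportions on `[5e-5, 5e-4]`). Parameter
estimation applies a Beaumont-style local-linear regression adjustment:
log sizes (change time raw) are regressed on standardized statistics with
Epanechnikov weights in distance and projected to the observed point;
rank-deficient designs are handled by pivoting, and posterior summaries
(weighted median and equal-tailed 95% interval of the reduction factor
`N_historical / N_present`) use the regression weights.

**PODs.** `run_pods()` simulates datasets with known truth, pushes each
through model choice and estimation against the same reference table, and
reports the fraction of PODs whose top model (at the median acceptance
proportion) is the truth, the mean posterior of the truth, the coverage of
the nominal-95% ratio interval, and the median absolute log ratio error.
`pod_power_grid()` sweeps reduction factors `{1, 2.5, 4.5, 10}` — bracketing
the reduction magnitudes such temporal datasets typically suggest — to
check that power is non-decreasing in effect size.

## The synthetic-data generator

`builtin_design()` encodes the emulated sampling structure: 68 historical
(collection years 1910-1980) plus 29 modern (2014) sequences for the
larger group, 18 + 8 for the smaller, on 15,000-site sequences (a
mitogenome with the hypervariable D-loop removed; the exact post-mask
length of the source data is not published, so 15 kb is the package's
choice). Historical collection years are drawn uniformly within the
design's range (explicit per-sample years can be supplied); modern samples
have age 0. A bundled *synthetic* D-loop mask
(`extdata/synthetic_dloop_mask.bed`, masking 1200 of 16,200 sites) and a
*synthetic* gene map (`extdata/synthetic_mito_annotation.tsv`) let the
masking and variant-classification stages run end to end without any
reference download; both are labelled synthetic and are not the
coordinates of any real assembly.

What the generator deliberately does **not** emulate: post-mortem DNA
damage, contamination, coverage-dependent consensus errors, capture bias,
base-composition asymmetry, rate heterogeneity among sites, or population
structure within groups. Passing tests therefore demonstrate that the
statistics and inference machinery are correct and calibrated *under the
model*, not that the model captures every artefact of real museum data.

## Numerical and design choices

* Coordinates are 0-based half-open (BED convention) everywhere.
* `N` and `-` both count as missing; the missing-fraction filter drops
  sequences *strictly above* the threshold (default 0.25).
* Every stochastic routine takes an explicit seed; reference tables seed
  each row independently from the master seed, so results are identical
  for any worker count, and simulation replicates map 1:1 to rows.
* Degenerate cases follow stated conventions rather than erroring deep in
  a run: Tajima's D with `S = 0` is `NA` with a warning; a t-test between
  two zero-variance distributions returns p = 1 (equal means) or 0;
  monomorphic FST in the ABC statistics is 0; an acceptance proportion
  must leave at least one row.
* Problem sizes used by the test suite and the acceptance script —
  30,000-row reference tables (10,000 per model), 200 prior-predictive
  repeats, 100 coverage PODs, 40 PODs per power cell, 1000-2000 replicate
  Monte-Carlo calibrations — are the package's scaled defaults: large
  enough for 3-SE calibration checks while keeping a full run in minutes.
  The source analyses used tables three to five orders of magnitude
  larger; those sizes are reachable through configuration.

## Known limitations

* The coalescent allows exactly one size change; staircase or continuous
  demographies are out of scope (and are the domain of skyline methods).
* The mutation process is symmetric K80-like; HKY-style unequal base
  frequencies are not modelled.
* The regression adjustment can push the change time slightly outside its
  prior range; the raw adjusted values are returned rather than clamped.
* With sequence data this weakly informative, ABC posteriors remain close
  to the prior; the POD machinery exists precisely to make that visible
  rather than to hide it.
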