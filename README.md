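# mitotempo

Temporal population genetics of mitochondrial genomes: compare the
diversity of **historical (museum) and modern samples** of one population,
and ask — with honest error bars — whether the female effective population
size changed within the last century.

The package was built for the kind of study design used on eastern
gorillas: tens of ~15 kb mitogenomes assembled from museum skins collected
1910–1980, compared against faecal-sample mitogenomes collected in 2014.
It bundles a synthetic-data generator that emulates exactly that design,
so every stage runs and is tested without downloading any sequence data.

## What it computes

**Diversity and differentiation.** Haplotype calling with a
missing-data-aware merging rule, haplotype (gene) diversity
`Hd = n/(n−1)(1 − Σ p_i²)`, mean pairwise differences `k̄` and per-site
nucleotide diversity `π`, Tajima's *D*, Hudson's
`F_ST = 1 − H_w/H_b`, private/shared haplotype counts, variant
classification (Ts/Tv, coding effect under the vertebrate mitochondrial
code, PAM250 acceptability, stop gains), and ε = 0 minimum spanning
haplotype networks.

**Permutation subsampling.** Groups of unequal size are repeatedly
subsampled without replacement to a common size (default: the smallest
group, n = 8; 1000 replicates) before comparison; Welch's t-test and a
label-permutation p-value are reported side by side.

**Serial-coalescent ABC.** A heterochronous (serially sampled) haploid
coalescent with one recent size change — lineages activate at their
sampling age, coalescing at rate `k(k−1)/2N(t)` with `N(t)` switching from
`N_present` to `N_historical` at `t_change ∈ [30, 110]` years — plus a
finite-sites Ts/Tv-biased mutation model (rate 1.28 × 10⁻⁸ /site/year,
generation time 20 y). Rejection ABC on eight summary statistics with a
Beaumont-style local-linear regression adjustment yields model posteriors
(constant / decline / expansion) and the posterior of the reduction factor
`N_historical / N_present`. Pseudo-observed datasets (PODs) quantify the
power and CI coverage of the whole procedure.

## Worked example

```r
library(mitotempo)

design <- builtin_design("mountain", length = 4000L)      # 18 historical + 8 modern
demo   <- demographic_model("decline", N_present = 800,
                            N_historical = 3600, t_change = 70)
mut    <- mutation_model(ts_tv_bias = 0.75, length = 4000L)
study  <- generate_study(design, demo, mut, seed = 7)

groups <- partition_alignment(study$alignment, study$table, "era")
group_diversity(groups)
#>        group  n  H        Hd   k_bar          pi  S   tajima_d
#> 1 historical 18 10 0.9150327 10.4183 0.002604575 34 0.21827368
#> 2     modern  8  6 0.9285714 11.0000 0.002750000 28 0.09845614

dh <- subsample_stat(groups$historical, 8, n_reps = 1000, statistic = "Hd", seed = 1)
dm <- subsample_stat(groups$modern,     8, n_reps = 1000, statistic = "Hd", seed = 2)
compare_groups(dh, dm, seed = 3)
#> comparison of Hd: mean 0.9179 vs 0.9286 (diff -0.0106)
#>   Welch t = -7.122, p_t = 2.037e-12; permutation p = 9.999e-05

ref <- build_reference_table(3000, realize_design(design, seed = 11), mut, seed = 13)
obs <- summarize_groups(groups$modern, groups$historical)
model_posterior(ref, obs, proportions = c(0.02, 0.05, 0.1))
#> ABC model choice over 3 acceptance proportions
#>      model posterior
#>   constant      0.29
#>    decline      0.40
#>  expansion      0.31

est <- abc_estimate(ref, obs, proportion = 0.05)
cat(sprintf("reduction factor: median %.2f, 95%% CI [%.2f, %.2f]\n",
            est$reduction$median, est$reduction$ci95[1], est$reduction$ci95[2]))
#> reduction factor: median 1.81, 95% CI [0.07, 35.68]
```

Reading: the subsampled diversity comparison easily separates the two
temporal groups of this toy decline, but model choice gives the decline
only weak support (0.40 vs a prior of 1/3) and the reduction-factor
posterior is wide — a single non-recombining locus observed over ~5
maternal generations carries little information about the size change,
which is exactly what the POD machinery (`run_pods()`, `pod_power_grid()`)
makes explicit. Larger reference tables (the 3000 rows above are for a
quick demo; 30,000+ for real use) tighten the Monte-Carlo noise but not
the fundamental limit.

A programmatic pipeline runner with hashed run manifests is available as
`run_pipeline(subcommand, config)`; subcommands cover `stats`, `permute`,
`network`, `variants`, `synth`, `simulate`, `abc-build`,
`abc-modelchoice`, `abc-estimate` and `pods`.

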