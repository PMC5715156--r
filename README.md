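# generescue

Analysis toolkit for **genetic rescue** experiments: a small, inbred,
long-isolated population receives a handful of immigrant males from a
large, genetically diverged population, and the question is whether the
resulting hybrids outperform residents and whether the population recovers.
The motivating system is an endangered alpine marsupial monitored by annual
live trapping and genotyped at 24 microsatellite loci, but every component
works on generic codominant genotype tables and capture histories.

The package covers the full analysis chain:

* **Ancestry** — build a panel of *diagnostic alleles* (alleles private to
  the source population at loci with fixed differences or non-overlapping
  allele ranges) and classify individuals as resident / F1 / F2 / backcross
  from per-locus homozygosity patterns, with closed-form Mendelian
  misclassification rates.
* **Hybrid relative fitness** — expected hybrid counts under a sire-pool
  model (first cohort: `exp_h = n·m_i/(m_i+m_r)`) and a random-mating model
  (later cohorts: `exp_h = n·(1−q²)` with non-hybrid parental frequency
  `q`), the fitness ratio `w = (obs_h/exp_h)/(obs_n/exp_n)`, a label-
  resampling bootstrap CI with an exact enumeration oracle, χ² goodness of
  fit, exact binomial and one-tailed Fisher tests.
* **Diversity** — per-year `n`, `Na`, rarefied allelic richness
  `Ar = Σ_a [1 − C(N−N_a, g)/C(N, g)]`, `Ho`, `He = 1 − Σp²`, and
  Weir–Cockerham `F_IS`; temporal effective population size from
  `H_t = H_0 (1 − 1/(2N_e))^t` with a locus-bootstrap CI.
* **Abundance** — closed-population conditional-likelihood (Huggins) models
  `M0`, `Mt`, `Msex` and a two-class finite mixture `Mh2`, BIC model
  selection, and per-year abundance series from capture histories.
* **Simulation** — a forward-time Mendelian generator of the whole study
  (diverged pools, male translocation, cohorts with a configurable hybrid
  fitness advantage, imperfect trapping) so every estimator can be
  calibrated against known truth.
* **I/O** — Genepop (4- and 6-digit), genotype/individual/capture CSV,
  MARK `.inp` export.

## Worked example

The headline computation on the published cohort counts — 34 new adults in
the first post-translocation spring (13 hybrid / 21 not), sired by a pool
of 5 introduced and 21 resident males:

```r
library(generescue)

e12 <- expected_f1_counts(34, n_introduced_males = 5, n_resident_males = 21)
cohort_fitness(2012, 13, 21, e12[["exp_hybrid"]], e12[["exp_nonhybrid"]],
               B = 1000, seed = 1)
#>   year obs_hybrid obs_nonhybrid exp_hybrid exp_nonhybrid relative_fitness
#> 1 2012         13            21       6.54          27.5              2.6
#>   ci_low ci_high  p_chi2 p_exact    B seed
#> 1   1.29    4.72 0.00493 0.00779 1000    1
```

Only 6.54 F1 hybrids were expected if introduced and resident sires had
equal fitness; 13 were observed. Hybrids were therefore represented 2.6×
as strongly as non-hybrids (95% bootstrap CI 1.29–4.72), and the χ²
goodness of fit rejects equal fitness at p ≈ 0.005.

Temporal effective population size from a 76% heterozygosity drop over 14
years at 1.54 years/generation:

```r
ne_from_het_decline(H0 = 1, Ht = 0.24, years = 14, gen_time = 1.54)
#> Ne = 3.44 (t = 9.09 generations, H0 = 1.000 -> Ht = 0.240)
```

An end-to-end run on simulated data (pools tuned to He 0.14 vs 0.55, five
translocated males, hybrid fitness advantage 2.6, annual trapping):

```r
cfg <- rescue_config(simulation = sim_config(seed = 1), seed = 1)
r <- run_rescue_pipeline(cfg, "out/")
r$diversity
#>         pop year  n   Na   Ar    Ho    He     Fis
#> 1 recipient 2010 41 1.54 1.53 0.154 0.157  0.0297
#> 2 recipient 2012 34 3.79 3.79 0.479 0.417 -0.1344
#> 3 recipient 2013 45 3.75 3.68 0.403 0.410  0.0300
r$abundance
#>   year model n_observed N_hat  se_N
#> 1 2010    M0         35 38.98 2.544
#> 2 2011    M0         12 13.75 1.766
#> 3 2012    M0         36 41.24 3.058
#> 4 2013    M0         57 67.09 4.427
#> 5 2014    M0         21 22.51 1.462
```

Diversity roughly triples after the translocation while abundance grows,
and the hybrid cohorts carry fitness ratios above 1 — the signature the
simulator was configured to produce. The run directory receives
`diversity.csv`, `fitness.csv`, `ancestry_calls.csv`, `abundance.csv`,
`random_mating.csv` and a `manifest.json` (seeds, configuration, file
checksums) sufficient to reproduce every number; reruns with the same
configuration are byte-identical.

See the methods vignette
(`vignettes/genetic-rescue-analysis.Rmd`) for the models, assumptions,
numerical conventions and the simulator's design choices.

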