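# hetrep

Does heterogenizing a single-laboratory study population — composing each
laboratory's cohort of animals from several breeding sites instead of one —
make results replicate better across laboratories? `hetrep` implements the
full statistical pipeline for answering that question in multi-laboratory
mouse phenotyping studies, together with a synthetic data generator so that
every stage can be exercised, calibrated and tested without access to raw
study data.

The package is aimed at biostatisticians and researchers working on
replicability and external validity in animal research.

## The design and the models

The reference design crosses 6 test laboratories with 6 breeding sites. In
the **STA** (standardized) arm each laboratory receives its whole cohort
(n = 24) from one laboratory-specific breeding site; in the **HET**
(heterogenized) arm it receives 6 animals from each of the 5 other sites
(n = 30). Animals are pair-housed, and cagemates always share laboratory,
breeding site and arm, so the cage is the clustering unit: 324 animals, 54
per laboratory, 162 cages, with 14 outcome variables per animal (body
weight, relative adrenal weight, three elevated-plus-maze measures, nine
blood-chemistry measures).

The analysis stages are:

- **Variance decomposition** — MANOVA with Type II sums of products and
  Pillai-trace effect sizes η² = V/s, followed by per-outcome mixed models
  `y ~ breeder * lab + (1 | cage)` fitted by REML, with Satterthwaite
  degrees of freedom and semi-partial explained-variance shares, plus
  per-arm between-laboratory marginal R².
- **Discriminant classification** — Fisher LDA of the outcome battery with
  breeding site (and separately laboratory) as the class label: proportion
  of trace per discriminant and correct-classification rates against the
  1/6 ≈ 17 % chance level.
- **Variance contrasts** — per-laboratory HET/STA SD ratios and
  median-centered (Brown–Forsythe) Levene tests over all 84 lab × outcome
  contrasts, with Bonferroni control (α′ = 0.05/84 ≈ 5.9 × 10⁻⁴) and
  Fisher's combined probabilities (−2Σln p ~ χ²₂ₖ) per outcome across
  laboratories.
- **Meta-analysis** — each laboratory treated as a replicate study
  (estimate = mean of cage means, SE over cages), pooled by
  DerSimonian–Laird (or REML) random-effects meta-analysis; the
  replicability statistic is the *coverage probability*: the fraction of
  per-laboratory estimates inside the pooled 95 % CI. A mixed model with
  crossed random intercepts for outcome and laboratory measures how much of
  the standardized "dance around the means" the design arm explains.
- **Power** — the design-stage simulated-sampling procedure: per replicate,
  draw per-variable effect sizes, simulate both cohorts, take the first
  principal component of the correlation-matrix PCA over the 12 continuous
  variables, and refer the one-way ANOVA F ratio to the design-level
  threshold F(0.05; 1, 5) = 6.6.

The generator mirrors the analysis model: each outcome is drawn from
`y = μ + a_lab + b_breeder + c_lab×breeder + d_cage + e` with configurable
variance fractions, and missingness reproduces the study's loss mechanisms
(16 animals lost with per-laboratory pattern 1/0/3/4/5/3, 9 survivors
losing the three EPM outcomes, 2 isolated blood values), which yields the
study's accounting: 308 retained animals, 299 behaviorally complete, 4,283
non-missing measures.

## Worked example

```r
library(hetrep)

dataset <- allocate_design(design_spec()) |>
  simulate_outcomes(default_profile(), seed = 1) |>
  inject_missingness(study_missingness(seed = 1))

dataset_accounting(dataset)
#> Animals retained: 308  (behaviorally complete: 299 )
#> Cages: 162
#> Non-missing measures: 4283

contrast_all(dataset)
#> 84 HET-vs-STA variance contrasts ( median centering )
#>   SD ratio > 1 in 61 cases, < 1 in 23
#>   significant: 5 raw (alpha = 0.05, expected false positives 4.2), 0 after Bonferroni (alpha' = 0.0006)

ms <- meta_all(dataset)
ms$coverage_summary
#>   arm mean_coverage sd_coverage n_outcomes
#> 1 HET     0.5357143   0.1624935         14
#> 2 STA     0.5595238   0.1241577         14
```

SD ratios above 1 dominate here because the generating profile gives
breeding site and the lab-by-breeder interaction real variance, which the
heterogenized cohorts absorb into their within-cohort spread; with those
fractions set to zero the split is even. The coverage probabilities of both
arms are statistically indistinguishable — the design arm explains almost
none of the between-laboratory scatter.

A full run writing every stage table plus a checksummed manifest:

```r
report <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
```

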