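---
title: "Models and methods behind hetrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hetrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hetrep` evaluates whether heterogenizing single-laboratory study
populations by animal breeding site improves replicability across
laboratories. This vignette documents the generative model, the statistical
procedures, the numerical choices, and what passing the package's tests
does — and does not — establish about real data.

## The generative model

Every outcome $v$ of animal $i$ is drawn from a crossed random-effects
model,

$$y_{vi} = \mu_v + a_{\mathrm{lab}(i)} + b_{\mathrm{breeder}(i)}
         + c_{\mathrm{lab} \times \mathrm{breeder}(i)}
         + d_{\mathrm{cage}(i)} + e_{vi},$$

with each effect an independent zero-mean Gaussian whose variance is a
configurable fraction of the outcome's total variance, shared by all
animals at the same factor level. This is the generative mirror of the
analysis model (fixed breeder, laboratory and interaction; random cage) and
the minimal model consistent with every analysis stage. The defaults in
`default_profile()` — laboratory 0.15, breeding site 0.04, interaction
0.11, cage 0.10, residual 0.60, on a standardized scale (mean 0, total SD
1) — are chosen to match the magnitudes observed in multi-laboratory mouse
phenotyping: a between-laboratory share around 15 % and a breeding-site
share several times smaller than the laboratory share.

Outcomes are generated independently of one another by default. Real
phenotype batteries are correlated; the optional `latent_cor` parameter
adds a per-animal latent factor inducing a common residual correlation,
which matters mainly for the discriminant analyses. Because independent
outcomes each carry their own copy of the factor signal, *multivariate*
statistics (Pillai-trace effect sizes, LDA rates) on default synthetic data
run higher than on real correlated data; the univariate shares are
comparable. Passing tests on synthetic data therefore demonstrates
correctness and calibration of the procedures, not the numerical values a
particular real dataset would give.

The allocation (`design_spec()`, `allocate_design()`) reproduces the
reference design exactly: 6 laboratories × 6 breeding sites, 24 STA animals
per laboratory from its mapped site, 6 HET animals from each of the 5 other
sites, pair-housed with cagemates always sharing laboratory, site and arm
(cages never mix arms — this matches how shipped pairs are co-housed and
keeps the cage variance estimable within arm). Missingness
(`study_missingness()`) reproduces the three loss mechanisms: 16 animals
lost with the per-laboratory pattern 1/0/3/4/5/3, 9 survivors losing all
three elevated-plus-maze outcomes (video loss hits the block, not single
values), and 2 isolated blood-chemistry exclusions, giving the accounting
identity $308 \times 14 - 27 - 2 = 4{,}283$ non-missing measures and 299
behaviorally complete animals. Mouse loss is uniform at random within
laboratory: the loss pattern is observational, the mechanism incidental.
Episodes of single housing are not modeled; no defensible covariate
construction exists without more detail than the design description
provides.

All randomness flows from one root seed; child seeds are derived
deterministically per stage, so identical configurations are bit-identical.

## Variance decomposition

`manova_pillai()` computes Type II sums-of-products matrices by model
comparison (each main effect adjusted for the other; the interaction
adjusted for both). Type II is the natural choice because the arms make the
lab × breeder cells unbalanced by construction (24 vs 6 animals) and Type
II avoids order dependence. The multivariate effect size is
$\eta^2 = V/s$ with $V$ the Pillai trace and $s = \min(p, \mathrm{df}_h)$;
the alternative $1-(1-V/s)^s$ was rejected in favor of the simpler, more
traceable convention. Listwise deletion is used for the multivariate
analysis; univariate models use all available cases per outcome.

`fit_lmm()` fits `y ~ breeder * lab + (1 | cage)` by REML through
`lmerTest::lmer`, then refines the variance components by solving the
restricted-likelihood score equation in the cage-to-residual variance ratio
with a root bracketing search. Root finding is used deliberately:
function-value optimization of the profiled criterion is limited by its
flatness near the optimum to roughly $10^{-7}$ relative precision, whereas
the score equation crosses zero with a usable slope and delivers machine
precision — on balanced designs the estimates equal the closed-form
expected-mean-squares estimators to ~1e-15. A fit is flagged singular when
$\hat\sigma^2_{\mathrm{cage}} < 10^{-10}\,\hat\sigma^2_{\mathrm{resid}}$;
one-animal cages make the cage variance unidentifiable and land on this
boundary. Satterthwaite degrees of freedom come from `lmerTest`; at the
boundary they collapse to the ordinary-least-squares residual df, and in
the balanced one-way case the grand-mean df equals $k - 1$ cages.

`explained_variance()` reports semi-partial shares: the variance of each
factor's fitted component over the observed animals, divided by total
variance (fixed + cage + residual); the combined share is the marginal
R² in the Nakagawa sense. Two numerical choices matter. First, factors are
coded with sum-to-zero contrasts, otherwise the reference-level
parameterization leaks interaction variance into main-effect components.
Second, the naive variance of a fitted component overestimates the variance
of the true component by the sampling noise of the coefficients; each
component variance is therefore bias-corrected by
$\operatorname{tr}(\widehat{\mathrm{Cov}}(\hat\beta_t)\,X_t^c{}'X_t^c)/n$
(centered design cross-product against the REML coefficient covariance),
floored at zero. Even after correction, an ANOVA-style decomposition of
unbalanced cells attributes the per-main-effect means of the interaction
draws to the main effects — that is a property of the estimand, not an
estimator defect. For recovering *generative* fractions the package
provides `estimate_profile()`, which treats laboratory, breeding site,
interaction and cage all as random intercepts and returns REML variance
components; its estimates are unbiased for the generator within Monte-Carlo
error.

`between_lab_variance()` fits, per outcome and arm, the mixed model with
laboratory as the only fixed factor and reports the laboratory marginal R²
— the between-laboratory share compared between STA and HET arms.

## Discriminant classification

`fit_lda()` wraps `MASS::lda` on complete cases with **equal class
priors**, despite mildly unequal class sizes: the chance level quoted for
six classes is $1/6 \approx 17\,\%$, which presumes equal priors.
Proportions of trace are the normalized squared singular values. Inputs
that are constant within classes or collinear are rejected by name before
fitting. `classify_lda()` reports resubstitution rates by default with a
leave-one-out option — published rates of this kind rarely state which was
used, so both are available and the optimism ordering (resubstitution ≥
leave-one-out on average) is itself under test. Chance-level behavior is
assessed on fresh data, because resubstitution is optimistic even for
uninformative features.

## Variance contrasts

`levene_test()` is the two-group Brown–Forsythe test: a one-way ANOVA F on
absolute deviations from the group **median** (mean centering optional),
referred to $F(1, n-2)$. Median centering is the default of the standard R
implementation and is robust for skewed blood-chemistry outcomes; the
package's statistic is verified against `car::leveneTest` and its type-I
error is simulated at the study's cohort sizes (24 vs 30). A constant group
makes the variance comparison undefined and is reported as `NA` rather
than silently zero. Cohort SDs use the $n-1$ denominator over animals, not
cage means — the contrast describes cohort spread; cage structure is
handled in the meta-analysis stage. `contrast_all()` produces the
84 lab × outcome contrasts with Bonferroni control ($\alpha' = \alpha/84$)
and ties (ratio exactly 1) counted as "not larger" and flagged.
`fisher_combine()` pools the six per-laboratory p-values per outcome via
$-2\sum\ln p \sim \chi^2_{2k}$; zero p-values are rejected with clipping
guidance rather than silently clipped. Stouffer or harmonic-mean
combination would slot into the same interface but is out of scope.

One behavior worth naming: under the default profile the HET arm genuinely
contains extra between-breeder and interaction variance inside each cohort,
so SD ratios above 1 dominate. Exchangeability nulls (used for the
symmetric-split calibration) must therefore set the breeder and interaction
fractions to zero — otherwise the "null" is not null.

## Meta-analysis and coverage

`study_summaries()` treats the cage as the independent unit: the study
estimate for a laboratory is the mean of its cage means and the standard
error is the SD of cage means over $\sqrt{n_{\mathrm{cages}}}$. Pair
housing induces cagemate correlation, and an animal-level SE would
understate the uncertainty whenever the cage fraction is positive (this is
tested). Laboratories with fewer than two cages, or zero variance across
cages, are excluded with a warning.

`random_effects_meta()` defaults to the DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\{0, (Q-(k-1))/(\sum w - \sum w^2/\sum w)\}$ with
fixed-effect weights $w = 1/\mathrm{se}^2$, and offers REML (via `metafor`)
as the likelihood-based alternative; the two agree within 10 % at moderate
heterogeneity. Confidence intervals use the normal quantile, the simplest
reading of "the 95 % confidence interval of the meta-analytic mean"; the
Knapp–Hartung t-based interval is available as an option. A known
limitation: with estimated $\tau^2$ the normal-quantile interval
undercovers at very small $k$ (about 89 % at $k = 6$); calibration is
therefore demonstrated at $k = 50$, where it sits within 93–97 %. The
coverage-probability statistic — the fraction of per-laboratory estimates
inside the pooled interval — is compared between arms as a mean ± SD over
the 14 outcomes.

The "dance around the means" response is defined here as the absolute
standardized deviation $|\hat\theta_j - \hat\mu|/\mathrm{se}_j$ of each
study estimate from its pooled mean; the phrase is informal in the field,
so the definition is isolated behind `deviation_table()` where an
alternative could be swapped in. `design_effect_model()` then fits
`deviation ~ arm + (1 | outcome) + (1 | lab)` and reports the arm's
marginal R² over the total (arm + outcome + laboratory + residual)
variance.

## Power simulation

`simulate_power()` reimplements the design-stage sample-size procedure:
per replicate, draw a mean shift for each of 12 continuous variables from
the effect-size distribution, simulate an STA cohort ($n = 24$) and a HET
cohort ($n = 30$) with unit within-cohort SD, run a correlation-matrix PCA,
and feed the first principal component into a one-way ANOVA whose F ratio
is referred to the design-level threshold $F(0.05; 1, 5) = 6.6$. Two
readings of "orthogonal rotation" exist; unrotated principal axes (which
are orthogonal by construction) are the default, with a varimax option.
The $(1, 5)$ referral is honored as stated even though an individual-level
ANOVA would have different df — the threshold is part of the procedure's
definition, and it makes the null exceedance rate far *below* the nominal
α, which is tested. The default effect-size distribution (normal with mean
0.5 SD, SD 0.25 SD per variable) is a documented placeholder: the original
design assumptions live in unpublished analysis code, so the published
power values (0.825, and 0.799 after attrition) are reproducible only after
transcribing those assumptions into `power_config()`; the package makes no
claim to reproduce them from the placeholder.

## Pipeline, problem sizes, and limits

`run_pipeline()` chains simulate → validate → variance → lda → contrasts →
meta → power, writing tab-separated stage tables with a version/config
header and an MD5-checksummed manifest; identical configurations and seeds
reproduce identical checksums. `validate_dataset()` enforces the canonical
CSV schema (`animal_id, lab, breeder, design, cage_id`, 14 outcome columns,
empty fields for missing values) and reports violations row by row.
`paper_benchmarks()` recomputes the headline quantities from any file in
that schema, for benchmarking against deposited raw data when available.

Monte-Carlo problem sizes used by the test suite were chosen to make each
property decisive at modest cost: 200 replicates of the full design for
parameter recovery (the Monte-Carlo SE of the mean is then a few times
smaller than the smallest generating fraction), 10,000 null replicates for
the Levene level, 2,000 for CI calibration and the power null, and 100 for
the arm-wise coverage comparison. Single-outcome properties that depend on
realized draws of only six laboratory effects are inherently noisy — the
probability that the realized laboratory variance exceeds the realized
breeding-site variance is capped near 91 % per outcome — so ordering
properties are asserted at the dataset level, where the 14 outcomes'
independent draws average that noise away.

Known limitations: no quadratic or regularized discriminant analysis; no
publication-bias diagnostics or multivariate meta-analysis; the mixed-model
engine handles a single grouping factor (crossed random effects appear only
in the design-effect model); and the generator does not model behavioral
dynamics, body-weight trajectories, or the aggression process behind single
housing.
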