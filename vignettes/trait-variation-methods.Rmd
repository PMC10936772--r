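---
title: "Methods: population trait variation and external-filtering tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population trait variation and external-filtering tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itvtools)
library(dplyr)
```

## The problem this package addresses

In a monodominant forest, one tree species contributes most of the stems, so
community-level trait analyses collapse to a single species and the relevant
variation is *intraspecific*: differences in functional trait values among
individuals, between populations, and between ontogenetic stages (juveniles
versus adults). `itvtools` implements an analysis pipeline for exactly this
setting: an individual-level trait table with a population label, a stage
label, and six functional traits — leaf thickness (LT, mm), leaf area
(LA, cm²), specific leaf area (SLA, cm² g⁻¹), leaf dry matter content
(LDMC, stored as a dimensionless dry/fresh mass ratio), wood density
(WD, g cm⁻³), and specific root length (SRL, cm g⁻¹).

Four questions structure the pipeline:

1. Do populations differ in trait means, within each stage?
2. Do stages differ, within each population?
3. Is each population a *random subset* of the regional trait pool, or is its
   trait variance constricted, as an external environmental filter would
   leave it?
4. How do individuals and environmental sites arrange along major axes of
   variation (PCA)?

## The trait table

All analyses consume one tidy format: a tibble with `individual_id`,
`population`, `stage` (`adult`/`juvenile`) and one numeric column per trait.
All six traits are physically positive quantities; validation rejects
nonpositive values, duplicate ids and stage labels outside the two-level
set. Missing values are allowed, never imputed, and dropped pairwise per
trait. Trait distributions are right-skewed, so analyses work on the
natural-log scale; `log_transform()` records the transform in the trait
registry and refuses double application. The natural log (not log10) is
used throughout: the choice affects only the scale of regression
coefficients, not test statistics or p-values.

## Assumption-driven test selection

For each trait, between-population contrasts (one per stage) and
between-stage contrasts (one per population) are tested after
log-transformation — 12 + 18 = 30 tests for the default 3-population
design. The selection rule is deterministic and recorded on every report:

* Shapiro–Wilk per group on the log values. If any group is non-normal at
  0.05 **and** there are exactly two groups, use the Mann–Whitney U test.
* Otherwise Levene's test across groups (Brown–Forsythe median centering by
  default; configurable): if it rejects at 0.05, use the Welch variant
  (Welch ANOVA for k ≥ 3, Welch t for k = 2); otherwise the classical
  ANOVA / pooled t-test.

With three or more non-normal groups there is no standard nonparametric
analogue in this design, so the (Welch) ANOVA on log values is retained and
the violation is flagged on the report rather than silently ignored. Groups
too small for Shapiro–Wilk (n < 3) are marked untestable and the Levene
branch decides. No multiple-testing correction is applied by default — each
test answers its own biological question — but `adjust = TRUE` adds a
Benjamini–Hochberg column for users who want battery-wide control.

## The dummy-coded two-factor model

As a complementary single-model view, each log trait is regressed on
stage, population and their interaction via explicit dummy coding:

$$E(y) = \beta_0 + \beta_1 S + \beta_2 P_2 + \beta_3 P_3 +
\beta_4 S P_2 + \beta_5 S P_3$$

where $S$ indicates the non-reference stage and $P_j$ the non-reference
populations. The reference cell defaults to juveniles of the first
population and is configurable — both conventions (juvenile-referenced and
adult-referenced) are common in reporting, and the choice only relabels
coefficients: fitted values, R² and the overall F are invariant, which the
tests assert. With all six cells populated the design is saturated, so
$\beta_0$ is the reference-cell mean and every cell's fitted value equals
its sample mean; this identity (to 1e-10) is the core correctness check.
Factor-level significance (ontogeny, population, interaction) uses Type II
nested-model F tests, which are order-invariant and sensible for this
near-balanced design.

## The external-filtering statistic T_IP.IR

The core contribution is a variance-ratio test of external filtering at
the individual level. For a trait, a stage and a population,

$$T_{IP.IR} = \frac{\mathrm{var}(\text{population cell})}
{\mathrm{var}(\text{stage-restricted regional pool})}$$

with the n−1 sample variance in both numerator and denominator (any
consistent convention nearly cancels in the ratio; consistency is what is
enforced and tested). Stages form separate pools: pooling them would
conflate ontogeny with filtering. The ratio is scale-free — adding or
multiplying a constant leaves it unchanged — which the suite verifies.

**Null model.** "Populations are random subsets of the pool" is made
operational by uniform permutation of the population labels within a
stage, preserving each population's sample size (the canonical
T-statistics null). The pool, and hence the denominator, is fixed under
permutation. The default is 1000 randomizations; tests and examples use
smaller budgets. Each (stage, trait) draws from its own deterministic
substream of the configured seed, so results are reproducible and adding
a trait does not perturb another trait's null.

**Standardized effect size and tests.** Each observed ratio is summarized
as $SES = (T_{obs} - \overline{T}_{sim}) / \mathrm{sd}(T_{sim})$; negative
values mean the population's variance is smaller than a random subset's.
Significance uses two one-sided empirical tests with add-one estimators,
$p_{low} = (\#\{T_{sim} \le T_{obs}\} + 1)/(n_{sim}+1)$ and the mirror
image for the upper tail, so no p-value can be exactly zero. The 5% level
is applied per tail (the two-one-sided-tests convention); read jointly,
the pair controls a 10% two-sided rate, and `alpha` is configurable.
Permutations act on raw trait values by default — a `scale = "log"`
switch is available, and because the variance ratio is scale-sensitive
only under nonlinear transforms, the two options genuinely differ and the
choice is reported with the results.

**Population-mean summary.** Per (trait, stage) the across-population mean
and sd of the SES values are reported, and the observed mean of the three
ratios is compared to the null distribution of the same mean computed on
the same randomization draws — the convention used by trait-statistics
toolkits that report a community-mean SES with a null envelope.

## The synthetic generator as the study design

No raw individual-level data ship with the package; the generator *is* the
study design used by all calibration tests: 3 populations × 2 stages × 20
individuals per cell, six traits, lognormal within cells. Lognormal is the
minimal faithful model for positive right-skewed traits that are analysed
on the log scale. External filtering is modelled as variance constriction
only — a multiplier below 1 on a population's log-scale sd — matching what
the variance-ratio statistic measures; mean shifts are expressed
separately through cell means. `oak_study_config()` fixes plausible trait
magnitudes (e.g. adult SLA around 75 cm² g⁻¹, WD around 0.65 g cm⁻³),
stage effects, population shifts, interactions, and filtering strengths of
0.6 and 0.8 for two populations; these magnitudes are illustrative by
design and are not estimates of any field population.

`generate_null_traits()` builds the reference world in which populations
are random subsets of one pool: within each (stage, trait) every
population draws from a single lognormal whose parameters are the
across-population means of the configured `meanlog` and `sdlog` (the
pooling rule had to be fixed somehow; averaging keeps the null world
centred on the alternative's overall scale). Ontogeny effects are
deliberately *preserved* — this generator nulls population structure, not
stage structure. Consequently the comparison battery, which also contrasts
stages, is calibrated in the tests against a fully homogeneous
configuration (one lognormal per trait across all cells), which is that
battery's own null hypothesis.

What the generator does not emulate: trait–trait covariance (traits are
drawn independently), spatial or genetic structure, and measurement error
models. Passing calibration tests therefore demonstrates correctness of
the statistical machinery under the stated design, not robustness to
correlated traits or structured noise in field data.

## Numerical choices

* Permutation variance ratios are computed by a cumulative-sum pass over
  the permuted vector (groups occupy contiguous blocks), giving exact
  agreement with two-pass variances to machine precision and making the
  1000-randomization default cheap.
* Per-cell and per-(stage, trait) random substreams are derived from the
  global seed by a deterministic string hash, keeping every component
  independently reproducible.
* Degenerate inputs have defined behaviour: a zero-variance pool is an
  error; a zero-variance cell gives $T_{IP.IR}=0$ with a forced-extreme
  lower p of $1/(n_{sim}+1)$; a constant response in the regression
  reports R² = 0 with the F flagged as undefined; location tests on
  groups that are all identical report p = 1.
* PCA is correlation-matrix PCA (standardize, then SVD), with the sign of
  each component fixed by making its largest-magnitude loading
  nonnegative. Explained fractions are taken over all components, so they
  sum to one even when the output is truncated.

## Problem sizes used by the test suite

Simulation-based checks run at the design's native scale (3 × 20 per
stage): 1000 replicate null datasets at 199 randomizations for the
calibration of the lower-tail SES test; 500 replicates for SES
mean/sd calibration, for the power–monotonicity curve over filtering
strengths {0.25, 0.5, 0.75, 1}, for regression CI coverage and for the
battery-wide type-I rate; 100 random tables for oracle equivalence; and
20,000 draws for the exhaustive-null comparison on a four-individual
pool. Unit tests use smaller replicate counts with wider bands.

## Known limitations

* The empirical test is conservative by construction: with 199
  randomizations the achievable lower-tail level is 9/200 = 4.5%, so
  observed rejection rates sit slightly below the nominal 5%.
* With three non-normal groups the pipeline reports a flagged Welch/classical
  ANOVA rather than a rank-based test.
* The mean-SES significance convention (mean T against the null of the
  mean over shared draws) is one of several defensible choices; it is
  reported explicitly rather than adjudicated.
* LDMC units are lab-convention-dependent (g g⁻¹ here, mg g⁻¹ elsewhere);
  the registry label is configurable, and the statistics are unaffected.
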