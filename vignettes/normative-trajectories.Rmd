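---
title: "Normative growth trajectories and study-level deviation calls: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative growth trajectories and study-level deviation calls: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normtraj)
```

# The procedure

`normtraj` contrasts *study-level* summaries of brain volumes in
preterm-born (PT) groups against *individual-level* normative reference
data from full-term (FT) controls. The pipeline has four stages:

1. **Study-table harmonization.** Published PT studies report group mean
   age and mean/SD of total intracranial volume (TIV), grey matter
   volume (GMV) and white matter volume (WMV), in assorted units.
   `parse_study_table()` reads the CSV schema, `convert_age()` /
   `convert_volume()` / `convert_weight()` harmonize months to years,
   mm³/dm³ to cm³ and kg to g, and `derive_volume_from_ratio()` recovers
   absolute volumes for studies that publish only tissue/TIV ratios.
   `filter_eligible()` applies the eligibility rules: mean age at scan
   strictly above one year (below that, brain growth is so rapid that
   small age differences swamp the group contrast) and all three volume
   means present. `select_largest_per_cohort()` implements the
   overlapping-cohort rule: when several studies describe the same birth
   cohort at the same age, only the largest sample is kept.
2. **Normative curve fitting** (`fit_hybrid()`), per measure, on
   individual FT scans.
3. **Band construction** — pointwise 95% confidence and prediction
   intervals (`confidence_band()`, `prediction_band()`, `mc_band()`).
4. **Deviation classification** (`contrast_table()`) of each study-group
   mean at its mean age.

# The growth model and its assumptions

The mean curve of each measure against age is the cubic hybrid model

$$\mathrm{Vol}(a) = \beta_4\!\left(1 - e^{-a/\beta_5}\right)
  + \beta_0 + \beta_1 a + \beta_2 a^2 + \beta_3 a^3 + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

the standard "saturating exponential plus cubic" candidate of the
lifespan volumetry literature. Assumptions worth stating explicitly:

* **Homoscedastic Gaussian residuals.** One $\sigma$ across the whole
  age range. Real volumetric data are likely heteroscedastic (wider
  spread in adults); no variance model is fitted here.
* **Age is the only covariate.** Sex and source dataset are carried
  through for reporting/plotting but not modelled; the four reference
  datasets are pooled without site harmonization.
* **Ratio measures are fitted directly.** GMV/TIV and WMV/TIV are
  computed per subject and fitted as their own response, not derived as
  a quotient of two fitted curves.
* **Cross-sectional curves.** The model describes the population mean at
  each age, not within-subject growth.

## Fitting: variable projection instead of damped least squares

For fixed $\beta_5$ the model is *linear* in $\beta_0..\beta_4$, so the
least-squares problem is solved by variable projection: profile out the
linear coefficients by ordinary least squares and minimize the
one-dimensional profiled SSE over $\beta_5 \in [10^{-3}, 50]$ years. The
profiled objective is scanned over a log-spaced grid
$\{0.25, 0.5, 1, 2, 4, 8\}$ years plus the bounds, then refined by
golden-section search in the bracketing interval. This reaches the same
optimum a damped (Levenberg-type) solver with polynomial-based
initialization would, but is deterministic, needs no starting values for
the linear part, and cannot diverge — which is why it replaced the
originally planned explicit multi-start damped least squares. The
exponential amplitude and the polynomial trade off strongly (parameter
correlations above 0.9 are normal), so *individual* coefficients are
weakly identified even when the mean curve is pinned down tightly; tests
therefore assert recovery of the fitted curve, never of raw
coefficients.

Degrees of freedom are $n - p$ with $p$ the number of free parameters
(6 for the full model); $\hat\sigma^2 = SSE/(n-p)$ and the parameter
covariance is $V = \hat\sigma^2 (J^\top J)^{-1}$ with $J$ the Jacobian
of the mean function at the optimum. A (near-)singular $J^\top J$ —
e.g. all ages equal, or data that cannot separate the saturating term
from the line — raises a non-identifiability error instead of returning
garbage.

## Bands

Two uncertainty propagation methods are implemented and labelled; both
return the full CI + PI set so the ordering invariant
`pi_lo <= ci_lo <= mean <= ci_hi <= pi_hi` is always checkable.

* **Delta (default):** CI half-width
  $t_{0.975, n-p}\sqrt{g(a)^\top V g(a)}$, PI half-width
  $t_{0.975, n-p}\sqrt{g(a)^\top V g(a) + \sigma^2}$, with $g$ the
  closed-form gradient. A Student-t quantile is used rather than the
  normal one — at $n = 880$ the difference is invisible, but it makes
  the small-$n$ behaviour correct and results bit-reproducible.
* **Monte-Carlo (`mc_band()`):** draw $\beta^* \sim MVN(\hat\beta, V)$
  (draws with $\beta_5^* \le 0$ rejected and redrawn; a rejection rate
  above 50% aborts), take empirical quantiles of the curve at each age;
  for the PI add an independent $N(0, \sigma^2)$ residual per draw.
  Seeded and reproducible; the caller's RNG stream is saved and
  restored.

The two methods agree (within ~10% of half-width) only in the
*well-conditioned* regime where $V$ is small enough that the curve is
near-linear over the sampled parameter region. At the default synthetic
noise ($\sigma \approx 6\%$ of the mean volume, $n = 880$) the $\beta_5$
uncertainty is large enough that the MC confidence band is visibly wider
than the first-order delta band below age ~10; that is a real
property of first-order propagation, not a bug, and the agreement test
is therefore run on a low-noise fit. Coverage of the *delta* bands at
the default noise is nevertheless well inside [0.92, 0.98] at the tested
ages (the acceptance suite measures it over 500 cohorts).

## Deviation classification

`band_at_age()` linearly interpolates the band between grid ages
(default grid 0.7–30 y, step 0.1) and refuses to extrapolate.
`classify_deviation()` assigns one of six ordered categories with
*closed inner intervals*: a value exactly on a CI bound is "within CI",
a value exactly on a PI bound is inside the outer band, and a value
exactly equal to the fitted mean goes to `within_CI_below` (an arbitrary
but fixed tie rule). Comparing a *group mean* against an *individual*
prediction interval is statistically generous — the sampling error of a
mean of $n$ subjects is far smaller than the individual spread — but it
is exactly what the visual meta-analytic contrast does, so it is
reproduced as-is. The standardized score
$z = (\text{obs} - \text{fit})/\sqrt{s_\text{mean}^2 + \sigma^2}$ is the
statistically interpretable companion; when the t-quantile is not
supplied it is recovered from the band itself via
$t = \sqrt{\text{pi}_\text{half}^2 - \text{ci}_\text{half}^2}/\sigma$,
which is exact for delta bands.

# The synthetic world

The generator replaces four non-redistributable FT reference datasets.
What it emulates:

* **Pool composition:** 880 subjects, ages uniform on [0.7, 30] years,
  source labels C-MIND / NDAR-NIHPD / ICBM / IXI apportioned
  deterministically (largest-remainder) to exactly 236/375/169/100 so
  the composition is reproduced exactly rather than in expectation.
* **True curves** (design choices, documented here once): GMV
  $\beta = (400, 12, -1.0, 0.018, 350, 1.5)$ — rapid infant growth,
  peak near age 8.5 (asserted to lie in the school-age window 6–12 y),
  decline to ~700 cm³ by 30; WMV $\beta = (120, 5, 0, 0, 250, 2.5)$ —
  monotone increase through age 30 toward ~520 cm³. Noise
  $\sigma_{GMV} = 45$, $\sigma_{WMV} = 25$ cm³, about 6% of the mean
  volume, a typical between-subject spread for global tissue volumes.
* **TIV reconciliation:** TIV is generated as $(GMV+WMV)/r$ with
  $r \sim N(0.85, 0.02)$ truncated to $(0.7, 0.95)$ — a "brain fill"
  ratio — so `gmv + wmv < tiv` holds for every subject by construction
  and the ratio measures inherit realistic coupling. Consequently the
  TIV and ratio "true curves" are plug-in approximations (error well
  under 1% at this ratio SD), and exact-recovery tests use GMV/WMV only.
* **PT study tables:** each design row draws $n$ subject-level volumes
  around a deficit-scaled true curve (multiplicative deficit $d(a)$,
  between-subject SDs defaulting to 70/50 cm³, the magnitude seen in
  published tables) and emits the group mean and SD. The shipped
  `default_paper_mimic_config()` copies the packaged table's 14
  sample-size/age pairs and sets an 8% GMV deficit at all ages and a
  WMV deficit of 15% at ages 12–17 and 5% elsewhere — the qualitative
  "consistently lower GMV, adolescent WMV dip" pattern.

What it does **not** emulate: scanner/site effects, sex differences,
the real datasets' non-uniform age histograms, heteroscedastic noise,
or any real study's actual values. A green test on synthetic data
establishes that the *machinery* (fitting, calibration, classification
logic) is correct — it does not reproduce, and cannot validate, the
published per-study band calls, which depend on the real reference
data.

# Numerical choices and edge cases

* $\beta_5$ bounded in $[10^{-3}, 50]$ years to keep the exponential
  well-scaled; golden-section tolerance $10^{-9}$.
* Cholesky with a relative pivot threshold of $10^{-10}$ decides
  (non-)identifiability of $J^\top J$.
* Fits require $n > p$ observations and at least two distinct ages.
* Monte-Carlo bands require $\ge 1000$ draws and an explicit seed; all
  stochastic functions either take a config seed or a seed argument and
  restore the caller's RNG state.
* The tie on `select_largest_per_cohort()` totals breaks to the
  lexicographically smallest study id, with a warning.
* Finite-difference oracle tests use step $10^{-4}$ (relative): large
  enough to avoid catastrophic cancellation on curve values of order
  $10^5$, small enough for $O(h^2)$ truncation to stay below the
  $10^{-6}$ comparison tolerance.

# Open design points, decided

* **Same-cohort studies at nearby ages:** the packaged table keeps two
  studies of the same Spanish cohort at ages 14.3 and 14.5, as
  published. `select_largest_per_cohort()` defaults to an age tolerance
  of 0 years (strictly "the same age") and is *not* applied to the
  packaged table by default; with tolerance 1.0 it would collapse the
  adolescent Spanish rows to the largest study, and users doing a
  stricter meta-analysis can opt in.
* **Corrected vs chronological age:** the youngest groups report
  age corrected for prematurity; values are carried as printed, no
  adjustment is attempted.
* **Which propagation the original band software used** (first-order
  Taylor vs MC) is unknowable from the outside; both are implemented,
  labelled, and neither is claimed to replicate any published band
  pixel-exactly.
* **Config files** are JSON (not YAML): no extra dependency, identical
  expressiveness for this schema.

# Limitations

* Study-level contrasts have no inferential weighting: no fixed- or
  random-effects pooling, no heterogeneity statistics — by design, as
  the underlying procedure is a visual/ordinal contrast.
* The normative fit ignores site and sex; on real multi-site data the
  bands would be too narrow.
* Classification at a study's *mean* age ignores the study's own age
  spread.
* Extrapolation beyond the fitted age range is refused rather than
  modelled.
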