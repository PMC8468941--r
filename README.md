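# normtraj

Normative brain-volume growth trajectories, and study-level deviation
calls for preterm-born cohorts.

## The problem

Individual-level MRI data on preterm (PT, born < 37 weeks of gestation)
populations are scarce, so PT brain development is mostly known through
small cross-sectional studies that publish only group summaries: a mean
age at scan and mean/SD of total intracranial volume (TIV), grey matter
volume (GMV) and white matter volume (WMV). Large open datasets of
full-term (FT) controls, by contrast, allow fitting smooth normative
volume-versus-age trajectories. `normtraj` implements the meta-analytic
contrast between the two: it harmonizes and filters a study-summary
table, fits normative curves to individual-level FT reference data, and
classifies each PT study-group mean into an ordinal deviation band
relative to the normative curve.

It is aimed at researchers doing normative modelling of derived MRI
volumetry (no images are touched — only scalar volumes in cm³).

## The model

For each measure `Vol` in {GMV, WMV, TIV, GMV/TIV, WMV/TIV} the FT
reference data are fitted with the *cubic hybrid* growth model

    Vol = β₄ (1 − e^(−Age/β₅)) + β₀ + β₁·Age + β₂·Age² + β₃·Age³ + ε,
    ε ~ N(0, σ²)

a saturating-exponential early-growth term plus a cubic polynomial.
Fitting is least squares with β₅ bounded in [10⁻³, 50] years, solved by
variable projection (the model is linear in β₀..β₄ given β₅). Pointwise
95% bands come either from the first-order delta method,

    CI half-width = t₀.₉₇₅,ₙ₋₆ · √(g(a)ᵀ V g(a)),
    PI half-width = t₀.₉₇₅,ₙ₋₆ · √(g(a)ᵀ V g(a) + σ²),

with `g` the parameter gradient of the curve and `V` the parameter
covariance, or from parametric Monte-Carlo propagation (quantiles over
draws β\* ~ MVN(β̂, V), plus a residual draw for the PI). A study mean
is then classified into one of six ordered categories — `below_PI`,
`below_CI`, `within_CI_below`, `within_CI_above`, `above_CI`,
`above_PI` — and given a standardized score
`z = (observed − fitted)/√(s_mean² + σ²)`.

Because the real reference datasets are not redistributable, the package
ships a seeded generator that emulates an 880-subject FT pool (uniform
ages 0.7–30 y, four source-dataset labels with exact 236/375/169/100
counts, hybrid mean curves plus homoscedastic Gaussian noise, TIV built
from a truncated-normal brain-fill ratio so `gmv + wmv < tiv` always
holds) and synthetic PT study tables with configurable age-dependent
deficits.

## Worked example

```r
library(normtraj)

studies <- parse_study_table(preterm_table_path())
summarize_cohort(studies)
#> 538 subjects in 14 groups from 9 studies, mean ages 1.1-28.5 years

cfg <- generator_config(seed = 42)      # synthetic FT reference pool
ft  <- generate_ft_cohort(cfg)          # 880 scans
fit <- fit_hybrid(ft, "GMV")
fit
#> Cubic hybrid growth fit -- GMV
#>   n = 880, SSE = 1.82782e+06, sigma = 45.731, df = 874
#>     beta0       beta1       beta2       beta3       beta4       beta5
#> 413.6110000  11.2420000  -1.0204100   0.0191388 348.0090000   1.7268900

band  <- confidence_band(fit, default_age_grid())   # delta-method CI + PI
calls <- contrast_table(filter_eligible(studies),
                        list(GMV = list(fit = fit, band = band)))
head(calls[, c("study_id", "age_years", "observed_mean", "fitted_mean",
               "category", "z_score")], 3)
#>              study_id age_years observed_mean fitted_mean category  z_score
#> 1      Padilla (2011)      1.10         683.7    588.7201 above_PI 2.050295
#> 2      Padilla (2011)      1.10         714.0    588.7201 above_PI 2.704370
#> 3 Soria-Pastor (2009)      9.30         821.7    791.7146 above_CI 0.654317
```

Each row compares one published PT group mean with the normative curve
at that group's mean age: `category` says where the mean falls relative
to the 95% confidence band (uncertainty of the fitted mean curve) and
the 95% prediction band (spread of individual FT observations);
`z_score` is the continuous version of the same comparison. Note that
against the *synthetic* reference pool these specific calls only
exercise the machinery — they do not reproduce the published per-study
findings, which depend on the real FT reference data (see the methods
vignette).

The same pipeline is scriptable:

```sh
Rscript -e 'normtraj::pt_cli()' simulate --out runs/demo --seed 7
Rscript -e 'normtraj::pt_cli()' contrast --out runs/demo --seed 7 --plot --force
Rscript -e 'normtraj::pt_cli()' report   --out runs/demo --force
```

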