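Package: normtraj
Title: Normative Brain-Volume Growth Trajectories and Study-Level Deviation
    Contrasts
Version: 0.1.0
Authors@R:
    person("normtraj", "developers", email = "normtraj@example.org",
           role = c("aut", "cre"))
Description: Fits the cubic hybrid growth model (a saturating-exponential
    early-growth term plus a cubic polynomial in age) to individual-level
    full-term reference data for grey matter volume, white matter volume,
    total intracranial volume and their ratios, computes pointwise 95
    percent confidence and prediction bands by the delta method or by
    parametric Monte-Carlo propagation, and classifies study-level mean
    volumes from preterm-born cohorts into ordinal deviation bands relative
    to the normative trajectory. Includes tools to parse, harmonize and
    summarize study-summary tables (unit conversions, eligibility filters,
    cohort deduplication), a seeded synthetic-data generator for full-term
    cohorts and preterm study tables, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
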