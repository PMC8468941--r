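# shared helpers: tiny in-code fixtures for bands, fits and study tables

# hand-built interval_band on an arbitrary grid (for classifier tests)
make_band <- function(age, mean, ci_lo, ci_hi, pi_lo, pi_hi,
                      measure = "GMV", level = 0.95, df = 874, sigma = 45) {
  structure(data.frame(age = age, mean = mean, ci_lo = ci_lo, ci_hi = ci_hi,
                       pi_lo = pi_lo, pi_hi = pi_hi),
            class = c("interval_band", "data.frame"),
            measure = measure, level = level, method = "delta",
            df = df, sigma = sigma)
}

# fabricated growth_fit with full control over covariance and sigma
make_fit <- function(beta, sigma, n_obs = 880, param_cov = matrix(0, 6, 6),
                     measure = "GMV") {
  structure(list(measure = measure, beta = stats::setNames(beta, paste0("beta", 0:5)),
                 sigma = sigma, n_obs = n_obs, df = n_obs - 6,
                 param_cov = param_cov, sse = sigma^2 * (n_obs - 6),
                 converged = TRUE, n_starts_tried = 0L,
                 settings = fit_settings()),
            class = "growth_fit")
}

# minimal valid study table rows
make_records <- function(study_id, n, age_years, tiv = 1500, gmv = 700,
                         wmv = 450, cohort_id = study_id, group_label = NA) {
  out <- data.frame(study_id = study_id, group_label = group_label,
                    cohort_id = cohort_id, n = as.integer(n),
                    age_years = age_years,
                    tiv_mean_cm3 = tiv, tiv_sd_cm3 = 150,
                    gmv_mean_cm3 = gmv, gmv_sd_cm3 = 70,
                    wmv_mean_cm3 = wmv, wmv_sd_cm3 = 50,
                    ga_weeks = 29, bw_grams = 1200, male_pct = 50,
                    year_of_birth = NA_character_, country = "x",
                    segmentation_method = "x")
  class(out) <- c("study_table", "data.frame")
  out
}

write_temp_csv <- function(lines) {
  p <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, p)
  p
}
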