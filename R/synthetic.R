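#' Default true parameter vectors of the synthetic full-term world
#'
#' The shipped generative curves are design choices, not estimates from
#' any real dataset. They are shaped to match the qualitative lifespan
#' volumetry picture: grey matter volume rises rapidly in infancy, peaks
#' at school age (between 6 and 12 years) around 790 cm^3 and declines
#' toward early adulthood; white matter volume rises monotonically through
#' age 30 toward roughly 520 cm^3.
#'
#' @return named list with 6-vectors `GMV` and `WMV` (beta0..beta5).
#' @export
default_true_beta <- function() {
  list(GMV = c(beta0 = 400, beta1 = 12, beta2 = -1.0, beta3 = 0.018,
               beta4 = 350, beta5 = 1.5),
       WMV = c(beta0 = 120, beta1 = 5, beta2 = 0, beta3 = 0,
               beta4 = 250, beta5 = 2.5))
}

#' Configuration of the full-term cohort generator
#'
#' Describes the synthetic reference pool: sample size, uniform age range,
#' source-dataset composition (defaulting to the 236/375/169/100 split of
#' the four public paediatric/adult MRI datasets the emulated pool draws
#' from), the true grey- and white-matter mean curves, homoscedastic
#' Gaussian noise levels (about 6% of typical volume), and the TIV
#' reconciliation rule: total intracranial volume is generated as
#' `(GMV + WMV) / r` with `r` a truncated normal brain-fill ratio, which
#' guarantees `gmv + wmv < tiv` for every subject by construction.
#'
#' @param seed integer seed driving every random draw.
#' @param n_subjects number of subjects (default 880).
#' @param age_range length-2 vector of the uniform age distribution in
#'   years (default 0.7 to 30).
#' @param dataset_weights named non-negative weights over source-dataset
#'   labels; subjects are apportioned to labels by deterministic
#'   largest-remainder allocation so default counts are hit exactly.
#' @param beta_gmv,beta_wmv true 6-vectors of the hybrid mean curves.
#' @param sigma_gmv,sigma_wmv residual SDs in cm^3.
#' @param male_frac expected fraction of male subjects.
#' @param tiv_ratio_mean,tiv_ratio_sd,tiv_ratio_bounds parameters of the
#'   truncated-normal brain-fill ratio `r = (gmv + wmv)/tiv`.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_subjects = 880,
                             age_range = c(0.7, 30),
                             dataset_weights = c("C-MIND" = 236, "NDAR-NIHPD" = 375,
                                                 "ICBM" = 169, "IXI" = 100) / 880,
                             beta_gmv = default_true_beta()$GMV,
                             beta_wmv = default_true_beta()$WMV,
                             sigma_gmv = 45,
                             sigma_wmv = 25,
                             male_frac = 0.5,
                             tiv_ratio_mean = 0.85,
                             tiv_ratio_sd = 0.02,
                             tiv_ratio_bounds = c(0.7, 0.95)) {
  if (!is_scalar_number(seed))
    abort2("seed must be a single finite number", "normtraj_schema_error")
  if (!is_scalar_number(n_subjects) || n_subjects < 1)
    abort2("n_subjects must be >= 1", "normtraj_schema_error")
  if (sigma_gmv < 0 || sigma_wmv < 0)
    abort2("sigma must be >= 0", "normtraj_schema_error")
  if (is.null(names(dataset_weights)) || any(dataset_weights < 0) ||
      sum(dataset_weights) <= 0)
    abort2("dataset_weights must be named and non-negative with positive sum",
           "normtraj_schema_error")
  check_beta(unname(beta_gmv)); check_beta(unname(beta_wmv))
  stopifnot(length(age_range) == 2L, age_range[1] > 0,
            age_range[1] <= age_range[2],
            tiv_ratio_bounds[1] > 0, tiv_ratio_bounds[2] < 1)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 age_range = age_range,
                 dataset_weights = dataset_weights / sum(dataset_weights),
                 beta_gmv = unname(beta_gmv), beta_wmv = unname(beta_wmv),
                 sigma_gmv = sigma_gmv, sigma_wmv = sigma_wmv,
                 male_frac = male_frac,
                 tiv_ratio_mean = tiv_ratio_mean,
                 tiv_ratio_sd = tiv_ratio_sd,
                 tiv_ratio_bounds = tiv_ratio_bounds),
            class = "generator_config")
}

#' True mean curve of the generator for a measure
#'
#' For `GMV` and `WMV` this is the exact generating curve. `TIV` and the
#' ratio measures have no closed-form mean under the brain-fill-ratio
#' construction; they are approximated by plugging in the mean ratio
#' (`(gmv + wmv)/E[r]` and `gmv_mu / tiv_mu`), an approximation good to
#' well under 1% at the default ratio SD.
#'
#' @param config a `generator_config`.
#' @param measure one of [normtraj_measures()].
#' @param ages numeric ages in years.
#' @return numeric vector of mean values.
#' @export
true_mean_curve <- function(config, measure, ages) {
  measure <- match.arg(measure, normtraj_measures())
  g <- evaluate_hybrid(config$beta_gmv, ages)
  w <- evaluate_hybrid(config$beta_wmv, ages)
  t <- (g + w) / config$tiv_ratio_mean
  switch(measure, GMV = g, WMV = w, TIV = t,
         GMV_over_TIV = g / t, WMV_over_TIV = w / t)
}

rnorm_trunc <- function(n, mean, sd, bounds) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= bounds[1] | x >= bounds[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= bounds[1] | x[bad] >= bounds[2]]
  }
  x
}

#' Generate a synthetic full-term reference cohort
#'
#' Draws ages uniformly over `config$age_range`, grey and white matter
#' volumes as the true hybrid curve plus homoscedastic Gaussian noise,
#' total intracranial volume via the brain-fill-ratio rule, and assigns
#' source-dataset labels with exact largest-remainder counts. Deterministic
#' given `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `subject_id`, `dataset`, `age_years`,
#'   `sex`, `tiv_cm3`, `gmv_cm3`, `wmv_cm3`.
#' @export
generate_ft_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  with_seed(config$seed, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    gmv <- evaluate_hybrid(config$beta_gmv, age) +
      stats::rnorm(n, 0, config$sigma_gmv)
    wmv <- evaluate_hybrid(config$beta_wmv, age) +
      stats::rnorm(n, 0, config$sigma_wmv)
    if (any(gmv <= 0) || any(wmv <= 0)) {
      i <- which(gmv <= 0 | wmv <= 0)[1]
      abort2(sprintf(
        "generation produced a non-positive volume at subject %d (age %.2f); reduce sigma",
        i, age[i]), "normtraj_generation_error")
    }
    r <- rnorm_trunc(n, config$tiv_ratio_mean, config$tiv_ratio_sd,
                     config$tiv_ratio_bounds)
    tiv <- (gmv + wmv) / r
    counts <- largest_remainder(n, config$dataset_weights)
    dataset <- sample(rep(names(config$dataset_weights), counts))
    sex <- ifelse(stats::runif(n) < config$male_frac, "male", "female")
    data.frame(subject_id = sprintf("ft%04d", seq_len(n)),
               dataset = dataset, age_years = age, sex = sex,
               tiv_cm3 = tiv, gmv_cm3 = gmv, wmv_cm3 = wmv)
  })
}

#' Designs for synthetic preterm study groups
#'
#' @param study_id,group_label identifiers of each synthetic group.
#' @param n group sizes.
#' @param age_years mean ages at scan.
#' @param gmv_deficit,wmv_deficit multiplicative factors applied to the
#'   true full-term curves (1 = no deficit; 0.92 = 8% lower).
#' @param sd_gmv,sd_wmv between-subject SDs in cm^3, magnitudes copied
#'   from typical published study tables.
#' @return data.frame of class `pt_study_design`.
#' @export
pt_study_design <- function(study_id, group_label = "", n, age_years,
                            gmv_deficit = 1, wmv_deficit = 1,
                            sd_gmv = 70, sd_wmv = 50) {
  d <- data.frame(study_id = study_id, group_label = group_label,
                  n = as.integer(n), age_years = age_years,
                  gmv_deficit = gmv_deficit, wmv_deficit = wmv_deficit,
                  sd_gmv = sd_gmv, sd_wmv = sd_wmv)
  if (any(d$n < 1) || any(d$gmv_deficit <= 0) || any(d$wmv_deficit <= 0))
    abort2("designs need n >= 1 and positive deficit factors",
           "normtraj_schema_error")
  class(d) <- c("pt_study_design", "data.frame")
  d
}

#' Generate a synthetic preterm study-summary table
#'
#' For every design row, draws `n` subject-level grey and white matter
#' volumes around the deficit-scaled true full-term curve, derives each
#' subject's TIV by the brain-fill-ratio rule, and emits the group means
#' and SDs as one study-table row. With `n = 1` the SDs are emitted as
#' missing, with a warning. Deterministic given `config$seed`.
#'
#' @param designs a [pt_study_design()] data.frame.
#' @param config a [generator_config()] supplying the true curves, the
#'   ratio rule and the seed.
#' @return a `study_table` data.frame (schema of [parse_study_table()]).
#' @export
generate_pt_studies <- function(designs, config) {
  stopifnot(inherits(designs, "pt_study_design"),
            inherits(config, "generator_config"))
  with_seed(config$seed + 1L, {
    rows <- lapply(seq_len(nrow(designs)), function(i) {
      d <- designs[i, ]
      g <- stats::rnorm(d$n, d$gmv_deficit *
                          evaluate_hybrid(config$beta_gmv, d$age_years),
                        d$sd_gmv)
      w <- stats::rnorm(d$n, d$wmv_deficit *
                          evaluate_hybrid(config$beta_wmv, d$age_years),
                        d$sd_wmv)
      r <- rnorm_trunc(d$n, config$tiv_ratio_mean, config$tiv_ratio_sd,
                       config$tiv_ratio_bounds)
      tiv <- (g + w) / r
      if (d$n < 2L)
        warning(sprintf("design '%s': n = 1, emitting SDs as missing",
                        d$study_id), call. = FALSE)
      sd_or_na <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
      data.frame(study_id = d$study_id, group_label = d$group_label,
                 cohort_id = d$study_id, n = d$n, age_years = d$age_years,
                 tiv_mean_cm3 = mean(tiv), tiv_sd_cm3 = sd_or_na(tiv),
                 gmv_mean_cm3 = mean(g), gmv_sd_cm3 = sd_or_na(g),
                 wmv_mean_cm3 = mean(w), wmv_sd_cm3 = sd_or_na(w),
                 ga_weeks = NA_real_, bw_grams = NA_real_,
                 male_pct = NA_real_, year_of_birth = NA_character_,
                 country = "synthetic", segmentation_method = "synthetic")
    })
    out <- do.call(rbind, rows)
    class(out) <- c("study_table", "data.frame")
    out
  })
}

#' Default configuration mimicking the emulated meta-analysis world
#'
#' Bundles a [generator_config()] for an 880-subject full-term pool with
#' the default true curves, plus a 14-row preterm design table copying the
#' packaged study table's sample sizes and mean ages, with an 8% grey
#' matter deficit at all ages and a white matter deficit of 15% in
#' adolescence (ages 12-17) and 5% elsewhere. All numeric choices are
#' generator configuration, not estimates of any real cohort.
#'
#' @param seed integer seed (default 1).
#' @return list with elements `config` and `designs`.
#' @export
default_paper_mimic_config <- function(seed = 1) {
  config <- generator_config(seed = seed)
  tab <- parse_study_table(preterm_table_path())
  adolescent <- tab$age_years >= 12 & tab$age_years <= 17
  designs <- pt_study_design(
    study_id = tab$study_id,
    group_label = ifelse(is.na(tab$group_label), "", tab$group_label),
    n = tab$n, age_years = tab$age_years,
    gmv_deficit = 0.92,
    wmv_deficit = ifelse(adolescent, 0.85, 0.95))
  list(config = config, designs = designs)
}

#' Read / write individual-scan tables
#'
#' CSV schema: `subject_id`, `dataset`, `age_years`, `sex`, `tiv_cm3`,
#' `gmv_cm3`, `wmv_cm3`.
#'
#' @param path CSV file path.
#' @return `read_scans` returns the scans data.frame; `write_scans`
#'   returns `path` invisibly.
#' @export
read_scans <- function(path) {
  if (!file.exists(path))
    abort2(paste0("file not found: ", path), "normtraj_io_error")
  scans <- utils::read.csv(path)
  need <- c("subject_id", "age_years", "tiv_cm3", "gmv_cm3", "wmv_cm3")
  miss <- setdiff(need, names(scans))
  if (length(miss))
    abort2(paste0("scan CSV missing column(s): ", paste(miss, collapse = ", ")),
           "normtraj_schema_error")
  bad <- which(!(scans$age_years > 0) | !(scans$gmv_cm3 > 0) |
                 !(scans$wmv_cm3 > 0) |
                 !(scans$gmv_cm3 + scans$wmv_cm3 < scans$tiv_cm3))
  if (length(bad))
    abort2(sprintf("scan row %d violates volume invariants", bad[1]),
           "normtraj_domain_error")
  scans
}

#' @rdname read_scans
#' @param scans an individual-scan data.frame.
#' @export
write_scans <- function(scans, path) {
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a study table as CSV
#'
#' @param records a `study_table` data.frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
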