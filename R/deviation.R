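#' Ordered deviation categories
#'
#' The ordinal scale a study-group mean is classified into relative to a
#' normative band, from lowest to highest: below the prediction interval,
#' below the confidence interval, within the CI below the fitted mean,
#' within the CI above it, above the CI, above the PI. The two `above_*`
#' categories extend the narrated below-curve vocabulary symmetrically so
#' the classifier is total.
#'
#' @return character vector of the six category labels in order.
#' @export
deviation_categories <- function() {
  c("below_PI", "below_CI", "within_CI_below", "within_CI_above",
    "above_CI", "above_PI")
}

#' Interpolate a band at an arbitrary age
#'
#' Linear interpolation of the fitted mean and all four bounds between
#' adjacent grid ages; exact at grid points. Ages outside the grid raise an
#' error rather than extrapolating.
#'
#' @param band an `interval_band`.
#' @param age a single age in years inside `[min(band$age), max(band$age)]`.
#' @return named numeric vector `(mean, ci_lo, ci_hi, pi_lo, pi_hi)`.
#' @export
band_at_age <- function(band, age) {
  stopifnot(inherits(band, "interval_band"), is_scalar_number(age))
  if (age < min(band$age) || age > max(band$age))
    abort2(sprintf("age %.3g outside the band grid [%.3g, %.3g]; refusing to extrapolate",
                   age, min(band$age), max(band$age)),
           "normtraj_extrapolation_error")
  vapply(c("mean", "ci_lo", "ci_hi", "pi_lo", "pi_hi"), function(col)
    stats::approx(band$age, band[[col]], xout = age, ties = "ordered")$y,
    numeric(1))
}

#' Classify an observed mean against a normative band
#'
#' Boundary convention: the inner intervals are closed, so a value exactly
#' on `ci_lo` or `ci_hi` is "within CI" and a value exactly on `pi_lo` or
#' `pi_hi` is inside the outer band; a value exactly equal to the fitted
#' mean is assigned `within_CI_below` (an arbitrary but fixed tie rule).
#' The category is monotone in the observed value.
#'
#' @param observed_mean observed study-group mean, in band units.
#' @param band_values 5-vector from [band_at_age()] (`mean`, `ci_lo`,
#'   `ci_hi`, `pi_lo`, `pi_hi`).
#' @return one of [deviation_categories()].
#' @export
classify_deviation <- function(observed_mean, band_values) {
  b <- band_values
  if (!(b[["pi_lo"]] <= b[["ci_lo"]] && b[["ci_lo"]] <= b[["mean"]] &&
        b[["mean"]] <= b[["ci_hi"]] && b[["ci_hi"]] <= b[["pi_hi"]]))
    abort2("malformed band: ordering pi_lo <= ci_lo <= mean <= ci_hi <= pi_hi violated",
           "normtraj_state_error")
  x <- observed_mean
  if (x < b[["pi_lo"]]) "below_PI"
  else if (x < b[["ci_lo"]]) "below_CI"
  else if (x <= b[["mean"]]) "within_CI_below"
  else if (x <= b[["ci_hi"]]) "within_CI_above"
  else if (x <= b[["pi_hi"]]) "above_CI"
  else "above_PI"
}

#' Standardized deviation score
#'
#' Continuous companion to the ordinal category:
#' `z = (observed - fitted) / sqrt(s_mean^2 + sigma^2)`, where `s_mean` is
#' the standard error of the fitted mean curve at that age, recovered from
#' the CI half-width and the t-quantile. When `t_quantile` is not given it
#' is recovered from the band itself via
#' `t = sqrt(pi_half^2 - ci_half^2) / sigma`, which is exact for
#' delta-method bands. A study mean exactly on the prediction bound
#' therefore scores `z = +/- t` (about 1.96 for a 95% band at large n).
#'
#' @param observed_mean observed study-group mean.
#' @param fitted_mean fitted normative mean at the same age.
#' @param band_values 5-vector from [band_at_age()].
#' @param fit_sigma residual standard deviation of the normative fit.
#' @param t_quantile optional Student-t quantile used to build the band;
#'   required when `fit_sigma` is 0.
#' @return unitless z score; negating `observed - fitted` negates it.
#' @export
standardized_deviation <- function(observed_mean, fitted_mean, band_values,
                                   fit_sigma, t_quantile = NULL) {
  ci_half <- (band_values[["ci_hi"]] - band_values[["ci_lo"]]) / 2
  pi_half <- (band_values[["pi_hi"]] - band_values[["pi_lo"]]) / 2
  if (is.null(t_quantile)) {
    if (fit_sigma <= 0)
      abort2("cannot recover the t-quantile from a band with sigma = 0; pass t_quantile",
             "normtraj_degenerate_band_error")
    t_quantile <- sqrt(max(pi_half^2 - ci_half^2, 0)) / fit_sigma
    if (t_quantile <= 0)
      abort2("degenerate band: prediction and confidence half-widths coincide despite sigma > 0",
             "normtraj_degenerate_band_error")
  }
  s_mean <- ci_half / t_quantile
  denom <- sqrt(s_mean^2 + fit_sigma^2)
  if (denom <= 0)
    abort2("zero prediction variance; z score undefined",
           "normtraj_degenerate_band_error")
  (observed_mean - fitted_mean) / denom
}

#' Contrast a study table against normative bands
#'
#' Produces one deviation call per study group and measure. Absolute
#' measures use the tabulated means directly; relative measures divide the
#' tissue mean by the TIV mean of the same group. Output is ordered by
#' measure (in [normtraj_measures()] order) and then age.
#'
#' @param records an eligible `study_table` (see [filter_eligible()]).
#' @param fits named list keyed by measure label; each element a list with
#'   components `fit` (a `growth_fit`) and `band` (an `interval_band`
#'   covering every record's age).
#' @return data.frame of class `deviation_calls` with columns `study_id`,
#'   `group_label`, `measure`, `age_years`, `n`, `observed_mean`,
#'   `fitted_mean`, `ci_lo`, `ci_hi`, `pi_lo`, `pi_hi`, `category`,
#'   `z_score`.
#' @export
contrast_table <- function(records, fits) {
  measures <- intersect(normtraj_measures(), names(fits))
  if (!length(measures))
    abort2("fits must be a named list keyed by measure label",
           "normtraj_domain_error")
  rows <- vector("list", length(measures) * nrow(records))
  k <- 0L
  for (m in measures) {
    fit <- fits[[m]]$fit
    band <- fits[[m]]$band
    stopifnot(inherits(fit, "growth_fit"), inherits(band, "interval_band"))
    tq <- stats::qt(1 - (1 - attr(band, "level")) / 2, df = attr(band, "df"))
    ord <- order(records$age_years)
    for (i in ord) {
      r <- records[i, ]
      obs <- switch(m,
        GMV = r$gmv_mean_cm3, WMV = r$wmv_mean_cm3, TIV = r$tiv_mean_cm3,
        GMV_over_TIV = compute_relative_volume(r$gmv_mean_cm3, r$tiv_mean_cm3),
        WMV_over_TIV = compute_relative_volume(r$wmv_mean_cm3, r$tiv_mean_cm3))
      bv <- tryCatch(band_at_age(band, r$age_years), error = function(e) {
        if (inherits(e, "normtraj_extrapolation_error"))
          abort2(sprintf("record '%s' (age %.3g) outside the %s band grid",
                         r$study_id, r$age_years, m),
                 "normtraj_extrapolation_error")
        stop(e)
      })
      k <- k + 1L
      rows[[k]] <- data.frame(
        study_id = r$study_id, group_label = r$group_label, measure = m,
        age_years = r$age_years, n = r$n, observed_mean = obs,
        fitted_mean = bv[["mean"]],
        ci_lo = bv[["ci_lo"]], ci_hi = bv[["ci_hi"]],
        pi_lo = bv[["pi_lo"]], pi_hi = bv[["pi_hi"]],
        category = classify_deviation(obs, bv),
        z_score = standardized_deviation(obs, bv[["mean"]], bv, fit$sigma,
                                         t_quantile = tq))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("deviation_calls", "data.frame")
  out
}

#' Count deviation calls per category and measure
#'
#' @param calls a `deviation_calls` data.frame from [contrast_table()].
#' @return named list (by measure) of named integer vectors over all six
#'   categories, suitable for JSON serialization.
#' @export
category_summary <- function(calls) {
  cats <- deviation_categories()
  by_measure <- split(calls$category, calls$measure)
  lapply(by_measure, function(x) {
    tab <- table(factor(x, levels = cats))
    stats::setNames(as.integer(tab), cats)
  })
}
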