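#' The cubic hybrid growth curve
#'
#' Evaluates the mean curve of the cubic hybrid model,
#' \deqn{f(a; \beta) = \beta_4 (1 - e^{-a/\beta_5}) + \beta_0 + \beta_1 a +
#'   \beta_2 a^2 + \beta_3 a^3,}
#' which combines a saturating-exponential early-growth term (amplitude
#' `beta[5]`, time constant `beta[6]` in years) with a cubic polynomial in
#' age. This functional form is the standard "hybrid" candidate in the
#' lifespan brain-volumetry literature for tissue volumes versus age.
#'
#' @param beta numeric vector of length 6: `(beta0, beta1, beta2, beta3,
#'   beta4, beta5)`. `beta0..beta4` are in measure units (cm^3, or a
#'   unitless fraction for relative volumes); `beta5` is in years and must
#'   be positive.
#' @param age numeric vector of ages in years, `>= 0`.
#' @return numeric vector of noise-free mean values, one per age.
#' @examples
#' evaluate_hybrid(c(100, 1, -0.1, 0.001, 50, 2), 10)
#' @export
evaluate_hybrid <- function(beta, age) {
  check_beta(beta)
  if (any(age < 0)) abort2("age must be >= 0", "normtraj_domain_error")
  beta[5] * (1 - exp(-age / beta[6])) +
    beta[1] + beta[2] * age + beta[3] * age^2 + beta[4] * age^3
}

#' Gradient of the hybrid curve in its parameters
#'
#' Partial derivatives of [evaluate_hybrid()] with respect to
#' `beta0..beta5`, the delta-method ingredient for the band computations:
#' `(1, a, a^2, a^3, 1 - e^(-a/beta5), -beta4 * (a/beta5^2) * e^(-a/beta5))`.
#'
#' @inheritParams evaluate_hybrid
#' @return if `age` has length 1, a numeric vector of length 6; otherwise a
#'   `length(age) x 6` matrix with one row per age.
#' @export
hybrid_gradient <- function(beta, age) {
  check_beta(beta)
  if (any(age < 0)) abort2("age must be >= 0", "normtraj_domain_error")
  e <- exp(-age / beta[6])
  g <- cbind(1, age, age^2, age^3, 1 - e, -beta[5] * (age / beta[6]^2) * e)
  colnames(g) <- paste0("beta", 0:5)
  if (length(age) == 1L) drop(g) else g
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 6L || anyNA(beta))
    abort2("beta must be a numeric 6-vector (beta0..beta5)",
           "normtraj_domain_error")
  if (beta[6] <= 0)
    abort2("beta5 (the saturation time constant) must be > 0",
           "normtraj_domain_error")
  invisible(beta)
}

#' Measure labels modelled by the package
#'
#' The five measures fitted against age: absolute grey matter volume,
#' white matter volume, total intracranial volume (all cm^3), and the two
#' head-size-controlled ratios GMV/TIV and WMV/TIV (unitless).
#'
#' @return character vector of the five measure labels.
#' @export
normtraj_measures <- function() {
  c("GMV", "WMV", "TIV", "GMV_over_TIV", "WMV_over_TIV")
}

# Extract the response vector for one measure from an individual-scan table.
measure_values <- function(scans, measure) {
  measure <- match.arg(measure, normtraj_measures())
  switch(measure,
    GMV = scans$gmv_cm3,
    WMV = scans$wmv_cm3,
    TIV = scans$tiv_cm3,
    GMV_over_TIV = scans$gmv_cm3 / scans$tiv_cm3,
    WMV_over_TIV = scans$wmv_cm3 / scans$tiv_cm3
  )
}
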