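#' Default age grid for band computation
#'
#' Ages 0.7 to 30 years in steps of 0.1, the span of the full-term
#' reference pool the package emulates.
#'
#' @param from,to,by grid specification in years.
#' @return numeric vector of ages.
#' @export
default_age_grid <- function(from = 0.7, to = 30, by = 0.1) {
  seq(from, to, by = by)
}

# shared construction of an interval_band
new_band <- function(fit, ages, level, method, mean, ci_lo, ci_hi,
                     pi_lo, pi_hi) {
  band <- data.frame(age = ages, mean = mean,
                     ci_lo = ci_lo, ci_hi = ci_hi,
                     pi_lo = pi_lo, pi_hi = pi_hi)
  structure(band, class = c("interval_band", "data.frame"),
            measure = fit$measure, level = level, method = method,
            df = fit$df, sigma = fit$sigma)
}

check_band_inputs <- function(fit, ages, level) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged))
    abort2("fit did not converge; no bands available", "normtraj_state_error")
  if (!is_scalar_number(level) || level <= 0 || level >= 1)
    abort2("level must be in (0, 1)", "normtraj_domain_error")
  if (is.unsorted(ages, strictly = TRUE))
    abort2("ages must be a strictly increasing grid", "normtraj_domain_error")
  invisible(TRUE)
}

# delta-method standard error of the mean curve at each age
delta_se_mean <- function(fit, ages) {
  G <- hybrid_gradient(fit$beta, ages)
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  sqrt(pmax(rowSums((G %*% fit$param_cov) * G), 0))
}

#' Pointwise confidence band for the fitted mean curve
#'
#' First-order delta-method band: at each grid age `a` the half-width is
#' `t_{1-(1-level)/2, df} * sqrt(g(a)' V g(a))` with `g` the parameter
#' gradient of the curve ([hybrid_gradient()]) and `V` the parameter
#' covariance. The returned object also carries the matching prediction
#' bounds (see [prediction_band()]), so the band-ordering invariant
#' `pi_lo <= ci_lo <= mean <= ci_hi <= pi_hi` can always be checked on one
#' object.
#'
#' @param fit a converged [fit_hybrid()] result.
#' @param ages strictly increasing age grid in years
#'   (default [default_age_grid()]).
#' @param level coverage fraction in (0, 1); default 0.95.
#' @return an `interval_band`: data.frame with columns `age`, `mean`,
#'   `ci_lo`, `ci_hi`, `pi_lo`, `pi_hi` and attributes `measure`, `level`,
#'   `method` (`"delta"`), `df`, `sigma`.
#' @export
confidence_band <- function(fit, ages = default_age_grid(), level = 0.95) {
  delta_band(fit, ages, level)
}

#' Pointwise prediction band for a new individual observation
#'
#' Same delta-method construction as [confidence_band()] but with the
#' residual variance added: half-width
#' `t * sqrt(g(a)' V g(a) + sigma^2)`. The prediction band contains the
#' confidence band pointwise and is the band a new full-term individual's
#' volume is expected to fall inside with probability `level`.
#'
#' @inheritParams confidence_band
#' @return an `interval_band` (same layout as [confidence_band()]).
#' @export
prediction_band <- function(fit, ages = default_age_grid(), level = 0.95) {
  delta_band(fit, ages, level)
}

delta_band <- function(fit, ages, level) {
  check_band_inputs(fit, ages, level)
  mu <- evaluate_hybrid(fit$beta, ages)
  se <- delta_se_mean(fit, ages)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  ci_half <- tq * se
  pi_half <- tq * sqrt(se^2 + fit$sigma^2)
  new_band(fit, ages, level, "delta", mu,
           mu - ci_half, mu + ci_half, mu - pi_half, mu + pi_half)
}

#' Monte-Carlo propagated confidence and prediction band
#'
#' Parametric Monte-Carlo alternative to the first-order delta method:
#' parameter vectors are drawn from `MVN(beta_hat, V)` (draws violating
#' `beta5 > 0` are rejected and redrawn; their count is reported as the
#' `n_rejected` attribute), the curve is evaluated at each grid age, and
#' the confidence bounds are the empirical `(1-level)/2` and
#' `1-(1-level)/2` quantiles. Prediction bounds add an independent
#' `N(0, sigma^2)` residual draw per curve before taking quantiles.
#'
#' @inheritParams confidence_band
#' @param n_draws number of parameter draws, at least 1000.
#' @param seed integer seed; the same seed reproduces the band exactly and
#'   the caller's RNG stream is left untouched.
#' @return an `interval_band` with `method = "monte_carlo"`.
#' @export
mc_band <- function(fit, ages = default_age_grid(), level = 0.95,
                    n_draws = 10000, seed) {
  check_band_inputs(fit, ages, level)
  if (!is_scalar_number(n_draws) || n_draws < 1000)
    abort2("n_draws must be >= 1000", "normtraj_domain_error")
  if (missing(seed)) abort2("mc_band requires an explicit seed",
                            "normtraj_domain_error")
  n_draws <- as.integer(n_draws)

  draws <- with_seed(seed, {
    B <- matrix(NA_real_, n_draws, 6)
    need <- seq_len(n_draws)
    n_rej <- 0L
    while (length(need)) {
      cand <- MASS::mvrnorm(length(need), mu = fit$beta,
                            Sigma = fit$param_cov)
      if (length(need) == 1L) cand <- matrix(cand, nrow = 1)
      ok <- cand[, 6] > 0
      n_rej <- n_rej + sum(!ok)
      if (n_rej > n_draws / 2 && n_rej > 100L)
        abort2(paste0("beta5 rejection rate exceeds 50%: the parameter ",
                      "covariance is inconsistent with the beta5 > 0 bound"),
               "normtraj_propagation_error")
      B[need[ok], ] <- cand[ok, , drop = FALSE]
      need <- need[!ok]
    }
    list(B = B, eps = stats::rnorm(n_draws, 0, fit$sigma), n_rej = n_rej)
  })

  mu <- evaluate_hybrid(fit$beta, ages)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  # curves: n_draws x n_ages
  curves <- vapply(ages, function(a) evaluate_hybrid_rows(draws$B, a),
                   numeric(n_draws))
  qci <- apply(curves, 2, stats::quantile, probs = probs, names = FALSE)
  qpi <- apply(curves + draws$eps, 2, stats::quantile, probs = probs,
               names = FALSE)
  band <- new_band(fit, ages, level, "monte_carlo", mu,
                   qci[1, ], qci[2, ], qpi[1, ], qpi[2, ])
  attr(band, "n_rejected") <- draws$n_rej
  attr(band, "seed") <- seed
  band
}

# hybrid curve at a single age for many parameter rows
evaluate_hybrid_rows <- function(B, age) {
  B[, 5] * (1 - exp(-age / B[, 6])) +
    B[, 1] + B[, 2] * age + B[, 3] * age^2 + B[, 4] * age^3
}

#' @export
print.interval_band <- function(x, ...) {
  cat(sprintf("%s band -- %s, level %.3g, %d grid ages in [%g, %g]\n",
              attr(x, "method"), attr(x, "measure"), attr(x, "level"),
              nrow(x), min(x$age), max(x$age)))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write a band table as CSV
#'
#' Columns: age, mean, ci_lo, ci_hi, pi_lo, pi_hi, method, level, measure.
#'
#' @param band an `interval_band`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_csv <- function(band, path) {
  stopifnot(inherits(band, "interval_band"))
  out <- as.data.frame(band)
  out$method <- attr(band, "method")
  out$level <- attr(band, "level")
  out$measure <- attr(band, "measure")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
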