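#' Settings for fitting the hybrid growth model
#'
#' @param beta5_grid numeric vector of starting values (years) for the
#'   saturation time constant. The residual sum of squares is profiled at
#'   each grid point before local refinement, which makes the weakly
#'   identified exponential term reproducible.
#' @param beta5_bounds length-2 numeric, box constraint on `beta5` in
#'   years. The lower bound keeps `exp(-age/beta5)` from degenerating.
#' @param fix_zero character vector naming coefficients among
#'   `"beta1", "beta2", "beta3", "beta4"` to freeze at zero (e.g. freeze
#'   `beta2..beta4` to fit a plain regression line). `beta0` is always
#'   estimated; freezing `beta4` removes `beta5` from the model.
#' @return an object of class `fit_settings`.
#' @export
fit_settings <- function(beta5_grid = c(0.25, 0.5, 1, 2, 4, 8),
                         beta5_bounds = c(1e-3, 50),
                         fix_zero = character()) {
  stopifnot(is.numeric(beta5_grid), all(beta5_grid > 0),
            length(beta5_bounds) == 2L, beta5_bounds[1] > 0,
            beta5_bounds[1] < beta5_bounds[2])
  bad <- setdiff(fix_zero, c("beta1", "beta2", "beta3", "beta4"))
  if (length(bad))
    abort2(paste0("cannot freeze: ", paste(bad, collapse = ", ")),
           "normtraj_domain_error")
  structure(list(beta5_grid = sort(unique(beta5_grid)),
                 beta5_bounds = beta5_bounds,
                 fix_zero = unique(fix_zero)),
            class = "fit_settings")
}

#' Fit the cubic hybrid growth model to individual-level scans
#'
#' Minimizes the residual sum of squares of the hybrid curve
#' (see [evaluate_hybrid()]) over `beta0..beta5` with `beta5` constrained
#' to `settings$beta5_bounds`. Because the model is linear in
#' `beta0..beta4` once `beta5` is fixed, the fit uses variable projection:
#' the linear coefficients are profiled out by ordinary least squares and
#' the one-dimensional profiled objective is minimized over `beta5`
#' (grid scan over `settings$beta5_grid`, then golden-section refinement).
#' This reaches the same least-squares optimum as a damped (Levenberg type)
#' full search but is deterministic and immune to poor starting values.
#'
#' The residual variance is estimated as `SSE / (n - p)` with `p` the
#' number of free parameters (6 for the full model), and the parameter
#' covariance as `sigma^2 * (J'J)^{-1}` with `J` the Jacobian of the mean
#' function at the optimum.
#'
#' @param scans data.frame of individual scans with columns `age_years`,
#'   `gmv_cm3`, `wmv_cm3`, `tiv_cm3` (see [generate_ft_cohort()] or
#'   [read_scans()]). Ratio measures are computed per subject before
#'   fitting.
#' @param measure one of [normtraj_measures()].
#' @param settings a [fit_settings()] object.
#' @return an object of class `growth_fit`: list with elements `measure`,
#'   `beta` (named 6-vector; frozen coefficients are exactly 0), `sigma`,
#'   `n_obs`, `df`, `param_cov` (6x6, zero rows/columns for frozen
#'   parameters), `sse`, `converged`, `n_starts_tried`, `settings`.
#' @examples
#' cfg <- generator_config(seed = 1, n_subjects = 200)
#' fit <- fit_hybrid(generate_ft_cohort(cfg), "GMV")
#' fit$beta
#' @export
fit_hybrid <- function(scans, measure, settings = fit_settings()) {
  stopifnot(inherits(settings, "fit_settings"))
  measure <- match.arg(measure, normtraj_measures())
  age <- scans$age_years
  y <- measure_values(scans, measure)
  if (anyNA(age) || anyNA(y))
    abort2("scans contain missing age or volume values",
           "normtraj_domain_error")

  free <- free_indices(settings$fix_zero)          # indices into beta0..beta5
  p <- length(free)
  n <- length(y)
  if (n <= p)
    abort2(sprintf(
      "insufficient data: %d observations for %d free parameters", n, p),
      "normtraj_insufficient_data_error")
  if (length(unique(age)) < 2L)
    abort2("all ages identical; the age trend is not identifiable",
           "normtraj_nonidentifiable_error")

  beta4_free <- 5L %in% free
  lin_cols <- function(b5) {
    X <- cbind(1, age, age^2, age^3, 1 - exp(-age / b5))
    X[, free[free <= 5L], drop = FALSE]
  }
  profile_sse <- function(b5) {
    f <- stats::.lm.fit(lin_cols(b5), y)
    sum(f$residuals^2)
  }

  if (beta4_free) {
    lo <- settings$beta5_bounds[1]; hi <- settings$beta5_bounds[2]
    cand <- sort(unique(pmin(pmax(c(settings$beta5_grid, lo, hi), lo), hi)))
    sse_cand <- vapply(cand, function(b) tryCatch(profile_sse(b),
                                                  error = function(e) Inf),
                       numeric(1))
    if (!any(is.finite(sse_cand)))
      abort2("no beta5 start produced a finite least-squares solution",
             "normtraj_convergence_error")
    i <- which.min(sse_cand)
    bracket <- c(cand[max(1L, i - 1L)], cand[min(length(cand), i + 1L)])
    if (bracket[1] < bracket[2]) {
      opt <- stats::optimize(profile_sse, interval = bracket, tol = 1e-9)
      beta5 <- if (opt$objective <= sse_cand[i]) opt$minimum else cand[i]
    } else beta5 <- cand[i]
    n_starts <- length(cand)
  } else {
    beta5 <- settings$beta5_grid[1]   # inert: saturating term is frozen out
    n_starts <- 0L
  }

  ls <- stats::lm.fit(lin_cols(beta5), y)
  beta <- numeric(6)
  beta[free[free <= 5L]] <- ls$coefficients
  beta[6] <- beta5
  names(beta) <- paste0("beta", 0:5)
  sse <- sum(ls$residuals^2)
  df <- n - p
  sigma2 <- sse / df

  J <- hybrid_gradient(beta, age)[, free, drop = FALSE]
  JtJ <- crossprod(J)
  R <- tryCatch(chol(JtJ), error = function(e) NULL)
  if (is.null(R) || min(abs(diag(R))) < 1e-10 * max(abs(diag(R))))
    abort2(paste0(
      "J'J is (near-)singular at the optimum; the model is not ",
      "identifiable on these data -- inspect the observed age range"),
      "normtraj_nonidentifiable_error")
  cov_free <- sigma2 * chol2inv(R)
  param_cov <- matrix(0, 6, 6, dimnames = list(names(beta), names(beta)))
  param_cov[free, free] <- (cov_free + t(cov_free)) / 2

  structure(list(measure = measure, beta = beta,
                 sigma = sqrt(sigma2), n_obs = n, df = df,
                 param_cov = param_cov, sse = sse,
                 converged = TRUE, n_starts_tried = n_starts,
                 settings = settings),
            class = "growth_fit")
}

# beta indices (1-based into beta0..beta5) that are estimated
free_indices <- function(fix_zero) {
  idx <- c(beta1 = 2L, beta2 = 3L, beta3 = 4L, beta4 = 5L)
  free <- c(1L, unname(idx[setdiff(names(idx), fix_zero)]))
  if (5L %in% free) free <- c(free, 6L)
  sort(free)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Cubic hybrid growth fit --", x$measure, "\n")
  cat(sprintf("  n = %d, SSE = %.6g, sigma = %.6g, df = %d\n",
              x$n_obs, x$sse, x$sigma, x$df))
  print(signif(x$beta, 6))
  invisible(x)
}

#' Write a fit report as JSON
#'
#' @param fit a `growth_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "growth_fit"))
  jsonlite::write_json(list(
    measure = fit$measure, beta = as.list(fit$beta), sigma = fit$sigma,
    n_obs = fit$n_obs, df = fit$df, sse = fit$sse,
    converged = fit$converged, n_starts_tried = fit$n_starts_tried,
    param_cov = fit$param_cov,
    settings = list(beta5_grid = fit$settings$beta5_grid,
                    beta5_bounds = fit$settings$beta5_bounds,
                    fix_zero = fit$settings$fix_zero)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
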