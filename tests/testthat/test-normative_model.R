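test_that("hybrid curve evaluates its closed form", {
  beta <- c(100, 1, -0.1, 0.001, 50, 2)
  expect_equal(evaluate_hybrid(beta, 0), 100)             # only beta0 survives
  expect_equal(evaluate_hybrid(c(100, 0, 0, 0, 50, 2), 1e4), 150,
               tolerance = 1e-12)                          # saturation asymptote
  expect_equal(evaluate_hybrid(beta, 10),
               100 + 10 - 10 + 1 + 50 * (1 - exp(-5)))
  expect_equal(evaluate_hybrid(beta, 10), 150.6631, tolerance = 1e-6)
  expect_error(evaluate_hybrid(c(1, 0, 0, 0, 0, -1), 5),
               class = "normtraj_domain_error")
  expect_error(evaluate_hybrid(1:5, 5), class = "normtraj_domain_error")
})

test_that("hybrid gradient matches hand values and finite differences", {
  expect_equal(unname(hybrid_gradient(c(1, 2, 3, 4, 5, 6), 0)),
               c(1, 0, 0, 0, 0, 0))
  g <- hybrid_gradient(c(0, 0, 0, 0, 50, 2), 2)
  expect_equal(unname(g[5]), 1 - exp(-1))
  expect_equal(unname(g[6]), -50 * (2 / 4) * exp(-1))
  expect_equal(unname(g[6]), -9.196986, tolerance = 1e-6)
  expect_equal(unname(hybrid_gradient(c(1, 1, 1, 1, 0, 2), 7)[6]), 0)

  # central finite differences at random parameter points and ages
  # (step 1e-4: small enough for O(h^2) truncation, large enough to avoid
  # cancellation on curve values up to ~1e5)
  set.seed(41)
  h <- 1e-4
  for (i in 1:100) {
    beta <- c(stats::runif(4, -2, 2), stats::runif(1, 10, 300),
              stats::runif(1, 0.5, 8))
    a <- stats::runif(1, 0.2, 30)
    fd <- vapply(1:6, function(j) {
      hj <- h * max(1, abs(beta[j]))
      bp <- beta; bp[j] <- bp[j] + hj
      bm <- beta; bm[j] <- bm[j] - hj
      (evaluate_hybrid(bp, a) - evaluate_hybrid(bm, a)) / (2 * hj)
    }, numeric(1))
    g <- unname(hybrid_gradient(beta, a))
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("zero-noise cohorts are recovered to numerical precision", {
  cfg <- generator_config(seed = 8, n_subjects = 150, sigma_gmv = 0,
                          sigma_wmv = 0)
  scans <- generate_ft_cohort(cfg)
  grid <- default_age_grid()
  for (m in c("GMV", "WMV")) {
    fit <- fit_hybrid(scans, m)
    truth <- true_mean_curve(cfg, m, grid)
    expect_lt(max(abs(evaluate_hybrid(fit$beta, grid) - truth)),
              1e-6 * max(truth))
    # residual noise is zero, so the prediction band collapses onto the CI
    b <- prediction_band(fit, grid)
    expect_equal(b$pi_lo, b$ci_lo, tolerance = 1e-6)
    expect_equal(b$pi_hi, b$ci_hi, tolerance = 1e-6)
  }
})

test_that("frozen-cubic fit reproduces the closed-form regression line", {
  set.seed(7)
  n <- 80
  a <- stats::runif(n, 1, 30)
  y <- 420 + 3.5 * a + stats::rnorm(n, 0, 12)
  scans <- data.frame(age_years = a, gmv_cm3 = y, wmv_cm3 = y / 3,
                      tiv_cm3 = 2 * y)
  fit <- fit_hybrid(scans, "GMV",
                    fit_settings(fix_zero = c("beta2", "beta3", "beta4")))
  ols <- stats::lm(y ~ a)
  expect_equal(unname(fit$beta[1:2]), unname(stats::coef(ols)),
               tolerance = 1e-9)
  expect_equal(fit$beta[3:5], c(beta2 = 0, beta3 = 0, beta4 = 0))
  expect_equal(fit$df, ols$df.residual)
  expect_equal(fit$sigma, summary(ols)$sigma, tolerance = 1e-9)

  grid <- seq(1, 30, by = 0.5)
  band <- confidence_band(fit, grid)
  ci <- stats::predict(ols, data.frame(a = grid), interval = "confidence")
  pi <- stats::predict(ols, data.frame(a = grid), interval = "prediction")
  expect_equal(band$mean, unname(ci[, "fit"]), tolerance = 1e-6)
  expect_equal(band$ci_lo, unname(ci[, "lwr"]), tolerance = 1e-6)
  expect_equal(band$ci_hi, unname(ci[, "upr"]), tolerance = 1e-6)
  expect_equal(band$pi_lo, unname(pi[, "lwr"]), tolerance = 1e-6)
  expect_equal(band$pi_hi, unname(pi[, "upr"]), tolerance = 1e-6)
})

test_that("fit rejects degenerate inputs", {
  cfg <- generator_config(seed = 2, n_subjects = 5)
  expect_error(fit_hybrid(generate_ft_cohort(cfg), "GMV"),
               class = "normtraj_insufficient_data_error")
  same_age <- data.frame(age_years = rep(5, 20), gmv_cm3 = stats::rnorm(20, 700, 10),
                         wmv_cm3 = rep(400, 20), tiv_cm3 = rep(1400, 20))
  expect_error(fit_hybrid(same_age, "GMV"),
               class = "normtraj_nonidentifiable_error")
})

test_that("delta bands are ordered, symmetric, and shrink with n", {
  cfg <- generator_config(seed = 31, n_subjects = 250)
  fit <- fit_hybrid(generate_ft_cohort(cfg), "GMV")
  grid <- default_age_grid()
  b <- confidence_band(fit, grid)
  expect_true(all(b$pi_lo <= b$ci_lo & b$ci_lo <= b$mean &
                    b$mean <= b$ci_hi & b$ci_hi <= b$pi_hi))
  expect_equal(b$ci_hi - b$mean, b$mean - b$ci_lo, tolerance = 1e-9)
  expect_equal(b$pi_hi - b$mean, b$mean - b$pi_lo, tolerance = 1e-9)

  cfg_big <- generator_config(seed = 31, n_subjects = 4000)
  fit_big <- fit_hybrid(generate_ft_cohort(cfg_big), "GMV")
  b_big <- confidence_band(fit_big, grid)
  inner <- grid >= 2 & grid <= 28
  expect_true(all((b_big$ci_hi - b_big$ci_lo)[inner] <
                    (b$ci_hi - b$ci_lo)[inner]))
  # PI half-width approaches t * sigma from above as n grows
  tq <- stats::qt(0.975, fit_big$df)
  expect_true(all((b_big$pi_hi - b_big$pi_lo) / 2 >= tq * fit_big$sigma))
  expect_lt(max((b_big$pi_hi - b_big$pi_lo) / 2 - tq * fit_big$sigma) /
              (tq * fit_big$sigma), 0.05)
})

test_that("degenerate uncertainty collapses the bands as expected", {
  beta <- c(400, 12, -1, 0.018, 350, 1.5)
  grid <- seq(1, 29, by = 1)
  # no parameter uncertainty: CI degenerates to the mean curve
  f0 <- make_fit(beta, sigma = 10)
  b0 <- confidence_band(f0, grid)
  expect_equal(b0$ci_lo, b0$mean)
  expect_equal(b0$ci_hi, b0$mean)
  # ... and the PI has constant half-width t * sigma
  tq <- stats::qt(0.975, f0$df)
  expect_equal(b0$pi_hi - b0$mean, rep(tq * 10, length(grid)))

  bad <- make_fit(beta, sigma = 10)
  bad$converged <- FALSE
  expect_error(confidence_band(bad, grid), class = "normtraj_state_error")
  expect_error(confidence_band(f0, grid, level = 1.2),
               class = "normtraj_domain_error")
})

test_that("Monte-Carlo bands are seeded, ordered and agree with the delta method", {
  # low noise keeps the fit well-conditioned, where the first-order delta
  # band is an oracle for the MC propagation (see methods vignette)
  cfg <- generator_config(seed = 77, sigma_gmv = 5, sigma_wmv = 5)
  fit <- fit_hybrid(generate_ft_cohort(cfg), "GMV")
  grid <- seq(5, 25, by = 2.5)

  m1 <- mc_band(fit, grid, seed = 123, n_draws = 2000)
  m2 <- mc_band(fit, grid, seed = 123, n_draws = 2000)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  m3 <- mc_band(fit, grid, seed = 124, n_draws = 2000)
  expect_false(identical(m1$ci_lo, m3$ci_lo))
  expect_true(all(m1$pi_lo <= m1$ci_lo & m1$ci_lo <= m1$mean &
                    m1$mean <= m1$ci_hi & m1$ci_hi <= m1$pi_hi))

  # the MC stream must not disturb the caller's RNG
  set.seed(5); before <- stats::runif(1)
  set.seed(5); invisible(mc_band(fit, grid, seed = 9, n_draws = 1000))
  expect_identical(stats::runif(1), before)

  d <- confidence_band(fit, grid)
  mc <- mc_band(fit, grid, seed = 2024, n_draws = 10000)
  rel <- abs((mc$ci_hi - mc$ci_lo) - (d$ci_hi - d$ci_lo)) /
    (d$ci_hi - d$ci_lo)
  expect_lt(max(rel), 0.10)
  rel_pi <- abs((mc$pi_hi - mc$pi_lo) - (d$pi_hi - d$pi_lo)) /
    (d$pi_hi - d$pi_lo)
  expect_lt(max(rel_pi), 0.10)

  # degenerate fit: both bands equal the mean curve
  f0 <- make_fit(fit$beta, sigma = 0)
  mc0 <- mc_band(f0, grid, seed = 1, n_draws = 1000)
  expect_equal(mc0$ci_lo, mc0$mean)
  expect_equal(mc0$pi_hi, mc0$mean)

  expect_error(mc_band(fit, grid, seed = 1, n_draws = 10),
               class = "normtraj_domain_error")
  expect_error(mc_band(fit, grid, n_draws = 1000),
               class = "normtraj_domain_error")
})

test_that("fits and bands serialize to JSON / CSV and reload consistently", {
  cfg <- generator_config(seed = 4, n_subjects = 200)
  fit <- fit_hybrid(generate_ft_cohort(cfg), "WMV")
  p <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$measure, "WMV")
  expect_equal(unlist(back$beta), fit$beta, tolerance = 1e-12)
  expect_equal(back$sigma, fit$sigma, tolerance = 1e-12)

  band <- confidence_band(fit, seq(1, 29, 1))
  pb <- withr::local_tempfile(fileext = ".csv")
  write_band_csv(band, pb)
  tab <- utils::read.csv(pb)
  expect_equal(nrow(tab), 29)
  expect_equal(unique(tab$measure), "WMV")
  expect_equal(tab$ci_lo, band$ci_lo, tolerance = 1e-6)
})
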