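test_that("clipped_logit matches direct evaluation and clips boundaries", {
  expect_identical(clipped_logit(0.5), 0)
  expect_equal(clipped_logit(0.73), log(0.73 / 0.27), tolerance = 1e-12)
  expect_equal(round(clipped_logit(0.73), 4), 0.9946)
  expect_equal(clipped_logit(0, eps = 1e-6), qlogis(1e-6), tolerance = 1e-12)
  expect_equal(round(clipped_logit(0, eps = 1e-6), 4), -13.8155)
  expect_equal(clipped_logit(1, eps = 0.01), -clipped_logit(0, eps = 0.01),
               tolerance = 1e-12)
  expect_error(clipped_logit(1.2), "\\[0, 1\\]")
  expect_error(clipped_logit(0.5, eps = 0.7), "eps")
})

test_that("weak calibration fit agrees with the glm oracle", {
  d <- draw_scores(5000, a = -1.1, b = 1.4, seed = 21)
  wc <- fit_weak_calibration(d$p_hat, d$outcome)
  x <- qlogis(pmin(pmax(d$p_hat, 1e-6), 1 - 1e-6))
  g_joint <- glm(d$outcome ~ x, family = binomial)
  g_offset <- glm(d$outcome ~ 1 + offset(x), family = binomial)
  expect_equal(wc$intercept, unname(coef(g_joint)[1]), tolerance = 1e-6)
  expect_equal(wc$slope, unname(coef(g_joint)[2]), tolerance = 1e-6)
  expect_equal(wc$citl, unname(coef(g_offset)[1]), tolerance = 1e-6)
  expect_true(wc$converged)
  expect_identical(wc$n, 5000L)
})

test_that("weak calibration recovers the generating truth at large n", {
  # identity miscalibration
  rec0 <- generate_cohort(single_group_config(100000, seed = 301, a = 0,
                                              b = 1))
  wc0 <- fit_weak_calibration(rec0$p_hat, rec0$outcome)
  expect_lt(abs(wc0$intercept), 0.05)
  expect_lt(abs(wc0$slope - 1), 0.05)
  # strong overestimation with slope above 1 (per-gender magnitude)
  rec1 <- generate_cohort(single_group_config(100000, seed = 302, a = -1.49,
                                              b = 1.42))
  wc1 <- fit_weak_calibration(rec1$p_hat, rec1$outcome)
  expect_lt(abs(wc1$intercept - (-1.49)), 0.05)
  expect_lt(abs(wc1$slope - 1.42), 0.05)
})

test_that("weak calibration rejects degenerate inputs", {
  p <- runif(100, 0.1, 0.9)
  expect_error(fit_weak_calibration(p, rep(0, 100)), "one class")
  expect_error(fit_weak_calibration(rep(0.4, 100), rep(c(0, 1), 50)),
               "unidentifiable")
  expect_error(fit_weak_calibration(p[1:10], rep(c(0, 1), 5)), "at least")
})

test_that("logit-shift invariance: slope unchanged, citl shifts by -delta", {
  d <- draw_scores(4000, a = -0.5, b = 1.2, seed = 31)
  delta <- 0.8
  x <- qlogis(pmin(pmax(d$p_hat, 1e-6), 1 - 1e-6))
  p_shift <- plogis(x + delta)
  wc <- fit_weak_calibration(d$p_hat, d$outcome)
  wc_s <- fit_weak_calibration(p_shift, d$outcome)
  expect_equal(wc_s$slope, wc$slope, tolerance = 1e-8)
  expect_equal(wc_s$citl, wc$citl - delta, tolerance = 1e-6)
})

test_that("Brier score identities hold", {
  # hand computation
  expect_equal(brier_score(c(0.8, 0.2, 0.6), c(1, 0, 0))$brier,
               (0.04 + 0.04 + 0.36) / 3, tolerance = 1e-12)
  # perfect predictions
  expect_identical(brier_score(c(1, 0, 1), c(1, 0, 1))$brier, 0)
  # constant predictor at the prevalence: brier == ybar (1 - ybar) exactly
  y <- rep(c(1, 0), c(30, 70))
  ybar <- mean(y)
  bs <- brier_score(rep(ybar, 100), y)
  expect_equal(bs$brier, ybar * (1 - ybar), tolerance = 1e-15)
  expect_equal(bs$brier_scaled, 0, tolerance = 1e-12)
  # single-class outcome: scaled undefined but raw returned
  bs1 <- brier_score(runif(10, 0.2, 0.4), rep(0, 10))
  expect_false(bs1$scaled_defined)
  expect_true(is.na(bs1$brier_scaled))
  expect_true(is.finite(bs1$brier))
})

test_that("loess curve reproduces constant and linear responses", {
  set.seed(41)
  x <- runif(80)
  const <- fit_loess_curve(x, rep(0.3, 80))
  expect_equal(const$fitted, rep(0.3, length(const$eval_points)),
               tolerance = 1e-8)
  # local linear reproduces a global line at every evaluation point
  yl <- 0.1 + 0.7 * x
  lin <- fit_loess_curve(x, yl, degree = 1)
  expect_equal(lin$fitted, 0.1 + 0.7 * lin$eval_points, tolerance = 1e-8)
})

test_that("loess curve matches the brute-force tricube WLS oracle", {
  set.seed(42)
  n <- 200
  x <- runif(n)
  y <- plogis(-1 + 1.4 * qlogis(x)) + rnorm(n, 0, 0.05)
  for (deg in c(1L, 2L)) {
    cv <- fit_loess_curve(x, y, span = 0.75, degree = deg, exact = TRUE)
    oracle <- loess_bruteforce(cv$eval_points, x, y, span = 0.75,
                               degree = deg)
    expect_equal(cv$fitted, pmin(pmax(oracle, 0), 1), tolerance = 1e-8)
  }
})

test_that("loess curve rejects invalid inputs", {
  x <- runif(30)
  expect_error(fit_loess_curve(x[1:10], rep(0.5, 10)), "at least 20")
  expect_error(fit_loess_curve(rep(c(0.3, 0.6), 15), rbinom(30, 1, 0.5),
                               degree = 2), "distinct")
  expect_error(fit_loess_curve(x, rnorm(30), span = 0), "span")
})

test_that("Eavg/Emax identities and integration oracle", {
  pts <- seq(0.05, 0.9, by = 0.05)
  identity_curve <- structure(
    list(eval_points = pts, fitted = pts, span = 0.75, degree = 1L,
         exact = TRUE, n = length(pts)), class = "smoothed_curve")
  expect_identical(unname(eavg_emax(identity_curve, pts)), c(0, 0))
  shifted <- identity_curve
  shifted$fitted <- pts + 0.1
  expect_equal(unname(eavg_emax(shifted, pts)), c(0.1, 0.1),
               tolerance = 1e-12)
  expect_error(eavg_emax(identity_curve, c(pts, 0.5 + 1e-9)),
               "observed predictions")

  # against the numerically integrated E|c(P) - P| under the generating
  # score distribution, c(p) = expit(-1 + 1.4 logit(p))
  mu <- -1; sig <- 1.25; n <- 50000
  truth <- integrate(function(z)
    abs(plogis(-1 + 1.4 * z) - plogis(z)) * dnorm(z, mu, sig),
    -12, 12, rel.tol = 1e-10)$value
  set.seed(11)
  z <- rnorm(n, mu, sig)
  p <- plogis(z)
  yb <- rbinom(n, 1, plogis(-1 + 1.4 * z))
  ee <- eavg_emax(fit_loess_curve(p, yb, exact = FALSE), p)
  expect_lt(abs(ee[["eavg"]] - truth), 0.01)
  expect_lte(ee[["eavg"]], ee[["emax"]])
})

test_that("moderate calibration bundle is internally consistent", {
  d <- draw_scores(2000, a = -1, b = 1.3, seed = 51)
  mc <- moderate_calibration(d$p_hat, d$outcome)
  expect_lte(mc$eavg, mc$emax)
  expect_equal(mc$brier, brier_score(d$p_hat, d$outcome)$brier)
  expect_s3_class(mc$curve, "smoothed_curve")
  expect_true(all(mc$curve$fitted >= 0 & mc$curve$fitted <= 1))
})
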