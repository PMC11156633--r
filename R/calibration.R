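# Weak and moderate calibration metrics.
#
# Weak calibration summarizes miscalibration by the intercept and slope of a
# logistic regression of the outcome on the logit of the predicted
# probability (0 and 1 are ideal). Calibration-in-the-large (CITL) is the
# intercept of the same regression with the slope fixed at 1 (the logit
# prediction entered as an offset). Under the standard convention a negative
# intercept indicates overestimation of risk and a slope above 1 indicates
# an underfitted risk distribution.

# Damped Newton solver for the two-parameter logistic calibration fit:
# maximizes the Bernoulli likelihood of y on (1, x). Convergence is declared
# on the score (gradient), max|score| < tol.
logistic_score_fit <- function(x, y, tol = 1e-8, max_iter = 100L,
                               start = c(0, 1)) {
  a <- start[[1]]
  b <- start[[2]]
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1pexp(eta))
  }
  ll <- loglik(a, b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(a + b * x)
    g1 <- sum(y - p)
    g2 <- sum(x * (y - p))
    if (max(abs(g1), abs(g2)) < tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    h11 <- sum(w)
    h12 <- sum(w * x)
    h22 <- sum(w * x * x)
    det <- h11 * h22 - h12 * h12
    if (!is.finite(det) || det <= 0)
      stop("singular information matrix in calibration fit")
    da <- (h22 * g1 - h12 * g2) / det
    db <- (h11 * g2 - h12 * g1) / det
    step <- 1
    repeat {
      a2 <- a + step * da
      b2 <- b + step * db
      ll2 <- loglik(a2, b2)
      if (is.finite(ll2) && ll2 >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10)
        stop("calibration fit failed: step-halving could not improve the likelihood")
    }
    a <- a2
    b <- b2
    ll <- ll2
    if (max(abs(a), abs(b)) > 50)
      stop("calibration fit did not converge (|coefficient| > 50 suggests separation)")
  }
  if (!converged)
    stop("calibration fit did not converge within ", max_iter, " iterations")
  list(coef = c(a, b), loglik = ll, converged = TRUE, iter = it)
}

# One-parameter intercept fit with the logit prediction as an offset
# (calibration-in-the-large).
offset_intercept_fit <- function(x, y, tol = 1e-8, max_iter = 100L,
                                 start = 0) {
  a <- start
  loglik <- function(a) {
    eta <- a + x
    sum(y * eta - log1pexp(eta))
  }
  ll <- loglik(a)
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(a + x)
    g <- sum(y - p)
    if (abs(g) < tol) return(a)
    h <- sum(p * (1 - p))
    da <- g / h
    step <- 1
    repeat {
      a2 <- a + step * da
      ll2 <- loglik(a2)
      if (is.finite(ll2) && ll2 >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10)
        stop("offset calibration fit failed: step-halving could not improve the likelihood")
    }
    a <- a2
    ll <- ll2
    if (abs(a) > 50)
      stop("offset calibration fit did not converge (|intercept| > 50 suggests separation)")
  }
  stop("offset calibration fit did not converge within ", max_iter, " iterations")
}

#' Weak calibration: logistic calibration intercept and slope
#'
#' Fits the logistic calibration model `outcome ~ logit(p_hat)` by maximum
#' likelihood and reports the intercept and slope of the joint fit (both
#' free) together with calibration-in-the-large (`citl`): the intercept of
#' the fit with the slope fixed at 1, the logit prediction entering as an
#' offset. Both conventions are surfaced because "calibration intercept" is
#' used for either in the applied literature; the joint-fit intercept is the
#' default headline value here.
#'
#' @param p_hat Predicted probabilities in `(0, 1)` (clipped by `eps`).
#' @param outcome Binary 0/1 outcomes.
#' @param eps Clipping bound passed to [clipped_logit()].
#' @param min_n Minimum number of observations (default 20).
#' @param tol Convergence tolerance on the score; default `1e-8`.
#' @param max_iter Maximum Newton iterations.
#' @param compute_citl Also run the offset fit for
#'   calibration-in-the-large (default `TRUE`); set `FALSE` to skip it in
#'   tight resampling loops that only use the joint fit.
#' @return An object of class `weak_calibration`: list with `intercept`,
#'   `slope`, `citl` (`NA` when not computed), `n`, `converged`.
#' @seealso [fit_recalibration()] which reuses these fits.
#' @export
fit_weak_calibration <- function(p_hat, outcome, eps = 1e-6, min_n = 20L,
                                 tol = 1e-8, max_iter = 100L,
                                 compute_citl = TRUE) {
  check_prob_outcome(p_hat, outcome)
  n <- length(p_hat)
  if (n < min_n)
    stop(sprintf("need at least %d observations for a calibration fit, got %d",
                 min_n, n))
  if (length(unique(outcome)) < 2L)
    stop("degenerate outcome: only one class present")
  x <- clipped_logit(p_hat, eps)
  if (diff(range(x)) == 0)
    stop("constant predictions: calibration slope is unidentifiable")
  joint <- logistic_score_fit(x, outcome, tol = tol, max_iter = max_iter)
  citl <- if (compute_citl)
    offset_intercept_fit(x, outcome, tol = tol, max_iter = max_iter)
  else NA_real_
  structure(
    list(intercept = joint$coef[[1]], slope = joint$coef[[2]], citl = citl,
         n = n, converged = joint$converged),
    class = "weak_calibration")
}

# Fast unvalidated core used by the audit's bootstrap loop: x is the
# precomputed clipped logit, warm starts come from the full-cell fit.
weak_core <- function(x, y, start_joint = c(0, 1), start_citl = 0,
                      tol = 1e-8, max_iter = 100L) {
  joint <- logistic_score_fit(x, y, tol = tol, max_iter = max_iter,
                              start = start_joint)
  citl <- offset_intercept_fit(x, y, tol = tol, max_iter = max_iter,
                               start = start_citl)
  c(intercept = joint$coef[[1]], slope = joint$coef[[2]], citl = citl)
}

# Eavg/Emax without materializing the deduplicated curve: the loess fitted
# values at the observed predictions are exactly the curve evaluated there.
eavg_emax_fast <- function(p, y, span, degree) {
  fit <- stats::loess(
    y ~ x, data = data.frame(x = p, y = y), span = span, degree = degree,
    family = "gaussian",
    control = stats::loess.control(surface = "interpolate",
                                   statistics = "none"))
  d <- abs(pmin(pmax(fit$fitted, 0), 1) - p)
  c(eavg = mean(d), emax = max(d))
}

#' @export
print.weak_calibration <- function(x, ...) {
  cat("Weak calibration (n =", x$n, ")\n")
  cat(sprintf("  intercept (joint fit): %.4f\n", x$intercept))
  cat(sprintf("  slope     (joint fit): %.4f\n", x$slope))
  cat(sprintf("  CITL  (slope fixed 1): %.4f\n", x$citl))
  invisible(x)
}

#' Brier score and scaled Brier score
#'
#' The Brier score is the mean squared difference between predicted
#' probability and binary outcome. The scaled version normalizes by the
#' score of the constant outcome-prevalence predictor,
#' `1 - brier / (ybar * (1 - ybar))`, so that higher is better (1 is
#' perfect, 0 matches the non-informative predictor). The raw Brier score is
#' the primary reported value; the scaled score is emitted alongside and
#' clearly labeled because scaling conventions differ across reports.
#'
#' @inheritParams fit_weak_calibration
#' @return List with `brier`, `brier_scaled` (`NA` when the outcome
#'   prevalence is 0 or 1), `scaled_defined` flag and `n`.
#' @export
brier_score <- function(p_hat, outcome) {
  check_prob_outcome(p_hat, outcome)
  n <- length(p_hat)
  if (n < 1L) stop("need at least one observation")
  b <- mean((p_hat - outcome)^2)
  ybar <- mean(outcome)
  if (ybar <= 0 || ybar >= 1) {
    list(brier = b, brier_scaled = NA_real_, scaled_defined = FALSE, n = n)
  } else {
    list(brier = b, brier_scaled = 1 - b / (ybar * (1 - ybar)),
         scaled_defined = TRUE, n = n)
  }
}

#' Smoothed (loess) calibration curve
#'
#' Locally weighted polynomial regression of the outcome on the predicted
#' probability with tricube weights, evaluated at the deduplicated, sorted
#' observed predictions; fitted values are clipped to `[0, 1]`. When
#' moderate calibration holds, the curve falls along the diagonal. The
#' response may be continuous (useful for testing the smoother itself).
#'
#' For small samples (`exact = TRUE`, default for n <= 2000) the local
#' regression is computed exactly at every evaluation point; for larger
#' samples the standard interpolating surface is used, which is the usual
#' loess practice at scale and is accurate to a few parts in 1e4 here.
#'
#' @inheritParams fit_weak_calibration
#' @param span Smoothing fraction in `(0, 1]`; default 0.75.
#' @param degree Local polynomial degree, 0, 1 or 2; default 1.
#' @param exact Logical; compute the local regression exactly at every point
#'   (`surface = "direct"`). Default `NULL` chooses `TRUE` when n <= 2000.
#' @return Object of class `smoothed_curve`: list with `eval_points`,
#'   `fitted` (clipped to `[0, 1]`), `span`, `degree`, `exact`, `n`.
#' @export
fit_loess_curve <- function(p_hat, outcome, span = 0.75, degree = 1L,
                            exact = NULL) {
  if (length(p_hat) != length(outcome))
    stop("`p_hat` and `outcome` must have the same length")
  if (anyNA(p_hat) || anyNA(outcome)) stop("missing values are not allowed")
  n <- length(p_hat)
  if (n < 20L) stop("need at least 20 observations for a smoothed curve")
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("`span` must be in (0, 1]")
  if (!degree %in% 0:2) stop("`degree` must be 0, 1 or 2")
  ux <- sort(unique(p_hat))
  if (length(ux) < degree + 2)
    stop("need at least degree + 2 distinct prediction values")
  if (is.null(exact)) exact <- n <= 2000L
  ctrl <- if (exact) {
    stats::loess.control(surface = "direct")
  } else {
    stats::loess.control(surface = "interpolate", statistics = "none")
  }
  df <- data.frame(x = as.numeric(p_hat), y = as.numeric(outcome))
  fit <- stats::loess(y ~ x, data = df, span = span, degree = degree,
                      family = "gaussian", control = ctrl)
  fitted_u <- as.numeric(stats::predict(fit, newdata = data.frame(x = ux)))
  fitted_u <- pmin(pmax(fitted_u, 0), 1)
  structure(
    list(eval_points = ux, fitted = fitted_u, span = span,
         degree = as.integer(degree), exact = isTRUE(exact), n = n),
    class = "smoothed_curve")
}

#' Eavg (ICI) and Emax from a smoothed calibration curve
#'
#' Eavg, also called the integrated calibration index (ICI), is the mean
#' absolute difference between the smoothed observed-risk curve and the
#' ideal diagonal over the observed predictions; Emax is the maximum
#' absolute vertical deviation. Both are 0 for a perfectly calibrated
#' model.
#'
#' @param curve A [fit_loess_curve()] result evaluated at the observed
#'   predictions.
#' @param p_hat The observed predicted probabilities (every value must be an
#'   evaluation point of `curve`).
#' @return Named numeric vector `c(eavg = ..., emax = ...)`.
#' @export
eavg_emax <- function(curve, p_hat) {
  if (!inherits(curve, "smoothed_curve"))
    stop("`curve` must be a smoothed_curve from fit_loess_curve()")
  idx <- match(p_hat, curve$eval_points)
  if (anyNA(idx))
    stop("curve was not evaluated at all observed predictions")
  d <- abs(curve$fitted[idx] - p_hat)
  c(eavg = mean(d), emax = max(d))
}

#' Moderate calibration bundle
#'
#' Convenience wrapper computing the Brier score (raw and scaled) and the
#' loess-based Eavg/Emax in one call.
#'
#' @inheritParams fit_loess_curve
#' @param eps Clipping bound (unused by the smoother, kept for interface
#'   symmetry).
#' @return Object of class `moderate_calibration`: list with `brier`,
#'   `brier_scaled`, `eavg`, `emax`, `n` and the `curve`.
#' @export
moderate_calibration <- function(p_hat, outcome, span = 0.75, degree = 1L,
                                 exact = NULL, eps = 1e-6) {
  check_prob_outcome(p_hat, outcome)
  bs <- brier_score(p_hat, outcome)
  curve <- fit_loess_curve(p_hat, outcome, span = span, degree = degree,
                           exact = exact)
  ee <- eavg_emax(curve, p_hat)
  structure(
    list(brier = bs$brier, brier_scaled = bs$brier_scaled,
         eavg = unname(ee[["eavg"]]), emax = unname(ee[["emax"]]),
         n = bs$n, curve = curve),
    class = "moderate_calibration")
}

#' @export
print.moderate_calibration <- function(x, ...) {
  cat("Moderate calibration (n =", x$n, ")\n")
  cat(sprintf("  Brier: %.4f  scaled Brier: %.4f\n", x$brier, x$brier_scaled))
  cat(sprintf("  Eavg (ICI): %.4f  Emax: %.4f\n", x$eavg, x$emax))
  invisible(x)
}
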