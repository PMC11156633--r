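# Discrimination metrics: Harrell's c-index and confusion-matrix metrics at
# site-specific decision thresholds.

#' Harrell's concordance index
#'
#' Over all case-control pairs, the fraction in which the case received the
#' higher prediction, with ties in `p_hat` counted 0.5. Computed by the
#' midrank (Wilcoxon) identity in O(n log n); equals the brute-force
#' pairwise definition exactly.
#'
#' @inheritParams fit_weak_calibration
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(p_hat, outcome) {
  check_prob_outcome(p_hat, outcome)
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0L || n0 == 0L)
    stop("c-index undefined: only one outcome class present")
  r <- rank(p_hat, ties.method = "average")
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a decision threshold
#'
#' Dichotomizes predictions at a threshold (positive call when
#' `p_hat >= threshold`; ties are called positive) and reports the counts
#' and the standard derived metrics. `threshold` may be a single cutoff or a
#' per-record vector (each record judged at its own site's cutoff, as in
#' deployments with site-specific thresholds). A metric whose denominator is
#' 0 is returned as `NA` and named in `undefined` rather than reported as 0.
#'
#' @inheritParams fit_weak_calibration
#' @param threshold Probability cutoff(s) in `(0, 1)`; length 1 or
#'   `length(p_hat)`.
#' @param include_c_index Also compute [c_index()] (default `TRUE`; set
#'   `FALSE` when the outcome is single-class).
#' @return Object of class `discrimination_report`: counts `tp`, `fp`,
#'   `tn`, `fn`, metrics `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, optional `c_index`, the `threshold` used, `n`, and
#'   `undefined` (names of metrics with zero denominators).
#' @export
confusion_at_threshold <- function(p_hat, outcome, threshold,
                                   include_c_index = TRUE) {
  check_prob_outcome(p_hat, outcome)
  if (!is.numeric(threshold) ||
      !(length(threshold) %in% c(1L, length(p_hat))))
    stop("`threshold` must have length 1 or length(p_hat)")
  if (any(threshold <= 0) || any(threshold >= 1))
    stop("`threshold` must lie in (0, 1)")
  pos <- p_hat >= threshold
  tp <- sum(pos & outcome == 1)
  fp <- sum(pos & outcome == 0)
  fn <- sum(!pos & outcome == 1)
  tn <- sum(!pos & outcome == 0)
  n <- length(p_hat)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    threshold = if (length(threshold) == 1L) threshold else NA_real_,
    per_record_threshold = length(threshold) > 1L,
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn),
    accuracy = (tp + tn) / n,
    c_index = if (include_c_index && tp + fn > 0 && tn + fp > 0)
      c_index(p_hat, outcome) else NA_real_)
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv", "c_index")],
    function(v) is.na(v), logical(1))))
  structure(out, class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Discrimination report (n =", x$n, ")\n")
  cat(sprintf("  counts: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sens=%.3f spec=%.3f ppv=%.3f npv=%.3f acc=%.3f c=%.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy,
              x$c_index))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
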