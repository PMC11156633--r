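# Bootstrap resampling: percentile confidence intervals for arbitrary
# metrics and empirical two-sided p-values for subgroup metric differences,
# with Bonferroni control for multiplicity.

n_records <- function(records) {
  if (is.data.frame(records)) nrow(records) else length(records)
}

take_records <- function(records, idx) {
  if (is.data.frame(records)) {
    # column-wise subset: much faster than `[.data.frame` in resampling loops
    list2DF(lapply(records, function(col) col[idx]))
  } else {
    records[idx]
  }
}

# Apply a metric function (scalar- or named-vector-valued), returning NA(s)
# on error.
eval_metric <- function(fn, records, template = NULL) {
  out <- tryCatch(fn(records), error = function(e) NULL)
  if (is.null(out)) {
    if (is.null(template)) NA_real_ else
      stats::setNames(rep(NA_real_, length(template)), template)
  } else {
    as.numeric(out)
  }
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples the records with replacement (same size), applies `metric_fn`
#' to each resample and returns the percentile interval of the successful
#' resamples. Resamples on which the metric is undefined (the function
#' errors) are counted in `n_failed`; more than `max_fail` of them aborts
#' with an error.
#'
#' @param metric_fn Function mapping a record collection (data frame or
#'   vector) to a single numeric value.
#' @param records Record collection; data frames are resampled by row.
#' @param reps Number of bootstrap replicates; default 100.
#' @param seed Integer RNG seed (the caller's RNG state is preserved).
#' @param level Confidence level in `(0, 1)`; default 0.95.
#' @param max_fail Maximum tolerated fraction of failed resamples; default
#'   0.2.
#' @return Object of class `bootstrap_result`: `point`, `ci_lo`, `ci_hi`,
#'   `reps`, `seed`, `n_failed`, `level`. Percentile intervals need not
#'   contain the point estimate in pathological cases, but `ci_lo <= ci_hi`
#'   always holds.
#' @export
bootstrap_ci <- function(metric_fn, records, reps = 100L, seed = 1L,
                         level = 0.95, max_fail = 0.2) {
  if (!is.function(metric_fn)) stop("`metric_fn` must be a function")
  reps <- as.integer(reps)
  if (reps < 2L) stop("`reps` must be at least 2")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  n <- n_records(records)
  point <- tryCatch(as.numeric(metric_fn(records)),
                    error = function(e)
                      stop("metric undefined on the full sample: ",
                           conditionMessage(e), call. = FALSE))
  vals <- with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      eval_metric(metric_fn, take_records(records, idx))
    }, numeric(1))
  })
  ok <- vals[is.finite(vals)]
  n_failed <- reps - length(ok)
  if (n_failed > max_fail * reps)
    stop(sprintf("metric undefined on %d of %d resamples (> %.0f%% tolerated)",
                 n_failed, reps, 100 * max_fail))
  qs <- stats::quantile(ok, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(
    list(point = point, ci_lo = qs[[1]], ci_hi = qs[[2]], reps = reps,
         seed = as.integer(seed), n_failed = n_failed, level = level),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.4f (%.0f%% CI %.4f, %.4f; B = %d%s)\n", x$point,
              100 * x$level, x$ci_lo, x$ci_hi, x$reps,
              if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Empirical two-sided bootstrap p-value for a subgroup metric difference
#'
#' Resamples each group independently with replacement (subgroups are
#' disjoint patient sets, so resampling is unpaired), computes the metric
#' difference `D*_b = metric(g1*_b) - metric(g2*_b)` on every replicate and
#' returns the add-one-corrected empirical two-sided p-value
#' `p = min(1, 2 * min(m_le, m_ge))` with
#' `m_le = (1 + #\{D*_b <= 0\}) / (B + 1)` and likewise for `>=`. The
#' add-one correction keeps p-values in `[2/(B+1), 1]`, never exactly 0.
#'
#' `metric_fn` may also be a *named list* of metric functions, or a single
#' function returning a named vector; all metrics then share the same
#' resamples and a named list of `comparison_result`s is returned.
#'
#' @inheritParams bootstrap_ci
#' @param records_g1,records_g2 Record collections for the two groups.
#' @param metric Name(s) of the metric(s), used for labeling.
#' @param groups Character vector of two group labels.
#' @param alpha_adjusted Optional multiplicity-adjusted significance
#'   threshold; when supplied, `significant = p_raw < alpha_adjusted`.
#' @return A `comparison_result` (or named list of them): `metric`,
#'   `group1`, `group2`, `difference` (group1 - group2, full samples),
#'   `p_raw`, `alpha_adjusted`, `significant`, `reps`, `seed`, `n_failed`.
#' @export
bootstrap_diff_pvalue <- function(metric_fn, records_g1, records_g2,
                                  reps = 100L, seed = 1L,
                                  metric = NULL, groups = c("group1", "group2"),
                                  alpha_adjusted = NULL, max_fail = 0.2) {
  single_fn <- is.function(metric_fn)
  fns <- if (single_fn) list(metric_fn) else metric_fn
  if (!length(fns) || !all(vapply(fns, is.function, logical(1))))
    stop("`metric_fn` must be a function or a named list of functions")
  reps <- as.integer(reps)
  if (reps < 2L) stop("`reps` must be at least 2")
  n1 <- n_records(records_g1)
  n2 <- n_records(records_g2)

  eval_full <- function(f, records, lab) {
    v <- tryCatch(f(records), error = function(e)
      stop("metric undefined on the full ", lab, " sample: ",
           conditionMessage(e), call. = FALSE))
    if (!is.numeric(v)) stop("metric function must return numeric values")
    v
  }
  full1 <- lapply(fns, eval_full, records = records_g1, lab = "group-1")
  full2 <- lapply(fns, eval_full, records = records_g2, lab = "group-2")

  # metric names: explicit > list names > names of a vector-valued metric
  m_names <- metric
  if (is.null(m_names)) m_names <- names(fns)
  flat1 <- unlist(full1)
  if (is.null(m_names) && !is.null(names(flat1))) m_names <- names(flat1)
  k_per_fn <- vapply(full1, length, integer(1))
  k_total <- sum(k_per_fn)
  if (is.null(m_names) || length(m_names) != k_total)
    m_names <- paste0("metric", seq_len(k_total))

  D <- with_seed(as.integer(seed), {
    out <- matrix(NA_real_, nrow = reps, ncol = k_total)
    for (b in seq_len(reps)) {
      i1 <- sample.int(n1, n1, replace = TRUE)
      i2 <- sample.int(n2, n2, replace = TRUE)
      r1 <- take_records(records_g1, i1)
      r2 <- take_records(records_g2, i2)
      v1 <- unlist(lapply(seq_along(fns), function(j)
        eval_metric(fns[[j]], r1, template = rep("", k_per_fn[j]))))
      v2 <- unlist(lapply(seq_along(fns), function(j)
        eval_metric(fns[[j]], r2, template = rep("", k_per_fn[j]))))
      out[b, ] <- v1 - v2
    }
    out
  })

  diffs <- unlist(full1) - unlist(full2)
  results <- lapply(seq_len(k_total), function(j) {
    d <- D[, j]
    ok <- d[is.finite(d)]
    n_failed <- reps - length(ok)
    if (n_failed > max_fail * reps)
      stop(sprintf("metric '%s' undefined on %d of %d resample pairs",
                   m_names[j], n_failed, reps))
    B <- length(ok)
    m_le <- (1 + sum(ok <= 0)) / (B + 1)
    m_ge <- (1 + sum(ok >= 0)) / (B + 1)
    p_raw <- min(1, 2 * min(m_le, m_ge))
    structure(
      list(metric = m_names[j], group1 = groups[[1]], group2 = groups[[2]],
           difference = diffs[[j]], p_raw = p_raw,
           alpha_adjusted = alpha_adjusted %||% NA_real_,
           significant = if (is.null(alpha_adjusted)) NA else
             p_raw < alpha_adjusted,
           reps = reps, seed = as.integer(seed), n_failed = n_failed),
      class = "comparison_result")
  })
  names(results) <- m_names
  if (single_fn && k_total == 1L) results[[1]] else results
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s - %s = %.4f (p = %s; B = %d)\n", x$metric, x$group1,
              x$group2, x$difference, format_pvalue(x$p_raw, x$reps), x$reps))
  if (!is.na(x$alpha_adjusted))
    cat(sprintf("  significant at adjusted threshold %.4g: %s\n",
                x$alpha_adjusted, x$significant))
  invisible(x)
}

# The add-one correction floors p at 2/(B+1); values at the floor are
# displayed as "< 2/(B+1)" (some reports print these as 0).
format_pvalue <- function(p, reps) {
  floor_p <- 2 / (reps + 1)
  if (p <= floor_p) sprintf("< %.4g", floor_p) else sprintf("%.4g", p)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Familywise significance level in `(0, 1)`.
#' @param k Number of tests, at least 1.
#' @return `alpha / k`.
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single value in (0, 1)")
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be at least 1")
  alpha / k
}
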