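# Audit pipeline: recalibration variants x samples x subgroups, metric
# bundles with bootstrap CIs, pairwise subgroup comparisons, calibration
# curves and risk-percentile summaries.

audit_metric_names <- c("intercept", "slope", "citl", "brier",
                        "brier_scaled", "eavg", "emax", "c_index",
                        "sensitivity", "specificity", "ppv", "npv",
                        "accuracy")

#' Audit configuration
#'
#' @param subgroups Subgroup variables to audit (columns of the record
#'   table); variables absent from the data are dropped with a warning.
#' @param pairs List of two-level comparison pairs; each pair must match
#'   the levels of exactly one audited subgroup variable.
#' @param methods Recalibration variants to evaluate.
#' @param reps Bootstrap replicates for CIs and comparison p-values;
#'   default 100.
#' @param seed Master seed; per-cell child seeds are derived from it.
#' @param span,degree Loess settings for the calibration curves.
#' @param alpha Familywise significance level; the comparison threshold is
#'   `alpha / k` over the k tests performed unless `fixed_threshold` is
#'   given (e.g. 0.001).
#' @param fixed_threshold Optional externally supplied significance
#'   threshold overriding the Bonferroni computation.
#' @param comparison_metrics Metrics compared between pair groups.
#' @param comparison_samples Samples on which pairwise comparisons run.
#' @param min_cell Minimum subgroup cell size (default 50); smaller cells
#'   are skipped with a logged reason.
#' @param level Confidence level for bootstrap percentile CIs.
#' @param eps Probability clipping bound.
#' @param threshold Optional single decision threshold; default `NULL`
#'   uses each record's own site threshold (column `threshold`), falling
#'   back to 0.5.
#' @param curve_points Maximum number of evaluation points stored per
#'   exported curve.
#' @return Object of class `audit_config`.
#' @export
audit_config <- function(subgroups = c("gender", "race", "payor",
                                       "hospital_type"),
                         pairs = list(c("White", "Black"),
                                      c("Female", "Male")),
                         methods = c("none", "ritl", "logistic"),
                         reps = 100L, seed = 1L,
                         span = 0.75, degree = 1L,
                         alpha = 0.05, fixed_threshold = NULL,
                         comparison_metrics = c("intercept", "slope",
                                                "brier", "eavg", "emax"),
                         comparison_samples = c("train", "holdout"),
                         min_cell = 50L, level = 0.95, eps = 1e-6,
                         threshold = NULL, curve_points = 200L) {
  methods <- match.arg(methods, c("none", "ritl", "logistic"),
                       several.ok = TRUE)
  structure(
    list(subgroups = subgroups, pairs = pairs, methods = methods,
         reps = as.integer(reps), seed = as.integer(seed), span = span,
         degree = as.integer(degree), alpha = alpha,
         fixed_threshold = fixed_threshold,
         comparison_metrics = comparison_metrics,
         comparison_samples = comparison_samples,
         min_cell = as.integer(min_cell), level = level, eps = eps,
         threshold = threshold, curve_points = as.integer(curve_points)),
    class = "audit_config")
}

# All cell metrics as one named vector; failed components are NA. This is
# the audit's hot loop (called per bootstrap replicate), so inputs are
# assumed pre-validated, the clipped logit may be passed in, and the weak
# fit can be warm-started from the full-cell estimate.
cell_metric_vector <- function(p, y, thr, config, x = NULL,
                               start_joint = c(0, 1), start_citl = 0) {
  out <- stats::setNames(rep(NA_real_, length(audit_metric_names)),
                         audit_metric_names)
  n <- length(p)
  if (is.null(x)) x <- clipped_logit(p, config$eps)
  n1 <- sum(y == 1)
  n0 <- n - n1
  if (n1 > 0L && n0 > 0L && n >= 20L && diff(range(x)) > 0) {
    wc <- tryCatch(weak_core(x, y, start_joint = start_joint,
                             start_citl = start_citl),
                   error = function(e) NULL)
    if (!is.null(wc)) out[c("intercept", "slope", "citl")] <- wc
  }
  out[["brier"]] <- mean((p - y)^2)
  ybar <- n1 / n
  if (ybar > 0 && ybar < 1)
    out[["brier_scaled"]] <- 1 - out[["brier"]] / (ybar * (1 - ybar))
  ee <- tryCatch(eavg_emax_fast(p, y, config$span, config$degree),
                 error = function(e) NULL)
  if (!is.null(ee)) out[c("eavg", "emax")] <- ee
  pos <- p >= thr
  tp <- sum(pos & y == 1)
  fp <- sum(pos) - tp
  fn <- n1 - tp
  tn <- n0 - fp
  if (n1 > 0L) out[["sensitivity"]] <- tp / n1
  if (n0 > 0L) out[["specificity"]] <- tn / n0
  if (tp + fp > 0L) out[["ppv"]] <- tp / (tp + fp)
  if (tn + fn > 0L) out[["npv"]] <- tn / (tn + fn)
  out[["accuracy"]] <- (tp + tn) / n
  if (n1 > 0L && n0 > 0L) {
    r <- rank(p, ties.method = "average")
    out[["c_index"]] <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

# Locate the subgroup variable whose levels contain both members of a pair.
find_pair_variable <- function(records, subgroups, pair) {
  for (v in subgroups) {
    if (all(pair %in% unique(records[[v]]))) return(v)
  }
  stop("comparison pair (", paste(pair, collapse = ", "),
       ") does not match the levels of any audited subgroup variable")
}

#' Run the full calibration audit
#'
#' Fits recalibration-in-the-large and logistic recalibration on the
#' training sample only, applies every requested variant to both samples,
#' computes the weak/moderate calibration and discrimination bundle with
#' bootstrap percentile CIs for the overall cohort and every subgroup
#' level, runs the configured pairwise subgroup comparisons per metric and
#' variant, and collects smoothed calibration curves and risk-percentile
#' summaries. Deterministic given the seed: per-cell bootstrap seeds are
#' derived from the master seed and cell identity, so results do not depend
#' on evaluation order. Cells below the minimum size or with a single
#' outcome class are skipped with a logged reason; individual metric
#' failures mark the metric `NA` rather than aborting the audit.
#'
#' @param records Data frame of risk records with at least `p_hat`,
#'   `outcome` and `sample` (train/holdout) columns; subgroup columns and a
#'   per-record `threshold` column are used when present.
#' @param config An [audit_config()].
#' @return Object of class `audit_report` with data frames `metrics`,
#'   `comparisons`, `curves`, `percentiles`, `skipped`, the fitted
#'   `models`, `provenance` and the `config`.
#' @export
run_audit <- function(records, config = audit_config()) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  need <- c("p_hat", "outcome", "sample")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("`records` is missing column(s): ", paste(miss, collapse = ", "))
  check_prob_outcome(records$p_hat, records$outcome)
  train <- records[records$sample == "train", , drop = FALSE]
  if (!nrow(train)) stop("empty training sample")
  if (length(unique(train$outcome)) < 2L)
    stop("training sample must contain both outcome classes")

  sg <- intersect(config$subgroups, names(records))
  dropped_sg <- setdiff(config$subgroups, sg)
  if (length(dropped_sg))
    warning("subgroup variable(s) not in the records, dropped: ",
            paste(dropped_sg, collapse = ", "))

  all_models <- list(
    none = fit_recalibration("none", fit_sample = "train"),
    ritl = if ("ritl" %in% config$methods)
      fit_recalibration("ritl", train$p_hat, train$outcome,
                        eps = config$eps, fit_sample = "train"),
    logistic = if ("logistic" %in% config$methods)
      fit_recalibration("logistic", train$p_hat, train$outcome,
                        eps = config$eps, fit_sample = "train"))
  models <- Filter(Negate(is.null), all_models[config$methods])

  p_var <- lapply(models, function(m)
    apply_recalibration(m, records$p_hat, config$eps))
  thr <- if (!is.null(config$threshold)) {
    rep(config$threshold, nrow(records))
  } else if ("threshold" %in% names(records)) {
    records$threshold
  } else {
    rep(0.5, nrow(records))
  }

  samples <- intersect(c("train", "holdout"), unique(records$sample))
  cells <- list()
  for (s in samples) {
    in_s <- records$sample == s
    cells[[length(cells) + 1L]] <-
      list(sample = s, subgroup = "overall", level = "overall",
           idx = which(in_s))
    for (v in sg) {
      for (lv in sort(unique(records[[v]][in_s]))) {
        cells[[length(cells) + 1L]] <-
          list(sample = s, subgroup = v, level = as.character(lv),
               idx = which(in_s & records[[v]] == lv))
      }
    }
  }

  metrics_rows <- list()
  skipped_rows <- list()
  curve_rows <- list()
  pct_rows <- list()
  probs_pct <- seq(0, 1, by = 0.1)

  for (variant in names(models)) {
    p_all <- p_var[[variant]]
    for (cell in cells) {
      idx <- cell$idx
      n <- length(idx)
      reason <- NULL
      if (n < config$min_cell) {
        reason <- sprintf("below minimum cell size (%d < %d)", n,
                          config$min_cell)
      } else if (length(unique(records$outcome[idx])) < 2L) {
        reason <- "single outcome class"
      }
      if (!is.null(reason)) {
        skipped_rows[[length(skipped_rows) + 1L]] <- data.frame(
          variant = variant, sample = cell$sample, subgroup = cell$subgroup,
          level = cell$level, n = n, reason = reason,
          stringsAsFactors = FALSE)
        next
      }
      p <- p_all[idx]
      y <- records$outcome[idx]
      th <- thr[idx]
      x <- clipped_logit(p, config$eps)
      point <- cell_metric_vector(p, y, th, config, x = x)
      warm_joint <- if (all(is.finite(point[c("intercept", "slope")])))
        unname(point[c("intercept", "slope")]) else c(0, 1)
      warm_citl <- if (is.finite(point[["citl"]])) point[["citl"]] else 0

      cell_seed <- child_seed(config$seed, paste("cell", variant,
                                                 cell$sample, cell$subgroup,
                                                 cell$level, sep = "|"))
      boot <- with_seed(cell_seed, {
        m <- matrix(NA_real_, nrow = config$reps,
                    ncol = length(audit_metric_names))
        for (b in seq_len(config$reps)) {
          i <- sample.int(n, n, replace = TRUE)
          m[b, ] <- cell_metric_vector(p[i], y[i], th[i], config, x = x[i],
                                       start_joint = warm_joint,
                                       start_citl = warm_citl)
        }
        m
      })
      a2 <- (1 - config$level) / 2
      for (j in seq_along(audit_metric_names)) {
        v_ok <- boot[, j][is.finite(boot[, j])]
        ci <- if (length(v_ok) >= 2L)
          stats::quantile(v_ok, c(a2, 1 - a2), names = FALSE, type = 7)
        else c(NA_real_, NA_real_)
        metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
          variant = variant, sample = cell$sample, subgroup = cell$subgroup,
          level = cell$level, metric = audit_metric_names[j],
          estimate = unname(point[j]), ci_lo = ci[[1]], ci_hi = ci[[2]],
          n = n, boot_failed = config$reps - length(v_ok),
          stringsAsFactors = FALSE)
      }

      curve <- tryCatch(
        fit_loess_curve(p, y, span = config$span, degree = config$degree,
                        exact = FALSE),
        error = function(e) NULL)
      if (!is.null(curve)) {
        np <- length(curve$eval_points)
        keep <- if (np > config$curve_points)
          unique(round(seq(1, np, length.out = config$curve_points)))
        else seq_len(np)
        curve_rows[[length(curve_rows) + 1L]] <- data.frame(
          variant = variant, sample = cell$sample, subgroup = cell$subgroup,
          level = cell$level, eval_point = curve$eval_points[keep],
          fitted = curve$fitted[keep], stringsAsFactors = FALSE)
      }
      qs <- stats::quantile(p, probs_pct, names = FALSE, type = 7)
      pct_rows[[length(pct_rows) + 1L]] <- data.frame(
        variant = variant, sample = cell$sample, subgroup = cell$subgroup,
        level = cell$level, percentile = 100 * probs_pct, p_hat = qs,
        stringsAsFactors = FALSE)
    }
  }

  comp_samples <- intersect(config$comparison_samples, samples)
  k_tests <- length(models) * length(comp_samples) * length(config$pairs) *
    length(config$comparison_metrics)
  sig_threshold <- config$fixed_threshold %||%
    (if (k_tests > 0) bonferroni_threshold(config$alpha, k_tests) else NA)
  comp_rows <- list()
  for (variant in names(models)) {
    p_all <- p_var[[variant]]
    for (s in comp_samples) {
      for (pair in config$pairs) {
        res <- compare_groups(
          p_hat = p_all[records$sample == s],
          outcome = records$outcome[records$sample == s],
          group = {
            v <- find_pair_variable(records, sg, pair)
            records[[v]][records$sample == s]
          },
          pair = pair, metrics = config$comparison_metrics,
          reps = config$reps,
          seed = child_seed(config$seed,
                            paste("cmp", variant, s, pair[1], pair[2],
                                  sep = "|")),
          span = config$span, degree = config$degree,
          alpha_adjusted = sig_threshold, eps = config$eps)
        for (r in res) {
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            variant = variant, sample = s, group1 = r$group1,
            group2 = r$group2, metric = r$metric, difference = r$difference,
            p_raw = r$p_raw, alpha_adjusted = r$alpha_adjusted,
            significant = r$significant, reps = r$reps,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  bind <- function(rows, proto) if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else proto
  metrics_df <- bind(metrics_rows, data.frame(
    variant = character(), sample = character(), subgroup = character(),
    level = character(), metric = character(), estimate = numeric(),
    ci_lo = numeric(), ci_hi = numeric(), n = integer(),
    boot_failed = integer(), stringsAsFactors = FALSE))
  comp_df <- bind(comp_rows, data.frame(
    variant = character(), sample = character(), group1 = character(),
    group2 = character(), metric = character(), difference = numeric(),
    p_raw = numeric(), alpha_adjusted = numeric(), significant = logical(),
    reps = integer(), stringsAsFactors = FALSE))
  curves_df <- bind(curve_rows, data.frame(
    variant = character(), sample = character(), subgroup = character(),
    level = character(), eval_point = numeric(), fitted = numeric(),
    stringsAsFactors = FALSE))
  pct_df <- bind(pct_rows, data.frame(
    variant = character(), sample = character(), subgroup = character(),
    level = character(), percentile = numeric(), p_hat = numeric(),
    stringsAsFactors = FALSE))
  skipped_df <- bind(skipped_rows, data.frame(
    variant = character(), sample = character(), subgroup = character(),
    level = character(), n = integer(), reason = character(),
    stringsAsFactors = FALSE))

  structure(
    list(metrics = metrics_df, comparisons = comp_df, curves = curves_df,
         percentiles = pct_df, skipped = skipped_df, models = models,
         provenance = list(
           seed = config$seed, reps = config$reps,
           config_hash = config_hash(unclass(config)),
           package_version = as.character(utils::packageVersion("calaudit")),
           timestamp = NA_character_),
         config = config),
    class = "audit_report")
}

#' Compare a metric bundle between two subgroups
#'
#' Splits the records by group, bootstraps each group independently with
#' replacement (shared resamples across metrics) and returns one
#' [bootstrap_diff_pvalue()] comparison per metric.
#'
#' @param p_hat Predicted probabilities (already recalibrated if desired).
#' @param outcome Binary outcomes.
#' @param group Group label per record.
#' @param pair Character vector of two group levels (difference is
#'   `pair[1] - pair[2]`).
#' @param metrics Subset of `intercept`, `slope`, `citl`, `brier`, `eavg`,
#'   `emax`.
#' @param reps,seed Bootstrap replicates and seed.
#' @param span,degree Loess settings (used when `eavg`/`emax` are
#'   requested).
#' @param alpha_adjusted Multiplicity-adjusted significance threshold.
#' @param eps Clipping bound.
#' @return Named list of `comparison_result` objects, one per metric.
#' @export
compare_groups <- function(p_hat, outcome, group, pair,
                           metrics = c("intercept", "slope", "brier",
                                       "eavg", "emax"),
                           reps = 100L, seed = 1L, span = 0.75, degree = 1L,
                           alpha_adjusted = NULL, eps = 1e-6) {
  allowed <- c("intercept", "slope", "citl", "brier", "eavg", "emax")
  if (!all(metrics %in% allowed))
    stop("`metrics` must be a subset of: ", paste(allowed, collapse = ", "))
  if (length(pair) != 2L) stop("`pair` must name exactly two groups")
  missing_lv <- setdiff(pair, unique(group))
  if (length(missing_lv))
    stop("unknown group level(s): ", paste(missing_lv, collapse = ", "))
  d1 <- data.frame(p = p_hat[group == pair[1]],
                   y = outcome[group == pair[1]])
  d2 <- data.frame(p = p_hat[group == pair[2]],
                   y = outcome[group == pair[2]])
  need_weak <- any(c("intercept", "slope", "citl") %in% metrics)
  need_curve <- any(c("eavg", "emax") %in% metrics)
  fn <- function(d) {
    out <- stats::setNames(rep(NA_real_, length(allowed)), allowed)
    if (need_weak) {
      wc <- fit_weak_calibration(d$p, d$y, eps = eps)
      out[c("intercept", "slope", "citl")] <- c(wc$intercept, wc$slope,
                                                wc$citl)
    }
    if ("brier" %in% metrics) out[["brier"]] <- brier_score(d$p, d$y)$brier
    if (need_curve)
      out[c("eavg", "emax")] <- eavg_emax_fast(d$p, d$y, span, degree)
    out[metrics]
  }
  bootstrap_diff_pvalue(fn, d1, d2, reps = reps, seed = seed,
                        metric = metrics, groups = pair,
                        alpha_adjusted = alpha_adjusted)
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Calibration audit report\n")
  cat("  variants:", paste(names(x$models), collapse = ", "), "\n")
  cat("  metric rows:", nrow(x$metrics), " comparisons:",
      nrow(x$comparisons), " skipped cells:", nrow(x$skipped), "\n")
  cat("  seed:", x$provenance$seed, " bootstrap reps:",
      x$provenance$reps, "\n")
  ov <- x$metrics[x$metrics$subgroup == "overall" &
                    x$metrics$metric %in% c("intercept", "slope", "brier"), ]
  if (nrow(ov)) {
    cat("  overall weak calibration by variant/sample:\n")
    for (i in seq_len(nrow(ov)))
      cat(sprintf("    %-8s %-7s %-9s %8.4f (%.4f, %.4f)\n", ov$variant[i],
                  ov$sample[i], ov$metric[i], ov$estimate[i], ov$ci_lo[i],
                  ov$ci_hi[i]))
  }
  invisible(x)
}

#' Export audit artifacts
#'
#' Writes `metrics.csv`, `comparisons.csv` (header only when no comparisons
#' were configured), one curve CSV per (variant, sample, subgroup, level)
#' cell under `curves/`, and a single JSON bundle `audit.json` carrying the
#' metric and comparison tables, percentile summaries, models, provenance
#' and configuration at full numeric precision.
#'
#' @param report An [run_audit()] report.
#' @param destination Output directory (created if needed).
#' @param timestamp Optional timestamp string recorded in the JSON
#'   provenance.
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(report, destination, timestamp = NULL) {
  if (!inherits(report, "audit_report"))
    stop("`report` must be an audit_report")
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(destination))
    stop("cannot create destination directory: ", destination)
  curves_dir <- file.path(destination, "curves")
  dir.create(curves_dir, showWarnings = FALSE)

  paths <- c(metrics = file.path(destination, "metrics.csv"),
             comparisons = file.path(destination, "comparisons.csv"),
             audit = file.path(destination, "audit.json"))
  utils::write.csv(report$metrics, paths[["metrics"]], row.names = FALSE)
  utils::write.csv(report$comparisons, paths[["comparisons"]],
                   row.names = FALSE)

  cu <- report$curves
  if (nrow(cu)) {
    key <- unique(cu[, c("variant", "sample", "subgroup", "level")])
    for (i in seq_len(nrow(key))) {
      sel <- cu$variant == key$variant[i] & cu$sample == key$sample[i] &
        cu$subgroup == key$subgroup[i] & cu$level == key$level[i]
      fname <- paste(key$variant[i], key$sample[i], key$subgroup[i],
                     key$level[i], sep = "_")
      fname <- paste0(gsub("[^A-Za-z0-9._-]+", "_", fname), ".csv")
      utils::write.csv(cu[sel, c("eval_point", "fitted")],
                       file.path(curves_dir, fname), row.names = FALSE)
      paths <- c(paths, file.path(curves_dir, fname))
    }
  }

  prov <- report$provenance
  if (!is.null(timestamp)) prov$timestamp <- timestamp
  bundle <- list(
    schema_version = "1.0",
    provenance = prov,
    models = lapply(report$models, function(m)
      list(method = m$method, alpha = m$alpha, beta = m$beta,
           fit_n = m$fit_n, fit_sample = m$fit_sample)),
    config = unclass(report$config),
    metrics = report$metrics,
    comparisons = report$comparisons,
    percentiles = report$percentiles,
    skipped = report$skipped)
  # 17 significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(bundle, paths[["audit"]], auto_unbox = TRUE,
                       digits = I(17), na = "null", null = "null",
                       dataframe = "columns")
  invisible(paths)
}
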