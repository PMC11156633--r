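# Cohort assembly: reduce longitudinal prediction/assessment events to one
# analysis record per patient, split samples by admission date, and build
# the baseline-characteristics table with standardized mean differences.

#' Reduce longitudinal events to one analysis record per patient
#'
#' For each patient, selects the maximum predicted probability among
#' predictions that are followed by at least one assessment, and takes the
#' outcome from the first assessment dated on or after that prediction
#' (same-day assessments count as "after": the data are daily-granularity).
#' Patients with no assessment, or with no prediction preceding any
#' assessment, are excluded and counted. Duplicate (patient, date)
#' predictions are resolved by keeping the larger probability.
#'
#' @param predictions Data frame with columns `patient_id`, `date`,
#'   `p_hat`.
#' @param assessments Data frame with columns `patient_id`, `date`,
#'   `diagnosis` (0/1).
#' @param quiet Suppress the exclusion-count message.
#' @return Data frame with one row per retained patient: `patient_id`,
#'   `admit_date` (earliest prediction date), `p_hat`, `outcome`. Exclusion
#'   counts are attached as `attr(, "exclusions")`.
#' @export
reduce_admissions <- function(predictions, assessments, quiet = FALSE) {
  need_p <- c("patient_id", "date", "p_hat")
  need_a <- c("patient_id", "date", "diagnosis")
  if (!all(need_p %in% names(predictions)))
    stop("`predictions` must have columns: ", paste(need_p, collapse = ", "))
  if (!all(need_a %in% names(assessments)))
    stop("`assessments` must have columns: ", paste(need_a, collapse = ", "))
  if (!all(assessments$diagnosis %in% c(0, 1)))
    stop("`diagnosis` must be coded 0/1")

  psplit <- split(predictions, predictions$patient_id)
  asplit <- split(assessments, assessments$patient_id)
  excl <- c(no_assessment = 0L, no_prediction_before_assessment = 0L,
            assessment_without_prediction = 0L)
  n_dup <- 0L
  rows <- vector("list", length(psplit))
  keep <- logical(length(psplit))

  for (i in seq_along(psplit)) {
    pr <- psplit[[i]]
    pid <- pr$patient_id[[1]]
    as_ <- asplit[[as.character(pid)]]
    if (is.null(as_) || nrow(as_) == 0L) {
      excl[["no_assessment"]] <- excl[["no_assessment"]] + 1L
      next
    }
    # duplicate same-day predictions: keep the larger p_hat
    pr <- pr[order(pr$date, -pr$p_hat), , drop = FALSE]
    dup <- duplicated(pr$date)
    if (any(dup)) {
      n_dup <- n_dup + sum(dup)
      pr <- pr[!dup, , drop = FALSE]
    }
    as_ <- as_[order(as_$date), , drop = FALSE]
    eligible <- pr[pr$date <= max(as_$date), , drop = FALSE]
    if (nrow(eligible) == 0L) {
      excl[["no_prediction_before_assessment"]] <-
        excl[["no_prediction_before_assessment"]] + 1L
      next
    }
    sel <- eligible[which.max(eligible$p_hat), , drop = FALSE]
    first_after <- as_[as_$date >= sel$date, , drop = FALSE][1L, ]
    rows[[i]] <- data.frame(patient_id = pid, admit_date = min(pr$date),
                            p_hat = sel$p_hat,
                            outcome = as.integer(first_after$diagnosis),
                            stringsAsFactors = FALSE)
    keep[i] <- TRUE
  }
  excl[["assessment_without_prediction"]] <-
    length(setdiff(names(asplit), names(psplit)))

  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(patient_id = character(), admit_date = predictions$date[0],
               p_hat = numeric(), outcome = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  attr(out, "duplicate_predictions_dropped") <- n_dup
  if (!quiet)
    message(sprintf(
      "reduce_admissions: retained %d patients; excluded %d (no assessment), %d (no prediction before an assessment); %d duplicate same-day predictions dropped",
      nrow(out), excl[["no_assessment"]],
      excl[["no_prediction_before_assessment"]], n_dup))
  out
}

#' Split records into training and temporal hold-out samples
#'
#' Records admitted on or before `boundary_date` are labeled `"train"`,
#' later ones `"holdout"` (inclusive-left convention: the boundary date
#' itself belongs to the training sample).
#'
#' @param records Data frame with an `admit_date` column (`Date` or
#'   ISO-8601 strings).
#' @param boundary_date Last training date.
#' @param quiet Suppress the count message.
#' @return `records` with a `sample` column added.
#' @export
split_train_holdout <- function(records, boundary_date, quiet = FALSE) {
  if (!"admit_date" %in% names(records))
    stop("`records` must have an `admit_date` column")
  dates <- as.Date(records$admit_date)
  if (anyNA(dates)) {
    bad <- records$patient_id[is.na(dates)]
    stop("missing or unparseable admission dates for: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  boundary <- as.Date(boundary_date)
  records$sample <- ifelse(dates <= boundary, "train", "holdout")
  n_train <- sum(records$sample == "train")
  n_hold <- nrow(records) - n_train
  if (n_train == 0L || n_hold == 0L)
    warning("one of the samples is empty (train n = ", n_train,
            ", holdout n = ", n_hold, ")")
  if (!quiet)
    message(sprintf("split_train_holdout: train n = %d, holdout n = %d",
                    n_train, n_hold))
  records
}

#' Standardized mean difference for a binary variable
#'
#' `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)` with
#' `p_i = k_i / n_i`, the standard SMD used in baseline-characteristics
#' tables.
#'
#' @param k1,n1 Count and total in group 1.
#' @param k2,n2 Count and total in group 2.
#' @return Non-negative SMD; 0 when both variances are 0 and the
#'   proportions are equal; error when both variances are 0 and they
#'   differ.
#' @export
smd_binary <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("group totals must be at least 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("counts must satisfy 0 <= k <= n")
  p1 <- k1 / n1
  p2 <- k2 / n2
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v == 0) {
    if (p1 == p2) return(0)
    stop("degenerate proportions with zero variance but unequal values")
  }
  abs(p1 - p2) / sqrt(v)
}

# SMD for a continuous variable from group means and sds.
smd_continuous <- function(mean1, sd1, mean2, sd2) {
  v <- (sd1^2 + sd2^2) / 2
  if (v == 0) {
    if (mean1 == mean2) return(0)
    stop("degenerate continuous variable with zero variance but unequal means")
  }
  abs(mean1 - mean2) / sqrt(v)
}

#' Standardized mean difference for a multicategory variable
#'
#' Mahalanobis-distance generalization of the SMD: `sqrt(T' S^{-1} T)`
#' where `T` is the vector of proportion differences over k - 1 categories
#' and `S` is the average of the two groups' multinomial covariance
#' matrices. Invariant to category order and to which category is dropped.
#' Categories empty in both groups are dropped first (with a message); a
#' singular average covariance matrix is an error.
#'
#' @param counts_g1,counts_g2 Per-category counts (same category set, same
#'   order; names are matched when present).
#' @return Non-negative SMD.
#' @export
smd_multicategory <- function(counts_g1, counts_g2) {
  if (!is.null(names(counts_g1)) && !is.null(names(counts_g2))) {
    if (!setequal(names(counts_g1), names(counts_g2)))
      stop("the two groups must share the same category set")
    counts_g2 <- counts_g2[names(counts_g1)]
  }
  if (length(counts_g1) != length(counts_g2))
    stop("the two groups must have the same number of categories")
  if (length(counts_g1) < 2L) stop("need at least 2 categories")
  if (any(counts_g1 < 0) || any(counts_g2 < 0)) stop("counts must be non-negative")
  empty <- counts_g1 == 0 & counts_g2 == 0
  if (any(empty)) {
    message("dropping ", sum(empty), " categor",
            if (sum(empty) == 1) "y" else "ies", " empty in both groups")
    counts_g1 <- counts_g1[!empty]
    counts_g2 <- counts_g2[!empty]
    if (length(counts_g1) < 2L) stop("fewer than 2 non-empty categories")
  }
  n1 <- sum(counts_g1)
  n2 <- sum(counts_g2)
  if (n1 <= 0 || n2 <= 0) stop("group totals must be positive")
  p1 <- counts_g1 / n1
  p2 <- counts_g2 / n2
  k <- length(p1)
  T_ <- (p1 - p2)[-k]
  S_of <- function(p) diag(p[-k], k - 1) - tcrossprod(p[-k])
  S <- (S_of(p1) + S_of(p2)) / 2
  sol <- tryCatch(solve(S, T_), error = function(e)
    stop("singular covariance matrix in multicategory SMD", call. = FALSE))
  sqrt(drop(crossprod(T_, sol)))
}

#' Baseline-characteristics table with standardized mean differences
#'
#' Summarizes covariates by outcome group in the familiar "Table 1" shape:
#' continuous variables as median (IQR), categorical variables as n (%),
#' with an Overall column and one SMD per variable. Missing values get
#' their own row (count and percentage) and are excluded from the SMD.
#' Continuous SMDs use means and standard deviations even though medians
#' are displayed.
#'
#' @param records Data frame containing `outcome` (0/1) and the requested
#'   variables.
#' @param variables Named character vector mapping variable name to
#'   `"continuous"` or `"categorical"`. Default: every column except
#'   bookkeeping ones, numeric columns treated as continuous.
#' @param outcome Name of the outcome column.
#' @return Data frame of class `baseline_table` with columns `variable`,
#'   `level`, `group0`, `group1`, `overall`, `smd` (on the variable's first
#'   row), `kind`.
#' @export
summarize_baseline <- function(records, variables = NULL, outcome = "outcome") {
  if (!outcome %in% names(records)) stop("no `", outcome, "` column")
  y <- records[[outcome]]
  if (!all(y %in% c(0, 1))) stop("`", outcome, "` must be coded 0/1")
  if (is.null(variables)) {
    skip <- c(outcome, "patient_id", "p_hat", "sample", "threshold",
              "admit_date")
    vars <- setdiff(names(records), skip)
    variables <- vapply(vars, function(v)
      if (is.numeric(records[[v]])) "continuous" else "categorical",
      character(1))
  }
  if (is.list(variables)) variables <- unlist(variables)
  unknown <- setdiff(names(variables), names(records))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  if (!all(variables %in% c("continuous", "categorical")))
    stop("variable kinds must be 'continuous' or 'categorical'")

  g0 <- records[y == 0, , drop = FALSE]
  g1 <- records[y == 1, , drop = FALSE]
  fmt_n <- function(k, n) sprintf("%d (%.1f%%)", k, 100 * k / max(n, 1))
  rows <- list()

  for (v in names(variables)) {
    kind <- variables[[v]]
    x0 <- g0[[v]]
    x1 <- g1[[v]]
    xa <- records[[v]]
    if (kind == "continuous") {
      m0 <- x0[!is.na(x0)]
      m1 <- x1[!is.na(x1)]
      smd <- smd_continuous(mean(m0), stats::sd(m0), mean(m1), stats::sd(m1))
      fmt_med <- function(z) sprintf("%.1f (%.1f)", stats::median(z),
                                     stats::IQR(z))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "Median (IQR)",
        group0 = fmt_med(m0), group1 = fmt_med(m1),
        overall = fmt_med(xa[!is.na(xa)]), smd = smd, kind = kind,
        stringsAsFactors = FALSE)
      if (anyNA(xa))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = "Missing",
          group0 = fmt_n(sum(is.na(x0)), nrow(g0)),
          group1 = fmt_n(sum(is.na(x1)), nrow(g1)),
          overall = fmt_n(sum(is.na(xa)), nrow(records)),
          smd = NA_real_, kind = kind, stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(xa[!is.na(xa)]))
      c0 <- vapply(lev, function(l) sum(x0 == l, na.rm = TRUE), integer(1))
      c1 <- vapply(lev, function(l) sum(x1 == l, na.rm = TRUE), integer(1))
      smd <- if (length(lev) == 1L) 0 else if (length(lev) == 2L)
        smd_binary(c0[1], sum(c0), c1[1], sum(c1))
      else smd_multicategory(stats::setNames(c0, lev), stats::setNames(c1, lev))
      for (j in seq_along(lev)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = as.character(lev[j]),
          group0 = fmt_n(c0[j], nrow(g0)), group1 = fmt_n(c1[j], nrow(g1)),
          overall = fmt_n(c0[j] + c1[j], nrow(records)),
          smd = if (j == 1L) smd else NA_real_, kind = kind,
          stringsAsFactors = FALSE)
      }
      if (anyNA(xa))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = "Missing",
          group0 = fmt_n(sum(is.na(x0)), nrow(g0)),
          group1 = fmt_n(sum(is.na(x1)), nrow(g1)),
          overall = fmt_n(sum(is.na(xa)), nrow(records)),
          smd = NA_real_, kind = kind, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("baseline_table", class(out))
  out
}
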