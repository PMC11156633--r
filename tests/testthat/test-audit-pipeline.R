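# Small-scale end-to-end audits: n and bootstrap reps are kept modest so
# the structural properties (cell completeness, invariances, determinism,
# export round trips) can be checked quickly.

small_audit <- function(n = 4000, seed = 97, reps = 25L, ...) {
  rec <- generate_cohort(synth_config(n = n, seed = seed))
  cfg <- audit_config(subgroups = c("gender", "race"),
                      pairs = list(c("White", "Black"),
                                   c("Female", "Male")),
                      reps = reps, seed = seed, ...)
  list(rec = rec, cfg = cfg, report = run_audit(rec, cfg))
}

test_that("audit reports are complete: every cell present or skipped", {
  sa <- small_audit()
  rep_ <- sa$report
  n_levels <- length(unique(sa$rec$gender)) + length(unique(sa$rec$race))
  cells_per_sample <- 1 + n_levels
  expected_cells <- 3 * 2 * cells_per_sample  # variants x samples x cells
  n_metrics <- length(unique(rep_$metrics$metric))
  expect_identical(nrow(rep_$metrics) / n_metrics + nrow(rep_$skipped),
                   as.numeric(expected_cells))
  expect_identical(nrow(rep_$skipped), 0L)  # all cells above min size here
  # every metric row carries a bootstrap interval with ci_lo <= ci_hi
  ok <- is.finite(rep_$metrics$ci_lo) & is.finite(rep_$metrics$ci_hi)
  expect_true(all(rep_$metrics$ci_lo[ok] <= rep_$metrics$ci_hi[ok]))
})

test_that("undersized cells are skipped with a reason", {
  sa <- small_audit(min_cell = 900L)
  expect_gt(nrow(sa$report$skipped), 0)
  expect_true(all(grepl("minimum cell size", sa$report$skipped$reason)))
  # race levels with < 900 records per sample are the skipped ones
  expect_true("Asian" %in% sa$report$skipped$level)
})

test_that("c-index is identical across recalibration variants per cell", {
  m <- small_audit()$report$metrics
  ci <- m[m$metric == "c_index", ]
  key <- paste(ci$sample, ci$subgroup, ci$level)
  for (k in unique(key)) {
    v <- ci$estimate[key == k]
    expect_lt(diff(range(v)), 1e-12)
  }
})

test_that("training-sample fixed points hold inside the audit", {
  m <- small_audit()$report$metrics
  tr_log <- m[m$variant == "logistic" & m$sample == "train" &
                m$subgroup == "overall", ]
  expect_lt(abs(tr_log$estimate[tr_log$metric == "intercept"]), 1e-6)
  expect_lt(abs(tr_log$estimate[tr_log$metric == "slope"] - 1), 1e-6)
  tr_ritl <- m[m$variant == "ritl" & m$sample == "train" &
                 m$subgroup == "overall", ]
  expect_lt(abs(tr_ritl$estimate[tr_ritl$metric == "citl"]), 1e-6)
  # ritl leaves the joint-fit slope exactly where "none" had it
  s_none <- m[m$variant == "none" & m$sample == "train" &
                m$subgroup == "overall" & m$metric == "slope", "estimate"]
  s_ritl <- tr_ritl$estimate[tr_ritl$metric == "slope"]
  expect_equal(s_ritl, s_none, tolerance = 1e-8)
})

test_that("audits are deterministic given records, config and seed", {
  a <- small_audit(n = 2500, reps = 10L)
  b <- small_audit(n = 2500, reps = 10L)
  expect_identical(a$report, b$report)
})

test_that("subgroup comparisons flag the built-in gender miscalibration gap", {
  # default truths differ in intercept by 0.61 between Female and Male;
  # with n = 20,000 and B = 99 the intercept difference must be detected.
  # (At B = 99 the add-one p-value floor is 0.02, so a Bonferroni cut of
  # 0.05/60 is unreachable by construction; test at a fixed 0.05.)
  sa <- small_audit(n = 20000, seed = 99, reps = 99L,
                    fixed_threshold = 0.05)
  cmp <- sa$report$comparisons
  expect_true(all(c("variant", "sample", "group1", "group2", "metric",
                    "difference", "p_raw", "significant") %in% names(cmp)))
  fm <- cmp[cmp$group1 == "Female" & cmp$variant == "none" &
              cmp$sample == "train" & cmp$metric == "intercept", ]
  expect_lt(fm$difference, -0.3)   # female intercept more negative
  expect_true(fm$significant)
  # race groups share identical truth under gender mode: differences small
  wb <- cmp[cmp$group1 == "White" & cmp$variant == "none" &
              cmp$sample == "train" & cmp$metric == "intercept", ]
  expect_lt(abs(wb$difference), 0.15)
})

test_that("comparison pairs referencing unknown levels raise errors", {
  rec <- generate_cohort(synth_config(n = 1500, seed = 101))
  cfg <- audit_config(subgroups = c("gender", "race"),
                      pairs = list(c("White", "Martian")), reps = 5L,
                      seed = 1)
  expect_error(run_audit(rec, cfg), "does not match")
  expect_error(compare_groups(rec$p_hat, rec$outcome, rec$gender,
                              c("Female", "Martian"), reps = 5L),
               "unknown group level")
})

test_that("export writes all artifact types and round-trips exactly", {
  sa <- small_audit(n = 2500, reps = 10L)
  dest <- file.path(tempdir(), "audit-export-test")
  on.exit(unlink(dest, recursive = TRUE), add = TRUE)
  paths <- export_tables(sa$report, dest)
  expect_true(file.exists(file.path(dest, "metrics.csv")))
  expect_true(file.exists(file.path(dest, "comparisons.csv")))
  expect_true(file.exists(file.path(dest, "audit.json")))
  curve_files <- list.files(file.path(dest, "curves"), pattern = "\\.csv$")
  key <- unique(sa$report$curves[, c("variant", "sample", "subgroup",
                                     "level")])
  expect_identical(length(curve_files), nrow(key))
  # the gender pair panels exist for every variant (the 6-panel layout)
  for (v in c("none", "ritl", "logistic"))
    for (g in c("Female", "Male"))
      expect_true(any(grepl(paste(v, "holdout", "gender", g, sep = "_"),
                            curve_files)))
  # JSON bundle reproduces every point estimate exactly
  bundle <- jsonlite::fromJSON(file.path(dest, "audit.json"))
  expect_identical(bundle$metrics$estimate, sa$report$metrics$estimate)
  expect_identical(bundle$comparisons$p_raw, sa$report$comparisons$p_raw)
  expect_identical(bundle$schema_version, "1.0")
})

test_that("empty comparison config yields a header-only comparisons file", {
  rec <- generate_cohort(synth_config(n = 1500, seed = 103))
  cfg <- audit_config(subgroups = "gender", pairs = list(), reps = 5L,
                      seed = 1)
  rep_ <- run_audit(rec, cfg)
  expect_identical(nrow(rep_$comparisons), 0L)
  dest <- file.path(tempdir(), "audit-empty-cmp")
  on.exit(unlink(dest, recursive = TRUE), add = TRUE)
  export_tables(rep_, dest)
  lines <- readLines(file.path(dest, "comparisons.csv"))
  expect_identical(length(lines), 1L)  # header only
})

test_that("null cohorts rarely flag subgroup differences", {
  # identical truth in both genders: at fixed threshold 0.001 the audit
  # should (almost) never declare significance
  truth <- list(Female = list(a = -1.17, b = 1.37, mu = NULL, sigma = 1.5),
                Male = list(a = -1.17, b = 1.37, mu = NULL, sigma = 1.5))
  n_sig <- 0L
  n_tests <- 0L
  for (r in 1:10) {
    rec <- generate_cohort(synth_config(n = 4000, seed = 200 + r,
                                        group_truth = truth))
    cfg <- audit_config(subgroups = "gender",
                        pairs = list(c("Female", "Male")),
                        comparison_metrics = c("intercept", "slope"),
                        comparison_samples = "train",
                        methods = "none", reps = 99L, seed = 200 + r,
                        fixed_threshold = 0.001)
    cmp <- run_audit(rec, cfg)$comparisons
    n_sig <- n_sig + sum(cmp$significant)
    n_tests <- n_tests + nrow(cmp)
  }
  expect_identical(n_tests, 20L)
  expect_lte(n_sig / n_tests, 0.1)
})
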