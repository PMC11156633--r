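test_that("admission reduction picks max eligible prediction, first assessment after", {
  d0 <- as.Date("2023-01-01")
  preds <- data.frame(patient_id = "A",
                      date = d0 + c(1, 3, 5),
                      p_hat = c(0.3, 0.7, 0.5))
  assess <- data.frame(patient_id = "A", date = d0 + 4, diagnosis = 0)
  out <- reduce_admissions(preds, assess, quiet = TRUE)
  # d5 prediction has no following assessment; max among eligible is 0.7
  expect_identical(nrow(out), 1L)
  expect_identical(out$p_hat, 0.7)
  expect_identical(out$outcome, 0L)
  expect_identical(out$admit_date, d0 + 1)
})

test_that("exclusions are counted and retained + excluded covers all patients", {
  d0 <- as.Date("2023-01-01")
  preds <- data.frame(
    patient_id = c("A", "B", "B", "C"),
    date = d0 + c(1, 1, 2, 5),
    p_hat = c(0.4, 0.2, 0.6, 0.9))
  assess <- data.frame(
    patient_id = c("A", "C"),
    date = d0 + c(2, 3),   # C's assessment precedes C's only prediction
    diagnosis = c(1, 0))
  out <- reduce_admissions(preds, assess, quiet = TRUE)
  excl <- attr(out, "exclusions")
  expect_identical(out$patient_id, "A")
  expect_identical(out$outcome, 1L)
  expect_identical(excl[["no_assessment"]], 1L)  # B
  expect_identical(excl[["no_prediction_before_assessment"]], 1L)  # C
  expect_identical(nrow(out) + sum(excl[c("no_assessment",
                                          "no_prediction_before_assessment")]),
                   length(unique(preds$patient_id)))
})

test_that("same-day assessment counts as after; duplicate predictions keep the max", {
  d0 <- as.Date("2023-06-01")
  preds <- data.frame(patient_id = c("A", "A"), date = c(d0 + 2, d0 + 2),
                      p_hat = c(0.5, 0.8))
  assess <- data.frame(patient_id = "A", date = d0 + 2, diagnosis = 1)
  out <- reduce_admissions(preds, assess, quiet = TRUE)
  expect_identical(nrow(out), 1L)
  expect_identical(out$p_hat, 0.8)
  expect_identical(out$outcome, 1L)
  expect_identical(attr(out, "duplicate_predictions_dropped"), 1L)
})

test_that("temporal split is inclusive-left with errors for missing dates", {
  rec <- data.frame(patient_id = c("A", "B", "C"),
                    admit_date = as.Date(c("2022-06-01", "2022-12-31",
                                           "2023-01-01")),
                    p_hat = c(0.3, 0.4, 0.5), outcome = c(0L, 1L, 0L))
  out <- split_train_holdout(rec, "2022-12-31", quiet = TRUE)
  expect_identical(out$sample, c("train", "train", "holdout"))
  rec_bad <- rec
  rec_bad$admit_date[2] <- NA
  expect_error(split_train_holdout(rec_bad, "2022-12-31", quiet = TRUE), "B")
  expect_warning(split_train_holdout(rec, "2030-01-01", quiet = TRUE),
                 "empty")
})

test_that("binary SMD matches hand computations and baseline-table counts", {
  expect_identical(smd_binary(10, 100, 10, 100), 0)
  expect_equal(smd_binary(3, 4, 1, 4), 0.5 / sqrt(0.1875), tolerance = 1e-12)
  expect_equal(round(smd_binary(3, 4, 1, 4), 4), 1.1547)
  # gender counts of the reference baseline table reproduce its printed SMD
  expect_equal(round(smd_binary(19606, 37878, 5177, 11774), 2), 0.16)
  expect_error(smd_binary(0, 10, 10, 10), "zero variance")
  expect_error(smd_binary(11, 10, 1, 10), "counts")
})

test_that("multicategory SMD: identity, printed race counts, binary equivalence", {
  expect_equal(smd_multicategory(c(10, 20, 30), c(1, 2, 3)), 0,
               tolerance = 1e-12)
  race1 <- c(Asian = 2465, Black = 11182, Other = 10900, White = 13331)
  race2 <- c(Asian = 835, Black = 3534, Other = 3146, White = 4259)
  expect_equal(round(smd_multicategory(race1, race2), 2), 0.05)
  # two categories: collapses to the binary SMD exactly
  expect_equal(smd_multicategory(c(a = 30, b = 70), c(a = 55, b = 45)),
               smd_binary(30, 100, 55, 100), tolerance = 1e-12)
})

test_that("multicategory SMD is invariant to category order and drop choice", {
  g1 <- c(a = 11, b = 52, c = 37, d = 9)
  g2 <- c(a = 22, b = 41, c = 30, d = 16)
  ref <- smd_multicategory(g1, g2)
  for (r in 1:5) {
    set.seed(r)
    perm <- sample(names(g1))
    expect_equal(smd_multicategory(g1[perm], g2[perm]), ref,
                 tolerance = 1e-10)
  }
  # all-zero category must be dropped (message), then still computable
  expect_message(v <- smd_multicategory(c(g1, e = 0), c(g2, e = 0)),
                 "dropping")
  expect_equal(v, ref, tolerance = 1e-10)
  # degenerate opposite-corner distributions are singular
  expect_error(smd_multicategory(c(5, 0), c(0, 5)), "singular")
})

test_that("baseline table summarizes both kinds and flags missingness", {
  rec <- data.frame(
    outcome = c(0, 0, 0, 1, 1, 1),
    age = c(1, 2, 3, 3, 4, 5),
    sex = c("F", "M", "F", "M", "M", NA))
  tab <- summarize_baseline(rec, c(age = "continuous", sex = "categorical"))
  expect_s3_class(tab, "baseline_table")
  # continuous SMD by hand: means 2 vs 4, sds 1 and 1 -> 2
  expect_equal(tab$smd[tab$variable == "age" & tab$level == "Median (IQR)"],
               2, tolerance = 1e-12)
  expect_true("Missing" %in% tab$level[tab$variable == "sex"])
  expect_error(summarize_baseline(rec, c(bmi = "continuous")), "unknown")
  # identical outcome groups: every SMD is 0
  rec2 <- data.frame(outcome = rep(c(0, 1), each = 4),
                     x = rep(c(1, 2, 3, 4), 2),
                     g = rep(c("a", "a", "b", "b"), 2))
  tab2 <- summarize_baseline(rec2, c(x = "continuous", g = "categorical"))
  expect_true(all(tab2$smd[!is.na(tab2$smd)] == 0))
})

test_that("default synthetic cohort reproduces its configured composition", {
  rec <- generate_cohort(synth_config(n = 20000, seed = 47))
  tab <- summarize_baseline(rec, c(gender = "categorical"))
  pct_female <- 100 * sum(rec$gender == "Female") / nrow(rec)
  expect_lt(abs(pct_female - 49.9), 1)
  expect_identical(tab$variable[1], "gender")
})
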