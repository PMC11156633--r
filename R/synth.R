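# Synthetic cohort generation with known, subgroup-specific logit-scale
# miscalibration.
#
# Each record belongs to a group g with truth (a_g, b_g, mu_g, sigma_g). A
# latent score z ~ Normal(mu_g, sigma_g) gives the deployed model's
# prediction p_hat = expit(z), while the true event probability is
# expit(a_g + b_g * z); the outcome is Bernoulli at that probability. A
# logistic calibration fit of outcome on logit(p_hat) within group g
# therefore has population intercept a_g and slope b_g, which is the ground
# truth every downstream stage is validated against.

#' Default generator building blocks
#'
#' `default_attributes()` gives the marginal attribute composition of a
#' large diverse multi-hospital inpatient cohort (about 49.9% female,
#' 29.6% Black, 35.4% White, five facilities). `default_group_truth()`
#' gives the per-gender miscalibration truth (female risk overestimated
#' more strongly than male); `default_effects()` the equivalent composite
#' deviations; `default_hospital_type_map()` the deterministic facility to
#' hospital-type mapping. All are starting points for customizing
#' [synth_config()].
#'
#' @return A list (or named vector for the map) in the shape
#'   [synth_config()] expects.
#' @export
default_attributes <- function() {
  list(
    gender = list(levels = c("Female", "Male"),
                  probs = c(24783, 24869) / 49652),
    race = list(levels = c("Asian", "Black", "Other", "White"),
                probs = c(3300, 14716, 14046, 17590) / 49652),
    ethnicity = list(levels = c("Hispanic", "Not Hispanic/Latino"),
                     probs = c(11973, 37679) / 49652),
    payor = list(levels = c("Commercial", "Medicaid", "Medicare", "Other",
                            "Uninsured"),
                 probs = c(8383, 13816, 27201, 31, 221) / 49652),
    service_line = list(levels = c("Med", "Surg"),
                        probs = c(33017, 16635) / 49652),
    facility = list(levels = paste("Facility", 1:5),
                    probs = c(5163, 7265, 20166, 9248, 7768) / 49610)
  )
}

#' @rdname default_attributes
#' @export
default_hospital_type_map <- function() {
  stats::setNames(
    c("Community Hospital", "Community Hospital",
      "Quaternary Academic Hospital", "Tertiary Acute Care",
      "Tertiary Acute Care"),
    paste("Facility", 1:5))
}

#' @rdname default_attributes
#' @param sigma Latent-score standard deviation shared by the groups.
#' @export
default_group_truth <- function(sigma = 1.5) {
  list(Female = list(a = -1.49, b = 1.42, mu = NULL, sigma = sigma),
       Male = list(a = -0.88, b = 1.40, mu = NULL, sigma = sigma))
}

#' @rdname default_attributes
#' @export
default_effects <- function() {
  list(
    gender = list(Female = list(da = -0.32, rb = 1.42 / 1.37),
                  Male = list(da = 0.29, rb = 1.40 / 1.37)),
    race = list(Black = list(da = 0.10, rb = 1.43 / 1.37),
                White = list(da = 0.00, rb = 1.29 / 1.37))
  )
}

#' Synthetic cohort configuration
#'
#' Assembles and validates the generator's ground truth: cohort size,
#' categorical attribute composition, per-group logit-scale miscalibration
#' `(a, b)` with latent-score distribution `Normal(mu, sigma)`, per-facility
#' decision thresholds, the train/holdout split fraction and the RNG seed.
#' When a group's `mu` is `NULL` it is solved at generation time so that
#' the group's event rate equals `target_prevalence` (see
#' [solve_mu_for_prevalence()]).
#'
#' Two modes: `"single_attribute"` ties the miscalibration truth to the
#' levels of one attribute (`group_by`), making within-group parameter
#' recovery exact in expectation; `"composite"` composes miscalibration
#' additively on intercepts and multiplicatively on slopes across the
#' attributes listed in `effects` (an approximation -- per-attribute values
#' cannot be jointly exact, so exact recovery tests use single-attribute
#' mode).
#'
#' @param n Number of admissions (>= 1).
#' @param seed Integer master seed; child streams per attribute/group are
#'   derived deterministically from it.
#' @param attributes Named list of attribute specs, each
#'   `list(levels =, probs =)` with probabilities summing to 1.
#' @param mode `"single_attribute"` or `"composite"`.
#' @param group_by Attribute carrying the miscalibration groups
#'   (single-attribute mode).
#' @param group_truth Named list (one entry per `group_by` level) of
#'   `list(a =, b =, mu =, sigma =)`.
#' @param base_truth Composite mode: base `list(a =, b =, mu =, sigma =)`.
#' @param effects Composite mode: per attribute level
#'   `list(da =, rb =)` deviations.
#' @param target_prevalence Event rate used to solve any `NULL` `mu`;
#'   default 0.24.
#' @param facility_thresholds Named vector of per-facility decision
#'   thresholds in `(0, 1)`; defaults spread over 0.44-0.58.
#' @param train_frac Fraction of admissions assigned to the training
#'   sample (the rest are the temporal hold-out); default 0.742.
#' @param hospital_type_map Named map facility -> hospital type.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n = 50000L,
                         seed = 1L,
                         attributes = default_attributes(),
                         mode = c("single_attribute", "composite"),
                         group_by = "gender",
                         group_truth = default_group_truth(),
                         base_truth = list(a = -1.17, b = 1.37, mu = NULL,
                                           sigma = 1.5),
                         effects = default_effects(),
                         target_prevalence = 0.24,
                         facility_thresholds = NULL,
                         train_frac = 0.742,
                         hospital_type_map = default_hospital_type_map()) {
  mode <- match.arg(mode)
  if (is.null(facility_thresholds) && "facility" %in% names(attributes))
    facility_thresholds <- stats::setNames(
      seq(0.44, 0.58, length.out = length(attributes$facility$levels)),
      attributes$facility$levels)
  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed), attributes = attributes,
         mode = mode, group_by = group_by, group_truth = group_truth,
         base_truth = base_truth, effects = effects,
         target_prevalence = target_prevalence,
         facility_thresholds = facility_thresholds,
         train_frac = train_frac, hospital_type_map = hospital_type_map),
    class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(config) {
  if (!inherits(config, "synth_config")) stop("not a synth_config")
  if (is.na(config$n) || config$n < 1L) stop("`n` must be at least 1")
  for (nm in names(config$attributes)) {
    at <- config$attributes[[nm]]
    if (length(at$levels) != length(at$probs))
      stop("attribute '", nm, "': levels and probs differ in length")
    if (any(at$probs < 0) || abs(sum(at$probs) - 1) > 1e-9)
      stop("attribute '", nm, "': probabilities must be non-negative and sum to 1 (within 1e-9)")
  }
  truths <- if (config$mode == "single_attribute") {
    if (!config$group_by %in% names(config$attributes))
      stop("`group_by` attribute '", config$group_by, "' not declared")
    lv <- config$attributes[[config$group_by]]$levels
    missing_t <- setdiff(lv, names(config$group_truth))
    if (length(missing_t))
      stop("no miscalibration truth for group(s): ",
           paste(missing_t, collapse = ", "))
    config$group_truth[lv]
  } else {
    list(base = config$base_truth)
  }
  for (g in names(truths)) {
    tr <- truths[[g]]
    if (!is.finite(tr$a) || !is.finite(tr$b))
      stop("non-finite (a, b) for group '", g, "'")
    if (!is.numeric(tr$sigma) || tr$sigma <= 0)
      stop("sigma must be > 0 for group '", g, "'")
    if (!is.null(tr$mu) && !is.finite(tr$mu))
      stop("non-finite mu for group '", g, "'")
  }
  if (!is.null(config$facility_thresholds) &&
      (any(config$facility_thresholds <= 0) ||
       any(config$facility_thresholds >= 1)))
    stop("facility thresholds must lie in (0, 1)")
  if (config$train_frac < 0 || config$train_frac > 1)
    stop("`train_frac` must lie in [0, 1]")
  invisible(config)
}

#' Solve the latent-score mean for a target event rate
#'
#' Finds `mu` such that `E[expit(a + b Z)]` with `Z ~ Normal(mu, sigma)`
#' equals `target_prevalence`, by one-dimensional root finding on the
#' numerically integrated expectation.
#'
#' @param a,b Logit-scale miscalibration intercept and slope.
#' @param sigma Latent-score standard deviation (> 0).
#' @param target_prevalence Desired event rate in `(0, 1)`.
#' @param tol Tolerance on the achieved prevalence; default `1e-6`.
#' @return The solved `mu`.
#' @export
solve_mu_for_prevalence <- function(a, b, sigma, target_prevalence,
                                    tol = 1e-6) {
  if (!is.finite(a) || !is.finite(b)) stop("`a` and `b` must be finite")
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("`target_prevalence` must lie in (0, 1)")
  # substitute z = mu + sigma * t so the integrand keeps its mass near 0
  # regardless of mu
  prev <- function(mu) {
    stats::integrate(function(t)
      stats::plogis(a + b * (mu + sigma * t)) * stats::dnorm(t),
      -12, 12, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  lo <- -50
  hi <- 50
  f_lo <- prev(lo) - target_prevalence
  f_hi <- prev(hi) - target_prevalence
  tries <- 0L
  while (f_lo * f_hi > 0 && tries < 4L) {
    lo <- lo * 2
    hi <- hi * 2
    f_lo <- prev(lo) - target_prevalence
    f_hi <- prev(hi) - target_prevalence
    tries <- tries + 1L
  }
  if (f_lo * f_hi > 0)
    stop("no bracketing interval: target prevalence ",
         target_prevalence, " is unreachable for (a, b, sigma) = (",
         a, ", ", b, ", ", sigma, ")")
  root <- stats::uniroot(function(mu) prev(mu) - target_prevalence,
                         lower = lo, upper = hi, tol = 1e-9)$root
  if (abs(prev(root) - target_prevalence) > tol)
    stop("root finding did not reach the requested tolerance")
  root
}

# Resolve any NULL mu in the truth entries against the target prevalence.
resolve_truths <- function(config) {
  solve1 <- function(tr) {
    if (is.null(tr$mu))
      tr$mu <- solve_mu_for_prevalence(tr$a, tr$b, tr$sigma,
                                       config$target_prevalence)
    tr
  }
  if (config$mode == "single_attribute") {
    config$group_truth <- lapply(config$group_truth, solve1)
  } else {
    config$base_truth <- solve1(config$base_truth)
  }
  config
}

#' Generate a synthetic risk-record cohort
#'
#' Draws attributes, latent scores, predictions and outcomes per the
#' configured ground truth (see [synth_config()]). Deterministic: the same
#' configuration (including seed) yields an identical record table; each
#' attribute and each random stage uses its own child seed derived from the
#' master seed, so streams do not depend on one another.
#'
#' @param config A [synth_config()].
#' @return Data frame of risk records: `patient_id`, `sample`
#'   (train/holdout), `p_hat`, `outcome`, the attribute columns, derived
#'   `hospital_type` and `year`, `admit_date` and the per-facility
#'   `threshold`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  config <- resolve_truths(config)
  n <- config$n

  draws <- list()
  for (nm in names(config$attributes)) {
    at <- config$attributes[[nm]]
    draws[[nm]] <- with_seed(
      child_seed(config$seed, paste0("attr:", nm)),
      at$levels[sample.int(length(at$levels), n, replace = TRUE,
                           prob = at$probs)])
  }

  sample_lab <- with_seed(child_seed(config$seed, "sample"),
                          ifelse(stats::runif(n) < config$train_frac,
                                 "train", "holdout"))
  admit_date <- with_seed(child_seed(config$seed, "dates"), {
    u <- stats::runif(n)
    as.Date(ifelse(sample_lab == "train",
                   as.Date("2021-01-01") + floor(u * 730),
                   as.Date("2023-01-01") + floor(u * 273)),
            origin = "1970-01-01")
  })

  if (config$mode == "single_attribute") {
    g <- draws[[config$group_by]]
    truth <- config$group_truth
    empty <- setdiff(names(truth), unique(g))
    if (length(empty))
      stop("empty group(s) in the generated cohort: ",
           paste(empty, collapse = ", "))
    a_vec <- vapply(truth, `[[`, numeric(1), "a")[g]
    b_vec <- vapply(truth, `[[`, numeric(1), "b")[g]
    mu_vec <- vapply(truth, `[[`, numeric(1), "mu")[g]
    sd_vec <- vapply(truth, `[[`, numeric(1), "sigma")[g]
  } else {
    bt <- config$base_truth
    a_vec <- rep(bt$a, n)
    b_vec <- rep(bt$b, n)
    mu_vec <- rep(bt$mu, n)
    sd_vec <- rep(bt$sigma, n)
    for (nm in names(config$effects)) {
      if (!nm %in% names(draws))
        stop("composite effect references undeclared attribute '", nm, "'")
      eff <- config$effects[[nm]]
      for (lv in names(eff)) {
        hit <- draws[[nm]] == lv
        a_vec[hit] <- a_vec[hit] + eff[[lv]]$da
        b_vec[hit] <- b_vec[hit] * eff[[lv]]$rb
      }
    }
  }

  z <- with_seed(child_seed(config$seed, "score"),
                 stats::rnorm(n, mu_vec, sd_vec))
  p_hat <- pmin(pmax(stats::plogis(z), 1e-12), 1 - 1e-12)
  p_true <- stats::plogis(a_vec + b_vec * z)
  outcome <- with_seed(child_seed(config$seed, "outcome"),
                       stats::rbinom(n, 1L, p_true))

  out <- data.frame(patient_id = sprintf("P%07d", seq_len(n)),
                    sample = sample_lab, p_hat = p_hat, outcome = outcome,
                    stringsAsFactors = FALSE)
  for (nm in names(draws)) out[[nm]] <- draws[[nm]]
  if ("facility" %in% names(draws)) {
    if (!is.null(config$hospital_type_map))
      out$hospital_type <- unname(config$hospital_type_map[draws$facility])
    if (!is.null(config$facility_thresholds))
      out$threshold <- unname(config$facility_thresholds[draws$facility])
  }
  out$year <- format(admit_date, "%Y")
  out$admit_date <- admit_date
  out
}

#' Generate longitudinal prediction and assessment events
#'
#' Emulates the deployed screening workflow at daily granularity: while a
#' patient is admitted, a prediction is issued each day unless suppressed;
#' on a prediction day the dietitian may assess the patient; a positive
#' assessment suppresses further predictions permanently, a negative one
#' suppresses them for three days. Intended to exercise
#' [reduce_admissions()].
#'
#' @param config A [synth_config()] (only `n`, `seed` and the truth are
#'   used).
#' @param assess_prob Daily probability that a prediction day is followed by
#'   a same-day assessment; default 0.35.
#' @param mean_los Mean additional length of stay in days beyond 3;
#'   default 6.
#' @return List with data frames `predictions` (`patient_id`, `date`,
#'   `p_hat`) and `assessments` (`patient_id`, `date`, `diagnosis`).
#' @export
generate_longitudinal <- function(config, assess_prob = 0.35, mean_los = 6) {
  validate_synth_config(config)
  config <- resolve_truths(config)
  n <- config$n
  tr0 <- if (config$mode == "single_attribute")
    config$group_truth[[1]] else config$base_truth

  with_seed(child_seed(config$seed, "longitudinal"), {
    preds <- list()
    assess <- list()
    admit <- as.Date("2021-01-01") + sample.int(900, n, replace = TRUE) - 1L
    for (i in seq_len(n)) {
      pid <- sprintf("P%07d", i)
      z <- stats::rnorm(1, tr0$mu, tr0$sigma)
      p_true <- stats::plogis(tr0$a + tr0$b * z)
      los <- 3L + stats::rpois(1, mean_los)
      suppressed_until <- -1L
      day <- 0L
      while (day <= los) {
        if (day > suppressed_until) {
          p_day <- min(max(stats::plogis(z + stats::rnorm(1, 0, 0.25)),
                           1e-12), 1 - 1e-12)
          preds[[length(preds) + 1L]] <- data.frame(
            patient_id = pid, date = admit[i] + day, p_hat = p_day,
            stringsAsFactors = FALSE)
          if (stats::runif(1) < assess_prob) {
            dx <- stats::rbinom(1, 1L, p_true)
            assess[[length(assess) + 1L]] <- data.frame(
              patient_id = pid, date = admit[i] + day,
              diagnosis = as.integer(dx), stringsAsFactors = FALSE)
            if (dx == 1L) break           # permanent suppression
            suppressed_until <- day + 3L  # suppressed for three days
          }
        }
        day <- day + 1L
      }
    }
    list(predictions = do.call(rbind, preds),
         assessments = if (length(assess)) do.call(rbind, assess) else
           data.frame(patient_id = character(), date = admit[0],
                      diagnosis = integer(), stringsAsFactors = FALSE))
  })
}
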