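# Recalibration on the logit scale: recalibration-in-the-large (intercept
# update only, slope fixed at 1) and logistic recalibration (intercept and
# slope freely estimated), applied as
# p' = expit(alpha + beta * logit(p)).

#' Fit a recalibration model
#'
#' Recalibration-in-the-large (`"ritl"`) keeps the slope at 1 and estimates
#' only the intercept (the calibration-in-the-large from the offset fit);
#' logistic recalibration (`"logistic"`) estimates intercept and slope
#' freely (the joint logistic calibration fit); `"none"` is the identity.
#' Recalibration is conventionally fitted on a training sample and applied
#' to both samples.
#'
#' @param method One of `"none"`, `"ritl"`, `"logistic"`.
#' @inheritParams fit_weak_calibration
#' @param fit_sample Optional label recording which sample the model was
#'   fitted on.
#' @return Object of class `recal_model`: list with `method`, `alpha`,
#'   `beta`, `fit_n`, `fit_sample`.
#' @export
fit_recalibration <- function(method = c("none", "ritl", "logistic"),
                              p_hat, outcome, eps = 1e-6,
                              fit_sample = NA_character_) {
  method <- match.arg(method)
  if (method == "none") {
    n <- if (missing(p_hat)) 0L else length(p_hat)
    return(structure(list(method = "none", alpha = 0, beta = 1,
                          fit_n = n, fit_sample = fit_sample),
                     class = "recal_model"))
  }
  wc <- fit_weak_calibration(p_hat, outcome, eps = eps)
  if (method == "ritl") {
    structure(list(method = "ritl", alpha = wc$citl, beta = 1,
                   fit_n = wc$n, fit_sample = fit_sample),
              class = "recal_model")
  } else {
    structure(list(method = "logistic", alpha = wc$intercept, beta = wc$slope,
                   fit_n = wc$n, fit_sample = fit_sample),
              class = "recal_model")
  }
}

#' Apply a recalibration model to predicted probabilities
#'
#' Returns `expit(alpha + beta * clipped_logit(p_hat))`. For
#' `method = "none"` the input is returned unchanged. The transform is
#' order-preserving whenever `beta > 0`, so rank-based discrimination
#' metrics are invariant under it; a non-positive `beta` triggers a warning
#' (rank reversal or collapse) but is still applied.
#'
#' @param model A [fit_recalibration()] result.
#' @param p_hat Predicted probabilities.
#' @param eps Clipping bound for the logit.
#' @return Recalibrated probabilities, strictly inside `(0, 1)`.
#' @export
apply_recalibration <- function(model, p_hat, eps = 1e-6) {
  if (!inherits(model, "recal_model"))
    stop("`model` must be a recal_model from fit_recalibration()")
  if (model$method == "none") return(p_hat)
  if (model$beta <= 0)
    warning("recalibration slope beta <= 0: ranking is reversed or collapsed")
  stats::plogis(model$alpha + model$beta * clipped_logit(p_hat, eps))
}

#' @export
print.recal_model <- function(x, ...) {
  cat(sprintf("Recalibration model: %s\n", x$method))
  cat(sprintf("  alpha = %.6f, beta = %.6f (fit n = %d%s)\n",
              x$alpha, x$beta, x$fit_n,
              if (is.na(x$fit_sample)) "" else paste0(", sample = ", x$fit_sample)))
  invisible(x)
}
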