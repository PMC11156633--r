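# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clipped logit transform
#'
#' Numerically guarded logit used by every calibration fit in the package.
#' Probabilities are clipped into `[eps, 1 - eps]` before the transform so
#' that boundary scores (0 or 1) map to large finite logits instead of
#' +/-Inf.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param eps Single clipping bound in `(0, 0.5)`; default `1e-6`.
#' @return `log(p'/(1 - p'))` with `p' = min(max(p, eps), 1 - eps)`.
#' @examples
#' clipped_logit(0.5)           # 0
#' clipped_logit(0, eps = 1e-6) # logit(1e-6), about -13.8155
#' @export
clipped_logit <- function(p, eps = 1e-6) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5)
    stop("`eps` must be a single value in (0, 0.5)")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("`p` must contain probabilities in [0, 1]")
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

# log(1 + exp(z)) without overflow
log1pexp <- function(z) {
  out <- numeric(length(z))
  big <- z > 0
  out[big] <- z[big] + log1p(exp(-z[big]))
  out[!big] <- log1p(exp(z[!big]))
  out
}

# Deterministic child seed derived from a master seed and a string key, so
# that independent random draws do not depend on the order in which other
# streams are consumed. Always in [0, 2^31 - 2].
child_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483563
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483563)
}

# Evaluate `code` under `set.seed(seed)` while preserving the caller's RNG
# state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Small stable hash of an R object (serialized), for report provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

check_prob_outcome <- function(p_hat, outcome) {
  if (length(p_hat) != length(outcome))
    stop("`p_hat` and `outcome` must have the same length")
  if (anyNA(p_hat) || anyNA(outcome))
    stop("`p_hat` and `outcome` must not contain missing values")
  if (any(p_hat < 0) || any(p_hat > 1))
    stop("`p_hat` must lie in [0, 1]")
  if (!all(outcome %in% c(0, 1)))
    stop("`outcome` must be coded 0/1")
  invisible(TRUE)
}
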