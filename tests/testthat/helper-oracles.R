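# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by the most direct route
# (pairwise enumeration, explicit weighted least squares) so they stay
# independent of the package's implementation paths.

# Brute-force O(n^2) concordance: fraction of case-control pairs ranked
# concordantly, ties in the score counted 0.5.
cindex_bruteforce <- function(p, y) {
  cases <- p[y == 1]
  controls <- p[y == 0]
  s <- 0
  for (a in cases) s <- s + sum(a > controls) + 0.5 * sum(a == controls)
  s / (length(cases) * length(controls))
}

# Brute-force local polynomial regression with tricube weights: at each
# x0 the q = floor(n * span) nearest points get weight
# (1 - (d/h)^3)^3 with h the distance to the q-th nearest, and a weighted
# least-squares polynomial of the given degree is solved explicitly.
loess_bruteforce <- function(x0s, x, y, span = 0.75, degree = 1L) {
  n <- length(x)
  q <- min(n, floor(n * span))
  vapply(x0s, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    w <- numeric(n)
    if (h > 0) {
      inside <- d <= h
      w[inside] <- (1 - (d[inside] / h)^3)^3
    } else {
      w[d == 0] <- 1
    }
    X <- outer(x - x0, 0:degree, `^`)
    beta <- solve(crossprod(X, w * X), crossprod(X, w * y))
    beta[1, 1]
  }, numeric(1))
}

# Single-group synthetic cohort with miscalibration truth (a, b): the
# composite mode with no effects collapses to one group.
single_group_config <- function(n, seed, a, b, sigma = 1.5,
                                target_prevalence = 0.24) {
  synth_config(n = n, seed = seed, mode = "composite",
               base_truth = list(a = a, b = b, mu = NULL, sigma = sigma),
               effects = list(), target_prevalence = target_prevalence)
}

# Raw (p_hat, outcome) draws from the generating model without the cohort
# scaffolding, for tests that only need scores and labels.
draw_scores <- function(n, a, b, mu = -1.5, sigma = 1.5, seed = 1) {
  set.seed(seed)
  z <- rnorm(n, mu, sigma)
  list(p_hat = plogis(z), outcome = rbinom(n, 1, plogis(a + b * z)))
}
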