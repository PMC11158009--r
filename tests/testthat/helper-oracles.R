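# Independent oracles used across the suite. These deliberately avoid the
# package's log-space code paths: plain direct summation and double loops
# over the finite outcome space.

# Direct (non-log-space) discretised Gaussian.
naive_discrete_gaussian <- function(mu, sigma, t_max) {
  p <- exp(-((seq_len(t_max) - mu)^2) / (2 * sigma^2))
  p / sum(p)
}

# Enumeration of the event-conditional censored probability.
enum_centime_censored <- function(pmf, cc) {
  t_max <- length(pmf)
  tt <- (cc + 1):t_max
  sum(pmf[tt] / (tt - 1))
}

# Enumeration of the classical censored probability.
enum_classical_censored <- function(pmf, cc, include = FALSE) {
  t_max <- length(pmf)
  s <- if (cc >= t_max) 0 else sum(pmf[(cc + 1):t_max])
  if (include) s / t_max else s
}

enum_classical_uncensored <- function(pmf, t, include = FALSE) {
  t_max <- length(pmf)
  if (include) (t_max - t + 1) / t_max * pmf[t] else pmf[t]
}

# Naive per-anchor Cox partial log-likelihood (no sweep, no shared code).
naive_cox_pll <- function(scores, time, status) {
  unc <- which(status == 1)
  terms <- vapply(unc, function(n) {
    r <- which(time >= time[n])
    scores[n] - log(sum(exp(scores[r])))
  }, numeric(1))
  mean(terms)
}

# Brute-force concordance with half credit for prediction ties.
brute_cindex <- function(pred, time, status, direction = "time") {
  num <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!(status[i] == 1 && time[i] < time[j])) next
    den <- den + 1
    d <- pred[j] - pred[i]
    if (direction == "risk") d <- -d
    num <- num + (d > 0) + 0.5 * (d == 0)
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# A random, strictly positive pmf on 1..t_max.
random_pmf <- function(t_max) {
  p <- stats::runif(t_max, min = 0.05)
  p / sum(p)
}

random_dist <- function(t_max) event_distribution(random_pmf(t_max))

# A small seeded cohort for plumbing tests.
toy_cohort <- function(n = 30, seed = 42, t_max = 40, d = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  survival_cohort(x,
                  status = rbinom(n, 1, 0.5),
                  time = sample.int(t_max - 1, n, replace = TRUE),
                  t_max = t_max)
}
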