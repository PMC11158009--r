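# Censored-data likelihoods.
#
# Two generative stories for a right-censored record:
#
#   * Event-conditional (CenTime): the death time t is drawn first from the
#     event model, then the censoring time c is drawn uniformly on 1..t-1.
#     Marginalising t gives  P(C = c | x) = sum_{t > c} p(D = t | x)/(t - 1).
#     Both the uncensored and the censored term are consistent objectives
#     for the event-model parameters, so the model can be learned from
#     purely censored records.
#
#   * Classical: t and c are drawn independently (c uniform on 1..t_max) and
#     the smaller one is observed. A censored record then contributes
#     (1/t_max) * sum_{t > c} p(D = t | x) and an uncensored one
#     ((t_max - t + 1)/t_max) * p(D = t | x). The factors not involving the
#     model parameters are additive constants of the training objective and
#     are dropped there ("omit"), but kept for the normalisation identities
#     ("include").
#
# All sums over log-probabilities go through log-sum-exp; an empty or
# zero-mass classical sum yields -Inf with a warning rather than an error,
# so a fitting loop can observe and report it.

check_censor_time <- function(dist, censor_time, max_allowed) {
  if (!is_whole(censor_time))
    stop_usage("censoring time must be a single integer month")
  if (censor_time < 1)
    stop_usage("censoring time must be >= 1")
  if (censor_time > max_allowed)
    stop_usage("censoring time ", censor_time, " exceeds ", max_allowed,
               " on a grid with t_max = ", dist$grid$t_max,
               if (max_allowed == dist$grid$t_max - 1L)
                 " (no admissible death time remains; raise t_max)" else "")
  as.integer(censor_time)
}

#' Event-conditional (CenTime) censored log-likelihood
#'
#' Log-probability that a subject with event-time distribution `dist` is
#' observed censored at month `censor_time`, under the event-conditional
#' mechanism: the death time is drawn from `dist` and the censoring time
#' uniformly below it, giving
#' \deqn{\log P(C = c \mid x) = \log \sum_{t = c+1}^{T_{max}} \frac{p(D = t \mid x)}{t - 1}.}
#' Evaluated by log-sum-exp over `log_pmf[t] - log(t - 1)`.
#'
#' A censoring time of `t_max` is rejected: the sum would be empty because no
#' death time beyond the grid exists — enlarge the grid instead.
#'
#' @param dist a `"discrete_event_dist"`.
#' @param censor_time integer censoring month, `1 <= c <= t_max - 1`.
#' @return log-probability (scalar).
#' @export
centime_censored_logprob <- function(dist, censor_time) {
  check_dist(dist)
  t_max <- dist$grid$t_max
  censor_time <- check_censor_time(dist, censor_time, t_max - 1L)
  tt <- (censor_time + 1L):t_max
  logsumexp(dist$log_pmf[tt] - log(tt - 1))
}

#' Marginal censoring-time distribution under the CenTime mechanism
#'
#' The vector P(C = c | x) for c = 1..t_max-1, i.e. the exponentiated
#' [centime_censored_logprob()] terms. It is a sub-probability vector: its
#' total is `1 - P(D = 1 | x)`, because a subject dying in month 1 admits no
#' censoring time below the death time.
#'
#' @param dist a `"discrete_event_dist"`.
#' @return numeric vector of length `t_max - 1`.
#' @export
centime_censoring_marginal <- function(dist) {
  check_dist(dist)
  t_max <- dist$grid$t_max
  # reverse cumulative sum of pmf[t]/(t-1) over t = 2..t_max
  w <- dist$pmf[2:t_max] / (seq.int(2L, t_max) - 1)
  rev(cumsum(rev(w)))
}

#' Classical censored log-likelihood
#'
#' Log-likelihood of a record censored at `censor_time` when death and
#' censoring times are drawn independently (censoring uniform on the grid):
#' \deqn{\log P(\delta = 0, C = c \mid x) = \log\Big[\tfrac{1}{T_{max}} \sum_{t = c+1}^{T_{max}} p(D = t \mid x)\Big].}
#' With `constants = "omit"` the additive `-log(t_max)` is dropped — the form
#' used in the training objective; `"include"` gives the fully normalised
#' probability used in the joint-normalisation identity.
#'
#' `censor_time = t_max` leaves an empty sum: the value is `-Inf`, returned
#' with a warning (the classical mechanism produces such a record with
#' probability zero).
#'
#' @param dist a `"discrete_event_dist"`.
#' @param censor_time integer censoring month in `1..t_max`.
#' @param constants `"omit"` (training objective, default) or `"include"`.
#' @return log-probability (scalar, possibly `-Inf`).
#' @export
classical_censored_logprob <- function(dist, censor_time,
                                       constants = c("omit", "include")) {
  check_dist(dist)
  constants <- match.arg(constants)
  t_max <- dist$grid$t_max
  censor_time <- check_censor_time(dist, censor_time, t_max)
  if (censor_time == t_max) {
    warning("classical censored likelihood at c = t_max has no mass beyond c; returning -Inf")
    return(-Inf)
  }
  val <- logsumexp(dist$log_pmf[(censor_time + 1L):t_max])
  if (constants == "include") val <- val - log(t_max)
  val
}

#' Classical uncensored log-likelihood
#'
#' Log-likelihood of a death observed at month `t` under the classical
#' mechanism:
#' \deqn{\log P(\delta = 1, D = t \mid x) = \log\Big[\tfrac{T_{max} - t + 1}{T_{max}}\, p(D = t \mid x)\Big].}
#' The survival-of-censoring factor `(t_max - t + 1)/t_max` does not involve
#' the model parameters; `constants = "omit"` drops it (training objective),
#' `"include"` keeps the full probability.
#'
#' @inheritParams classical_censored_logprob
#' @param t integer death month in `1..t_max`.
#' @return log-probability (scalar).
#' @export
classical_uncensored_logprob <- function(dist, t, constants = c("omit", "include")) {
  check_dist(dist)
  constants <- match.arg(constants)
  t_max <- dist$grid$t_max
  if (!is_whole(t) || t < 1 || t > t_max)
    stop_usage("`t` must be an integer month in 1..t_max")
  val <- dist$log_pmf[t]
  if (constants == "include") val <- val + log((t_max - t + 1) / t_max)
  val
}

#' Dataset log-likelihood under a censoring model
#'
#' Sums, over the cohort, the event log-probability `log p(D = t_n | x_n)`
#' for uncensored subjects and the model-specific censored log-term for
#' censored subjects ([centime_censored_logprob()] or
#' [classical_censored_logprob()]).
#'
#' @param cohort a `"survival_cohort"`.
#' @param dists list of `"discrete_event_dist"`, one per subject, on the
#'   cohort's grid.
#' @param model `"centime"` or `"classical"`.
#' @param constants for the classical model, whether additive constants are
#'   omitted (default, the training objective) or included (the normalised
#'   probability form). Ignored for `"centime"`, which is already a proper
#'   probability.
#' @return list with `total` (sum over subjects), `mean` (per-observation
#'   average, the optimiser scale) and `per_observation` (vector of terms).
#' @export
dataset_loglik <- function(cohort, dists, model = c("centime", "classical"),
                           constants = c("omit", "include")) {
  check_cohort(cohort)
  model <- match.arg(model)
  constants <- match.arg(constants)
  n <- n_subjects(cohort)
  if (!is.list(dists) || length(dists) != n)
    stop_usage("`dists` must be a list with one distribution per subject")
  if (model == "centime") validate_cohort(cohort, "centime")
  terms <- vapply(seq_len(n), function(i) {
    d <- dists[[i]]
    if (cohort$status[i] == 1L) {
      if (model == "centime") d$log_pmf[cohort$time[i]]
      else classical_uncensored_logprob(d, cohort$time[i], constants)
    } else {
      if (model == "centime") centime_censored_logprob(d, cohort$time[i])
      else classical_censored_logprob(d, cohort$time[i], constants)
    }
  }, numeric(1))
  list(total = sum(terms), mean = mean(terms), per_observation = terms)
}
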