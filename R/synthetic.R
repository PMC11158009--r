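# Seeded synthetic survival cohorts.
#
# Two generative censoring mechanisms produce the test bed for every
# estimator in the package:
#
#   * event-conditional: draw the death time t from the subject's event
#     distribution; if the subject is censored (a per-subject coin with
#     probability `censoring_prob`), draw c uniformly on 1..t-1 and record
#     (status = 0, c), otherwise record (status = 1, t);
#
#   * classical: draw t from the event distribution and c uniformly on
#     1..t_max independently; if c < t record (status = 0, c), else
#     (status = 1, t).
#
# A third sampler draws an exact number of censored records directly from
# the event-conditional censoring marginal, so cohorts with any prescribed
# censored fraction — including 100% — can be produced; that is the bed for
# the consistency-under-pure-censoring experiments.
#
# The true event model is linear: mu(x) = intercept + weights . x with
# standard-normal covariates and a shared sigma, so parameter recovery is
# well posed.

#' Configuration of a synthetic cohort generator
#'
#' @param n_subjects number of subjects.
#' @param t_max grid horizon in months (default 156, a 13-year horizon
#'   typical of fibrotic-lung-disease cohorts).
#' @param covariate_dim number of standard-normal covariates (0 allowed).
#' @param intercept true intercept of mu(x), months. Defaults to the grid
#'   midpoint.
#' @param true_weights true covariate weights of mu(x), months per unit
#'   covariate; recycled scalar or length `covariate_dim`.
#' @param sigma event-distribution scale, months (default 12).
#' @param mechanism `"event_conditional"`, `"classical"` or
#'   `"fixed_proportion"`.
#' @param censoring_prob per-subject probability of censoring under the
#'   event-conditional mechanism (default 0.65, a typical right-censored
#'   share of clinical survival cohorts).
#' @param censored_fraction exact fraction of censored records under the
#'   fixed-proportion sampler, in \[0, 1\].
#' @param t1_policy what the event-conditional mechanism does with subjects
#'   whose drawn death month is 1 (no admissible censoring time):
#'   `"uncensored"` emits them uncensored (default), `"resample"` redraws t
#'   until it exceeds 1.
#' @param seed RNG seed; the same config always yields the identical cohort.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects, t_max = 156, covariate_dim = 2,
                             intercept = (t_max + 1) / 2,
                             true_weights = rep(5, covariate_dim),
                             sigma = 12,
                             mechanism = c("event_conditional", "classical",
                                           "fixed_proportion"),
                             censoring_prob = 0.65,
                             censored_fraction = 0.65,
                             t1_policy = c("uncensored", "resample"),
                             seed = 1L) {
  mechanism <- match.arg(mechanism)
  t1_policy <- match.arg(t1_policy)
  if (!is_whole(n_subjects) || n_subjects < 1)
    stop_usage("`n_subjects` must be a positive integer")
  if (!is_whole(covariate_dim) || covariate_dim < 0)
    stop_usage("`covariate_dim` must be a non-negative integer")
  if (length(true_weights) == 1L) true_weights <- rep(true_weights, covariate_dim)
  if (length(true_weights) != covariate_dim)
    stop_usage("`true_weights` must have length `covariate_dim`")
  if (sigma <= 0) stop_usage("`sigma` must be positive")
  if (censoring_prob < 0 || censoring_prob > 1)
    stop_usage("`censoring_prob` must be in [0, 1]")
  if (censored_fraction < 0 || censored_fraction > 1)
    stop_usage("`censored_fraction` must be in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects), t_max = as.integer(t_max),
                 covariate_dim = as.integer(covariate_dim),
                 intercept = intercept, true_weights = as.numeric(true_weights),
                 sigma = sigma, mechanism = mechanism,
                 censoring_prob = censoring_prob,
                 censored_fraction = censored_fraction,
                 t1_policy = t1_policy, seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw the covariate matrix of a config
#'
#' Standard-normal covariates, seeded from the config, one row per subject.
#'
#' @param config a [generator_config()].
#' @return numeric matrix `n_subjects x covariate_dim` (possibly 0 columns).
#' @export
generate_covariates <- function(config) {
  set.seed(config$seed)
  x <- matrix(stats::rnorm(config$n_subjects * config$covariate_dim),
              nrow = config$n_subjects, ncol = config$covariate_dim)
  if (config$covariate_dim > 0)
    colnames(x) <- paste0("x", seq_len(config$covariate_dim))
  x
}

true_mu <- function(config, covariates) {
  drop(config$intercept + covariates %*% config$true_weights)
}

# inverse-CDF draw of one month per row of a pmf matrix
draw_from_pmf_rows <- function(pmf_matrix) {
  cum <- t(apply(pmf_matrix, 1, cumsum))
  u <- stats::runif(nrow(pmf_matrix)) * cum[, ncol(cum)]
  as.integer(rowSums(cum < u) + 1L)
}

subject_pmf_matrix <- function(config, mu) {
  grid <- time_grid(config$t_max)
  if (length(unique(mu)) == 1L) {
    # intercept-only cohorts share one event distribution
    p <- discrete_gaussian(mu[1], config$sigma, grid)$pmf
    return(matrix(p, nrow = length(mu), ncol = config$t_max, byrow = TRUE))
  }
  do.call(rbind, lapply(mu, function(m)
    discrete_gaussian(m, config$sigma, grid)$pmf))
}

#' Sample a cohort under the event-conditional censoring mechanism
#'
#' Per subject: draw the death month t from their discretised-Gaussian event
#' distribution; with probability `censoring_prob` (and t > 1) draw the
#' censoring month uniformly on `1..t-1` and emit a censored record,
#' otherwise emit the death. Subjects drawn at t = 1 have no admissible
#' censoring time and follow `t1_policy`.
#'
#' @param config a [generator_config()].
#' @return a `"survival_cohort"` with attribute `"true_mu"`.
#' @export
sample_event_conditional <- function(config) {
  x <- generate_covariates(config) # sets the seed
  mu <- true_mu(config, x)
  t <- draw_from_pmf_rows(subject_pmf_matrix(config, mu))
  if (config$t1_policy == "resample") {
    while (any(t == 1L)) {
      redo <- which(t == 1L)
      t[redo] <- draw_from_pmf_rows(subject_pmf_matrix(config, mu[redo]))
    }
  }
  censor <- stats::runif(config$n_subjects) < config$censoring_prob & t > 1L
  time <- t
  time[censor] <- vapply(t[censor], function(ti)
    sample.int(ti - 1L, 1L), integer(1))
  out <- survival_cohort(x, status = as.integer(!censor), time = time,
                         t_max = config$t_max)
  attr(out, "true_mu") <- mu
  out
}

#' Sample a cohort under the classical censoring mechanism
#'
#' Per subject: draw the death month t from the event distribution and a
#' censoring month c uniformly on `1..t_max`, independently. If c < t the
#' record is censored at c; otherwise the death at t is observed.
#'
#' @param config a [generator_config()].
#' @return a `"survival_cohort"` with attribute `"true_mu"`.
#' @export
sample_classical <- function(config) {
  x <- generate_covariates(config)
  mu <- true_mu(config, x)
  t <- draw_from_pmf_rows(subject_pmf_matrix(config, mu))
  cc <- sample.int(config$t_max, config$n_subjects, replace = TRUE)
  censored <- cc < t
  time <- ifelse(censored, cc, t)
  out <- survival_cohort(x, status = as.integer(!censored), time = time,
                         t_max = config$t_max)
  attr(out, "true_mu") <- mu
  out
}

#' Sample a cohort with an exact censored proportion
#'
#' Draws exactly `round(n_subjects * censored_fraction)` censored records
#' directly from the event-conditional censoring marginal
#' ([centime_censoring_marginal()], by inverse CDF) and the remainder as
#' deaths from the event distribution. Which subjects are censored is chosen
#' uniformly at random, independent of covariates. The subject counts are
#' exact, not stochastic — a property the event-conditional mixture affords
#' and the classical mechanism does not — so purely censored cohorts
#' (`censored_fraction = 1`) can be produced for consistency experiments.
#'
#' @param config a [generator_config()].
#' @return a `"survival_cohort"` with attribute `"true_mu"`.
#' @export
sample_fixed_proportion <- function(config) {
  x <- generate_covariates(config)
  mu <- true_mu(config, x)
  n <- config$n_subjects
  n_cens <- round(n * config$censored_fraction)
  cens_idx <- if (n_cens > 0) sort(sample.int(n, n_cens)) else integer(0)
  grid <- time_grid(config$t_max)
  time <- integer(n)
  status <- rep(1L, n)
  status[cens_idx] <- 0L
  for (i in seq_len(n)) {
    d <- discrete_gaussian(mu[i], config$sigma, grid)
    if (status[i] == 1L) {
      time[i] <- sample.int(config$t_max, 1L, prob = d$pmf)
    } else {
      marg <- centime_censoring_marginal(d)
      time[i] <- sample.int(config$t_max - 1L, 1L, prob = marg)
    }
  }
  out <- survival_cohort(x, status = status, time = time, t_max = config$t_max)
  attr(out, "true_mu") <- mu
  out
}

#' Sample a cohort according to the config's mechanism
#'
#' Dispatches to the mechanism named in the config.
#'
#' @param config a [generator_config()].
#' @return a `"survival_cohort"`.
#' @export
sample_cohort <- function(config) {
  switch(config$mechanism,
         event_conditional = sample_event_conditional(config),
         classical = sample_classical(config),
         fixed_proportion = sample_fixed_proportion(config))
}
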