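# Discrete time grid and the discretised-Gaussian event-time distribution.
#
# All likelihood machinery in the package works on a finite integer grid of
# months 1..t_max. The event-time model places a Gaussian density on that
# grid and renormalises it to a proper probability mass function, which keeps
# the ordinal structure of time (near misses are cheap, far misses expensive)
# while emitting only two parameters (mu, sigma) per subject.

#' Discrete monthly time grid
#'
#' The survival horizon: consecutive integer months `1..t_max`. Every
#' distribution, likelihood and metric in the package is defined on such a
#' grid.
#'
#' @param t_max integer horizon in months, at least 2.
#' @return an object of class `"time_grid"` with elements `t_max` and
#'   `times` (the vector `1:t_max`).
#' @examples
#' g <- time_grid(156)
#' g$t_max
#' @export
time_grid <- function(t_max) {
  if (!is_whole(t_max) || t_max < 2)
    stop_usage("`t_max` must be a single integer >= 2")
  structure(list(t_max = as.integer(t_max), times = seq_len(t_max)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> months 1..", x$t_max, "\n", sep = "")
  invisible(x)
}

as_time_grid <- function(grid) {
  if (inherits(grid, "time_grid")) return(grid)
  time_grid(grid)
}

#' Discretised Gaussian event-time distribution
#'
#' Evaluates a Gaussian density with parameters `mu` (months, unconstrained;
#' it may lie outside the grid) and `sigma` (months, positive) at the grid
#' points `1..t_max` and renormalises so the mass function sums to one.
#' Computation is carried out in log space with max-subtraction, so extreme
#' `mu`/`sigma` values produce valid (if tiny) probabilities rather than
#' underflowing to zero-with-invalid-log.
#'
#' @param mu real location parameter in months.
#' @param sigma positive scale parameter in months.
#' @param grid a [time_grid()] object, or an integer `t_max` as shorthand.
#' @return an object of class `"discrete_event_dist"`: a list with `grid`,
#'   `pmf`, `log_pmf`, `mu`, `sigma`. Index `t` of `pmf` is P(D = t | x).
#' @examples
#' d <- discrete_gaussian(mu = 36, sigma = 12, grid = time_grid(156))
#' sum(d$pmf)
#' point_estimate(d, "mean")
#' @seealso [event_distribution()] to wrap an arbitrary mass function.
#' @export
discrete_gaussian <- function(mu, sigma, grid) {
  grid <- as_time_grid(grid)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop_usage("`mu` must be a single finite number")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_usage("`sigma` must be a single positive number")
  log_unnorm <- -((grid$times - mu)^2) / (2 * sigma^2)
  log_pmf <- log_unnorm - logsumexp(log_unnorm)
  structure(list(grid = grid, pmf = exp(log_pmf), log_pmf = log_pmf,
                 mu = mu, sigma = sigma),
            class = "discrete_event_dist")
}

#' Event-time distribution from an explicit mass function
#'
#' Wraps an arbitrary probability vector over the grid `1..length(pmf)` in
#' the container used throughout the package. The vector must be
#' non-negative and sum to one (renormalised exactly after a tolerance
#' check), which makes it convenient for uniform or point-mass distributions
#' in examples and tests.
#'
#' @param pmf numeric vector of probabilities, one per grid month.
#' @param tol tolerance on `abs(sum(pmf) - 1)`.
#' @return a `"discrete_event_dist"` object.
#' @export
event_distribution <- function(pmf, tol = 1e-8) {
  if (!is.numeric(pmf) || length(pmf) < 2L)
    stop_usage("`pmf` must be a numeric vector with at least 2 entries")
  if (any(!is.finite(pmf)) || any(pmf < 0))
    stop_usage("`pmf` entries must be finite and non-negative")
  if (abs(sum(pmf) - 1) > tol)
    stop_usage("`pmf` must sum to 1 (got ", format(sum(pmf)), ")")
  pmf <- pmf / sum(pmf)
  structure(list(grid = time_grid(length(pmf)), pmf = pmf,
                 log_pmf = log(pmf), mu = NA_real_, sigma = NA_real_),
            class = "discrete_event_dist")
}

#' @export
print.discrete_event_dist <- function(x, ...) {
  cat("<discrete_event_dist> on months 1..", x$grid$t_max, sep = "")
  if (is.finite(x$mu))
    cat("  (discretised Gaussian, mu = ", format(x$mu),
        ", sigma = ", format(x$sigma), ")", sep = "")
  cat("\n  mean = ", format(point_estimate(x, "mean")), "\n", sep = "")
  invisible(x)
}

check_dist <- function(dist) {
  if (!inherits(dist, "discrete_event_dist"))
    stop_usage("expected a `discrete_event_dist` object")
  dist
}

#' Cumulative distribution function of an event-time distribution
#'
#' Returns F(t | x) = P(D <= t | x), the sum of the mass function up to and
#' including month `t`.
#'
#' @param dist a `"discrete_event_dist"`.
#' @param t integer month(s) in `1..t_max`; vectorised.
#' @return cumulative probabilities, same length as `t`.
#' @export
event_cdf <- function(dist, t) {
  check_dist(dist)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t != round(t)))
    stop_usage("`t` must be integer month(s)")
  if (any(t < 1) || any(t > dist$grid$t_max))
    stop_usage("`t` must lie in 1..t_max = 1..", dist$grid$t_max)
  cumsum(dist$pmf)[t]
}

#' Point prediction of the event time
#'
#' Collapses a distribution over months to a single predicted death time.
#' The default, the distribution mean, uses the full shape of the mass
#' function and is the estimate fed to the MAE/RAE metrics; the mode is
#' offered as a discrete alternative, with ties broken to the smallest month
#' so predictions are reproducible.
#'
#' @param dist a `"discrete_event_dist"`.
#' @param method `"mean"` (default) or `"mode"`.
#' @return predicted time in months (real for `"mean"`, integer for
#'   `"mode"`).
#' @export
point_estimate <- function(dist, method = c("mean", "mode")) {
  check_dist(dist)
  method <- match.arg(method)
  switch(method,
         mean = sum(dist$grid$times * dist$pmf),
         mode = dist$grid$times[which.max(dist$pmf)])
}
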