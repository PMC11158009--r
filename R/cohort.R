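# Survival cohort container: covariates plus (status, time) per subject.
#
# status is the event indicator delta: 1 means the death time t was observed
# ("uncensored"), 0 means the subject was only known alive up to a censoring
# time c ("right-censored"); the `time` column holds t or c accordingly, in
# integer months on the grid 1..t_max.

#' Construct a survival cohort
#'
#' One row per subject: a covariate vector, an event indicator
#' `status` (1 = death observed at `time`, 0 = right-censored at `time`),
#' and the observed time in integer months on the grid `1..t_max`.
#'
#' @param covariates numeric matrix or data frame with one row per subject;
#'   may have zero columns for an intercept-only cohort.
#' @param status integer vector of 0/1 event indicators.
#' @param time integer vector of observed months, each in `1..t_max`.
#' @param t_max the grid horizon in months.
#' @return an object of class `"survival_cohort"`: list with `covariates`
#'   (matrix), `status`, `time`, `t_max`.
#' @examples
#' cohort <- survival_cohort(matrix(rnorm(10), 5), status = c(1, 0, 1, 1, 0),
#'                           time = c(3, 8, 12, 2, 20), t_max = 60)
#' uncensored_index(cohort)
#' @export
survival_cohort <- function(covariates, status, time, t_max) {
  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = length(status), ncol = 0)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- nrow(covariates)
  if (length(status) != n || length(time) != n)
    stop_usage("`covariates`, `status` and `time` must describe the same number of subjects")
  if (n < 1L) stop_usage("a cohort must contain at least one subject")
  if (!all(status %in% c(0, 1)))
    stop_usage("`status` entries must be 0 (censored) or 1 (uncensored); offending rows: ",
               paste(utils::head(which(!(status %in% c(0, 1))), 5), collapse = ", "))
  if (any(!is.finite(time)) || any(time != round(time)))
    stop_usage("`time` entries must be integer months; offending rows: ",
               paste(utils::head(which(!is.finite(time) | time != round(time)), 5), collapse = ", "))
  if (!is_whole(t_max) || t_max < 2) stop_usage("`t_max` must be an integer >= 2")
  if (any(time < 1) || any(time > t_max))
    stop_usage("`time` entries must lie in 1..t_max; offending rows: ",
               paste(utils::head(which(time < 1 | time > t_max), 5), collapse = ", "))
  if (is.null(colnames(covariates)) && ncol(covariates) > 0)
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  structure(list(covariates = covariates,
                 status = as.integer(status),
                 time = as.integer(time),
                 t_max = as.integer(t_max)),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat("<survival_cohort> ", n_subjects(x), " subjects, ",
      ncol(x$covariates), " covariates, t_max = ", x$t_max, "\n",
      "  uncensored: ", length(uncensored_index(x)),
      ", censored: ", length(censored_index(x)), "\n", sep = "")
  invisible(x)
}

#' @rdname survival_cohort
#' @param cohort a `"survival_cohort"`.
#' @export
n_subjects <- function(cohort) length(cohort$status)

#' Index sets of a cohort
#'
#' `uncensored_index()` returns the subjects with `status == 1` (death time
#' observed); `censored_index()` the complement. Together they partition the
#' cohort.
#'
#' @param cohort a `"survival_cohort"`.
#' @return integer vector of subject indices.
#' @export
uncensored_index <- function(cohort) which(cohort$status == 1L)

#' @rdname uncensored_index
#' @export
censored_index <- function(cohort) which(cohort$status == 0L)

#' @export
as.data.frame.survival_cohort <- function(x, ...) {
  df <- as.data.frame(x$covariates)
  df$status <- x$status
  df$time <- x$time
  df
}

check_cohort <- function(cohort) {
  if (!inherits(cohort, "survival_cohort"))
    stop_usage("expected a `survival_cohort` object")
  cohort
}

#' Validate a cohort for a given likelihood
#'
#' The event-conditional (CenTime) likelihood assigns zero probability to a
#' censoring time of `t_max` (there is no admissible death time beyond it),
#' so such records are rejected up front with an instruction to raise
#' `t_max`, rather than silently contributing `-Inf` to the objective.
#'
#' @param cohort a `"survival_cohort"`.
#' @param likelihood `"centime"` or `"classical"`.
#' @return the cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort, likelihood = c("centime", "classical")) {
  check_cohort(cohort)
  likelihood <- match.arg(likelihood)
  if (likelihood == "centime") {
    bad <- which(cohort$status == 0L & cohort$time >= cohort$t_max)
    if (length(bad))
      stop_usage("CenTime likelihood requires censored times < t_max (no admissible ",
                 "death time remains); raise `t_max` above ", cohort$t_max,
                 ". Offending rows: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(cohort)
}
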