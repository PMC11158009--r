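# Cohort and model file formats.
#
# Cohorts are comma-delimited text with a header: free-form covariate
# columns, then "status" (0/1) and "time" (integer months). Fitted event
# models round-trip through JSON. Neither reader mutates its input.

#' Read a survival cohort from delimited text
#'
#' Expects a comma-delimited file with a header row containing `status` and
#' `time` columns; every other column is taken as a covariate. Validation
#' failures name the offending rows.
#'
#' @param path file path.
#' @param t_max grid horizon; defaults to the largest time in the file.
#' @param likelihood optional; when `"centime"`, censored times equal to
#'   `t_max` are rejected (see [validate_cohort()]).
#' @return a `"survival_cohort"`.
#' @export
read_survival_table <- function(path, t_max = NULL, likelihood = NULL) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(c("status", "time"), names(df))
  if (length(missing_cols))
    stop_usage("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad_status <- which(!(df$status %in% c(0, 1)))
  if (length(bad_status))
    stop_usage("`status` must be 0 or 1; offending rows: ",
               paste(utils::head(bad_status, 5), collapse = ", "))
  bad_time <- which(!is.finite(df$time) | df$time != round(df$time) | df$time < 1)
  if (length(bad_time))
    stop_usage("`time` must be integer months >= 1; offending rows: ",
               paste(utils::head(bad_time, 5), collapse = ", "))
  covars <- df[setdiff(names(df), c("status", "time"))]
  if (is.null(t_max)) t_max <- max(df$time)
  if (t_max < 2) t_max <- 2
  cohort <- survival_cohort(as.matrix(covars), df$status, df$time, t_max)
  if (!is.null(likelihood) && likelihood %in% c("centime", "classical"))
    validate_cohort(cohort, likelihood)
  cohort
}

#' Write a survival cohort as delimited text
#'
#' @param cohort a `"survival_cohort"`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_survival_table <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a fitted event model as JSON
#'
#' @param fit an `"event_model_fit"`.
#' @param path file path.
#' @return `write_event_model` the path invisibly; `read_event_model` the
#'   fit object (without the optimisation trace).
#' @export
write_event_model <- function(fit, path) {
  if (!inherits(fit, "event_model_fit")) stop_usage("expected an `event_model_fit`")
  payload <- list(type = "event_model_fit",
                  likelihood = fit$likelihood,
                  intercept = fit$intercept,
                  weights = as.list(fit$weights),
                  sigma = fit$sigma, learn_sigma = fit$learn_sigma,
                  t_max = fit$t_max, loglik = fit$loglik,
                  converged = fit$converged, n_iter = fit$n_iter)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_event_model
#' @export
read_event_model <- function(path) {
  if (!file.exists(path)) stop_usage("file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$type) || p$type != "event_model_fit")
    stop_usage("not an event-model file: ", path)
  structure(list(intercept = p$intercept,
                 weights = unlist(p$weights) %||% numeric(0),
                 sigma = p$sigma, learn_sigma = isTRUE(p$learn_sigma),
                 likelihood = p$likelihood, t_max = p$t_max,
                 loglik = p$loglik, loglik_total = NA_real_,
                 trace = numeric(0), converged = isTRUE(p$converged),
                 n_iter = p$n_iter,
                 init = NULL),
            class = "event_model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
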