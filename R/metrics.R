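# Evaluation metrics: Harrell-style concordance index, mean absolute error
# and relative absolute error of predicted death times. MAE/RAE are averaged
# over uncensored subjects only — a censored time is a lower bound, not a
# target.

#' Concordance index
#'
#' Probability that a randomly chosen comparable pair of subjects is ordered
#' by the predictions the same way as by their true times. A pair (i, j) is
#' comparable when `time_i < time_j` and subject i is uncensored (a
#' censored earlier time cannot certify the ordering); tied times are not
#' comparable. Tied predictions receive half credit (Harrell convention),
#' so a constant predictor scores 0.5 rather than being undefined.
#'
#' @param predictions per-subject orderable values: risk scores
#'   (`direction = "risk"`, larger = expected to die earlier) or predicted
#'   survival times (`direction = "time"`, larger = expected to die later).
#' @param time integer observed months.
#' @param status 0/1 event indicators.
#' @param direction `"risk"` or `"time"`.
#' @return the concordance index in \[0, 1\], with attribute `n_pairs` (the
#'   number of comparable pairs). Zero comparable pairs is an error.
#' @export
concordance_index <- function(predictions, time, status,
                              direction = c("risk", "time")) {
  direction <- match.arg(direction)
  n <- length(predictions)
  if (length(time) != n || length(status) != n)
    stop_usage("`predictions`, `time` and `status` lengths differ")
  concordant <- 0
  n_pairs <- 0L
  for (i in which(status == 1)) {
    js <- which(time > time[i])
    if (!length(js)) next
    diff <- predictions[js] - predictions[i] # j minus i
    # i dies first; concordant if model places i earlier:
    #   direction = "time": pred_i < pred_j  (diff > 0)
    #   direction = "risk": pred_i > pred_j  (diff < 0)
    if (direction == "risk") diff <- -diff
    concordant <- concordant + sum(diff > 0) + 0.5 * sum(diff == 0)
    n_pairs <- n_pairs + length(js)
  }
  if (n_pairs == 0L)
    stop_usage("concordance index undefined: no comparable pairs ",
               "(need an uncensored subject with a strictly smaller time)")
  structure(concordant / n_pairs, n_pairs = n_pairs)
}

check_metric_inputs <- function(predicted_times, true_times, status) {
  n <- length(predicted_times)
  if (length(true_times) != n || length(status) != n)
    stop_usage("`predicted_times`, `true_times` and `status` lengths differ")
  unc <- which(status == 1)
  if (length(unc) == 0L)
    stop_usage("metric undefined: no uncensored subjects to evaluate")
  unc
}

#' Mean absolute error of predicted death times
#'
#' Average of `|t_hat_i - t_i|` in months over uncensored subjects; censored
#' subjects are excluded.
#'
#' @param predicted_times per-subject predicted death times (months).
#' @param true_times observed months.
#' @param status 0/1 event indicators.
#' @return MAE in months.
#' @export
mae <- function(predicted_times, true_times, status) {
  unc <- check_metric_inputs(predicted_times, true_times, status)
  mean(abs(predicted_times[unc] - true_times[unc]))
}

#' Relative absolute error of predicted death times
#'
#' Average of `|t_hat_i - t_i| / t_i` over uncensored subjects. Times live
#' on the grid starting at month 1, so the denominator is never zero.
#'
#' @inheritParams mae
#' @return RAE (dimensionless).
#' @export
rae <- function(predicted_times, true_times, status) {
  unc <- check_metric_inputs(predicted_times, true_times, status)
  mean(abs(predicted_times[unc] - true_times[unc]) / true_times[unc])
}

new_metrics_report <- function(c_index, mae, rae, n_uncensored, n_pairs) {
  structure(list(c_index = c_index, mae = mae, rae = rae,
                 n_uncensored_evaluated = n_uncensored,
                 n_pairs_evaluated = n_pairs),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report>\n",
      "  C-index: ", format(round(x$c_index, digits)),
      "  (", x$n_pairs_evaluated, " comparable pairs)\n",
      "  MAE:     ", format(round(x$mae, digits)), " months\n",
      "  RAE:     ", format(round(x$rae, digits)), "\n",
      "  uncensored subjects evaluated: ", x$n_uncensored_evaluated, "\n",
      sep = "")
  invisible(x)
}
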