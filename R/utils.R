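# Internal numerical helpers shared across likelihood code.

#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` with max-subtraction so that large negative
#' magnitudes do not underflow. An all `-Inf` input returns `-Inf`.
#'
#' @param x numeric vector of log-scale values.
#' @return a single numeric value.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m) # all -Inf, or contains +Inf/NaN dominated cases
  m + log(sum(exp(x - m)))
}

# Scalar integer-ness check used by input validators.
is_whole <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

stop_usage <- function(...) {
  stop(..., call. = FALSE)
}
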