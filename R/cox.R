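# Cox proportional-hazards partial likelihood, minibatch and memory-bank
# (CoxMB) variants, DeepHit-style losses, and death-time prediction from
# risk scores via the Breslow baseline hazard.
#
# Risk-set convention: R_n = { m : time_m >= time_n }, using observed times
# for censored and uncensored subjects alike (Breslow handling of ties).
# All objectives are invariant to adding a constant to every score.

risk_set_members <- function(time, anchor) which(time >= time[anchor])

#' Relative death risk of a subject within its risk set
#'
#' Under the proportional-hazards factorisation h(t|x) = h0(t) exp(g(x)),
#' the probability that the anchor subject is the one to die among its risk
#' set is `exp(g_n) / sum_{m in R_n} exp(g_m)`; computed via log-sum-exp.
#'
#' @param scores numeric vector of risk scores g(x), one per subject.
#' @param anchor index of the (uncensored) subject whose risk is evaluated.
#' @param members indices of the risk set; must contain `anchor`.
#' @return probability (scalar).
#' @export
cox_relative_risk <- function(scores, anchor, members) {
  if (length(members) == 0L) stop_usage("risk set is empty")
  if (!anchor %in% members) stop_usage("`members` must contain `anchor`")
  exp(scores[anchor] - logsumexp(scores[members]))
}

# Per-subject log risk-set denominators log sum_{m: time_m >= time_n} exp(g_m).
# method "naive" loops subject by subject; "sweep" exploits the nesting of
# risk sets under the time ordering with one reverse running log-sum-exp.
cox_log_denominators <- function(scores, time, method = c("naive", "sweep")) {
  method <- match.arg(method)
  n <- length(scores)
  if (method == "naive") {
    vapply(seq_len(n), function(i) logsumexp(scores[time >= time[i]]), numeric(1))
  } else {
    o <- order(time)
    s <- scores[o]; tm <- time[o]
    suf <- numeric(n)
    run <- -Inf
    for (i in n:1) {
      m <- max(run, s[i])
      run <- m + log(exp(run - m) + exp(s[i] - m))
      suf[i] <- run
    }
    # tied times share the denominator of the first (earliest) position
    first_pos <- match(tm, tm)
    out <- numeric(n)
    out[o] <- suf[first_pos]
    out
  }
}

#' Cox partial log-likelihood
#'
#' The average, over uncensored subjects, of
#' `g_n - log sum_{m in R_n} exp(g_m)` with the risk set
#' `R_n = {m : time_m >= time_n}`. The `1/|N_uncens|` normalisation makes the
#' value comparable across cohorts and minibatches. Censored subjects enter
#' only through the risk-set denominators, which is why the objective is
#' undefined on a cohort with no observed deaths.
#'
#' @param scores numeric vector of risk scores, one per subject.
#' @param time integer observed months.
#' @param status 0/1 event indicators.
#' @param method `"naive"` per-subject evaluation (default; exact reference
#'   arithmetic) or `"sweep"`, a single reverse cumulative log-sum-exp over
#'   the nested risk sets.
#' @return mean partial log-likelihood (scalar).
#' @export
cox_partial_loglik <- function(scores, time, status, method = c("naive", "sweep")) {
  if (any(!is.finite(scores))) stop_usage("`scores` must be finite")
  unc <- which(status == 1)
  if (length(unc) == 0L)
    stop_usage("Cox partial likelihood is undefined without uncensored subjects")
  denom <- cox_log_denominators(scores, time, method)
  mean(scores[unc] - denom[unc])
}

#' Minibatch Cox objective with an explicit skip signal
#'
#' Evaluates the partial log-likelihood within a minibatch, using risk sets
#' restricted to the batch. A batch containing no uncensored subject leaves
#' the objective undefined; rather than returning 0 (which would silently
#' contribute a gradient-free term), an explicit skip signal is returned so
#' a training loop can exclude the batch.
#'
#' @inheritParams cox_partial_loglik
#' @return the batch objective, or an object of class `"cox_skip"` (test
#'   with [is_skip_signal()]).
#' @export
minibatch_cox_loglik <- function(scores, time, status) {
  if (!any(status == 1))
    return(structure(list(reason = "no uncensored subjects in minibatch"),
                     class = "cox_skip"))
  cox_partial_loglik(scores, time, status, method = "naive")
}

#' @rdname minibatch_cox_loglik
#' @param x object to test.
#' @export
is_skip_signal <- function(x) inherits(x, "cox_skip")

#' @export
print.cox_skip <- function(x, ...) {
  cat("<cox_skip>", x$reason, "\n")
  invisible(x)
}

#' Memory bank of per-subject risk scores
#'
#' A persistent store holding, for every training subject, the most recent
#' risk score the model produced for them, together with the fixed
#' `(time, status)` labels. Small minibatches of high-resolution inputs
#' often contain no uncensored subject, making the within-batch Cox
#' objective undefined; the bank supplies stored scores of out-of-batch
#' subjects so risk sets (and anchors) can be built anyway. Stored scores
#' are treated as constants — gradients flow only through current-batch
#' scores.
#'
#' @param time integer observed months, one per training subject.
#' @param status 0/1 event indicators.
#' @param K fraction in (0, 1] of eligible out-of-batch subjects drawn from
#'   the bank when forming risk sets (default 1: use all).
#' @return an object of class `"memory_bank"` with `scores` (initially
#'   `NA`), `time`, `status`, `K`.
#' @export
memory_bank <- function(time, status, K = 1) {
  if (length(time) != length(status)) stop_usage("`time` and `status` lengths differ")
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K > 1)
    stop_usage("`K` must be in (0, 1]")
  structure(list(scores = rep(NA_real_, length(time)),
                 time = as.integer(time), status = as.integer(status), K = K),
            class = "memory_bank")
}

#' @rdname memory_bank
#' @param bank a `"memory_bank"`.
#' @param indices subject indices whose scores are refreshed.
#' @param new_scores replacement scores, same length as `indices`.
#' @export
memory_bank_update <- function(bank, indices, new_scores) {
  if (!inherits(bank, "memory_bank")) stop_usage("expected a `memory_bank`")
  if (length(indices) != length(new_scores))
    stop_usage("`indices` and `new_scores` lengths differ")
  if (any(indices < 1) || any(indices > length(bank$scores)) ||
      any(indices != round(indices)))
    stop_usage("`indices` out of range for this bank")
  bank$scores[indices] <- new_scores
  bank
}

#' Memory-bank Cox objective (CoxMB)
#'
#' Partial-likelihood objective for a minibatch augmented with bank-stored
#' scores. A fraction `K` of out-of-batch subjects is drawn from the bank
#' (without replacement); anchors are the uncensored subjects among the
#' batch and the drawn bank members, and each anchor's risk set is the
#' eligible (time >= anchor time) members of that pool — batch subjects with
#' their current scores, bank subjects with their stored ones. With `K = 1`
#' and the batch equal to the full cohort this is exactly
#' [cox_partial_loglik()]; unlike [minibatch_cox_loglik()], an all-censored
#' batch still yields a finite value whenever the drawn bank members include
#' an uncensored subject.
#'
#' Sampling of the bank subset uses the session RNG; seed it for
#' reproducibility.
#'
#' @param bank a `"memory_bank"` initialised for all subjects that can be
#'   drawn.
#' @param batch_indices subject indices in the current minibatch.
#' @param batch_scores current model scores for the batch subjects.
#' @param K override of the bank's stored fraction.
#' @return objective value, or a `"cox_skip"` signal if the augmented pool
#'   contains no uncensored subject.
#' @export
coxmb_loglik <- function(bank, batch_indices, batch_scores, K = bank$K) {
  if (!inherits(bank, "memory_bank")) stop_usage("expected a `memory_bank`")
  if (length(batch_indices) != length(batch_scores))
    stop_usage("`batch_indices` and `batch_scores` lengths differ")
  n <- length(bank$scores)
  scores <- bank$scores
  scores[batch_indices] <- batch_scores
  nonbatch <- setdiff(seq_len(n), batch_indices)
  n_draw <- round(K * length(nonbatch))
  drawn <- if (n_draw >= length(nonbatch)) nonbatch
           else sort(sample(nonbatch, n_draw))
  if (any(is.na(scores[drawn])))
    stop_usage("memory bank has uninitialised slots among the drawn members; ",
               "update the bank before use")
  pool <- c(batch_indices, drawn)
  anchors <- pool[bank$status[pool] == 1L]
  if (length(anchors) == 0L)
    return(structure(list(reason = "no uncensored subjects in batch or drawn bank members"),
                     class = "cox_skip"))
  tm <- bank$time
  terms <- vapply(anchors, function(a) {
    members <- pool[tm[pool] >= tm[a]]
    scores[a] - logsumexp(scores[members])
  }, numeric(1))
  mean(terms)
}

#' DeepHit ranking loss
#'
#' Pairwise penalty that rewards a model for assigning, at each observed
#' death time `t_i`, a larger cumulative death probability to the subject
#' who actually died earlier:
#' \deqn{\sum_{(i,j)} \exp\{-(F_i(t_i) - F_j(t_i))/s\},}
#' over admissible pairs with `i` uncensored and `t_i < t_j` (a censored
#' `t_i` is only a lower bound, so the ordering would be unverifiable; tied
#' times are excluded). The sharpness hyperparameter `s` defaults to 0.1.
#'
#' @param cdf numeric matrix, `cdf[n, t]` = F(t | x_n), one row per subject
#'   (see [event_cdf()]).
#' @param time integer observed months.
#' @param status 0/1 event indicators.
#' @param s sharpness hyperparameter (months of CDF difference scale).
#' @param aggregate `"sum"` over pairs (default) or `"mean"`.
#' @return the loss; 0 with a warning if no admissible pair exists.
#' @export
deephit_rank_loss <- function(cdf, time, status, s = 0.1,
                              aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  cdf <- as.matrix(cdf)
  n <- nrow(cdf)
  if (length(time) != n || length(status) != n)
    stop_usage("`cdf` rows, `time` and `status` must agree")
  total <- 0
  n_pairs <- 0L
  for (i in which(status == 1)) {
    js <- which(time > time[i])
    if (!length(js)) next
    total <- total + sum(exp(-(cdf[i, time[i]] - cdf[js, time[i]]) / s))
    n_pairs <- n_pairs + length(js)
  }
  if (n_pairs == 0L) {
    warning("no admissible (uncensored i, t_i < t_j) pairs; ranking loss is 0")
    return(0)
  }
  if (aggregate == "mean") total / n_pairs else total
}

#' DeepHit total loss
#'
#' The negated classical censoring training objective plus `rank_weight`
#' times the ranking loss. `rank_weight = 0` gives the likelihood-only
#' ablation.
#'
#' @param cohort a `"survival_cohort"`.
#' @param dists list of per-subject `"discrete_event_dist"`.
#' @param rank_weight multiplier on the ranking term (0 disables it).
#' @param s ranking sharpness, see [deephit_rank_loss()].
#' @return the loss (to be minimised).
#' @export
deephit_total_loss <- function(cohort, dists, rank_weight = 1, s = 0.1) {
  check_cohort(cohort)
  lik <- -dataset_loglik(cohort, dists, model = "classical", constants = "omit")$total
  if (rank_weight == 0) return(lik)
  cdf <- do.call(rbind, lapply(dists, function(d) cumsum(d$pmf)))
  # deephit_rank_loss warns and returns 0 when no pair is admissible
  rnk <- deephit_rank_loss(cdf, cohort$time, cohort$status, s = s)
  lik + rank_weight * rnk
}

#' Predict death times from Cox risk scores
#'
#' A fitted Cox model ranks subjects but does not emit a death time; the
#' standard route to one is the Breslow estimator of the cumulative baseline
#' hazard from the training records,
#' `H0(t) = sum_{event months s <= t} d_s / sum_{m: time_m >= s} exp(g_m)`,
#' giving per-subject survival curves `S(t | g) = exp(-H0(t) e^g)`. The
#' default prediction is the median crossing — the first grid month with
#' `S(t) <= 0.5`, or `t_max` if the curve never crosses; `"mean"` returns
#' the restricted mean survival time `sum_{t=0}^{t_max - 1} S(t)`.
#'
#' @param train_scores risk scores of the training subjects.
#' @param train_time training observed months.
#' @param train_status training 0/1 indicators.
#' @param t_max grid horizon.
#' @param new_scores risk score(s) of the subject(s) to predict; vectorised.
#' @param method `"median"` (default) or `"mean"`.
#' @return predicted month(s), same length as `new_scores`.
#' @export
cox_predict_time <- function(train_scores, train_time, train_status, t_max,
                             new_scores, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!any(train_status == 1))
    stop_usage("Breslow baseline is undefined without uncensored training subjects")
  event_months <- sort(unique(train_time[train_status == 1]))
  increments <- vapply(event_months, function(s) {
    d_s <- sum(train_time == s & train_status == 1)
    d_s / sum(exp(train_scores[train_time >= s]))
  }, numeric(1))
  # cumulative baseline hazard on the full grid 1..t_max
  H0 <- cumsum(vapply(seq_len(t_max), function(t)
    sum(increments[event_months == t]), numeric(1)))
  vapply(new_scores, function(g) {
    S <- exp(-H0 * exp(g))
    if (method == "median") {
      hit <- which(S <= 0.5)
      if (length(hit)) as.numeric(hit[1]) else as.numeric(t_max)
    } else {
      1 + sum(S[seq_len(t_max - 1)]) # sum_{t=0}^{t_max-1} S(t), S(0) = 1
    }
  }, numeric(1))
}
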