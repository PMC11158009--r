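# Maximum-likelihood fitting.
#
# Event models: mu(x) = intercept + weights . x feeding a discretised
# Gaussian with shared sigma (fixed by default; learnable through a log
# reparameterisation that keeps it positive). The dataset log-likelihood
# under either censoring model is smooth in the parameters, with the clean
# gradient structure of an exponential-family mixture:
#
#   d/dmu log sum_t w_t p(t | mu)  =  (E_w[T] - E_p[T]) / sigma^2
#
# where E_p is the mean of the event distribution and E_w the mean under the
# w-reweighted, renormalised distribution (w_t = indicator of the observed
# death month for uncensored terms; 1/(t-1) above the censoring time for
# the event-conditional censored term; the plain indicator t > c for the
# classical one).
#
# Optimisation is deterministic monotone gradient ascent with a
# backtracking/doubling step: an accepted iterate never lowers the
# objective, so the recorded trace is non-decreasing. Convergence is
# declared when the objective improves by less than `tol` for `patience`
# successive iterates.

default_fit_control <- function(control = list()) {
  out <- list(max_iter = 2000L, tol = 1e-7, patience = 5L, step0 = 1)
  out[names(control)] <- control
  out
}

# Monotone backtracking gradient ascent. fn/gr take the parameter vector;
# fn must be finite at `par`.
ascend <- function(par, fn, gr, control) {
  f <- fn(par)
  if (!is.finite(f))
    stop_usage("objective is not finite at the initial parameters (",
               paste(format(par), collapse = ", "), ")")
  trace <- f
  step <- control$step0
  stable <- 0L
  n_iter <- 0L
  for (it in seq_len(control$max_iter)) {
    g <- gr(par)
    repeat {
      cand <- par + step * g
      fc <- fn(cand)
      if (is.finite(fc) && fc >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-14) { cand <- par; fc <- f; break }
    }
    improve <- fc - f
    par <- cand
    f <- fc
    trace <- c(trace, f)
    n_iter <- it
    step <- step * 2
    stable <- if (improve < control$tol) stable + 1L else 0L
    if (stable >= control$patience) break
  }
  list(par = par, value = f, trace = trace,
       converged = stable >= control$patience, n_iter = n_iter)
}

# Mean log-likelihood of the cohort and its gradient, as closures over the
# design matrix. Parameter vector: (intercept, weights..., [log sigma]).
event_objective <- function(cohort, likelihood, sigma, learn_sigma) {
  X <- cohort$covariates
  n <- n_subjects(cohort)
  d <- ncol(X)
  t_max <- cohort$t_max
  times <- seq_len(t_max)
  status <- cohort$status
  obs_time <- cohort$time

  # per-subject log-weight matrix of the observation terms (fixed by data)
  logW <- matrix(-Inf, n, t_max)
  for (i in seq_len(n)) {
    if (status[i] == 1L) {
      logW[i, obs_time[i]] <- 0
    } else if (obs_time[i] < t_max) {
      tt <- (obs_time[i] + 1L):t_max
      logW[i, tt] <- if (likelihood == "centime") -log(tt - 1) else 0
    } # else: no admissible death month; the row stays -Inf (zero probability)
  }

  unpack <- function(par) {
    list(mu = rep(par[1], n) + if (d > 0) drop(X %*% par[2:(1 + d)]) else 0,
         sigma = if (learn_sigma) exp(par[length(par)]) else sigma)
  }

  pieces <- function(par) {
    p <- unpack(par)
    M <- -(outer(p$mu, times, "-")^2) / (2 * p$sigma^2) # n x t_max
    rmax <- apply(M, 1, max)
    logZ <- rmax + log(rowSums(exp(M - rmax)))
    A <- M + logW
    amax <- apply(A, 1, max)
    logS <- amax + log(rowSums(exp(A - amax)))
    list(p = p, M = M, logZ = logZ, A = A, logS = logS)
  }

  fn <- function(par) {
    z <- pieces(par)
    mean(z$logS - z$logZ)
  }

  gr <- function(par) {
    z <- pieces(par)
    sig <- z$p$sigma
    P <- exp(z$M - z$logZ)    # event pmf rows
    Q <- exp(z$A - z$logS)    # reweighted rows
    Q[!is.finite(Q)] <- 0
    e_p <- drop(P %*% times)
    e_q <- drop(Q %*% times)
    g_mu <- (e_q - e_p) / sig^2
    g <- numeric(length(par))
    g[1] <- mean(g_mu)
    if (d > 0) g[2:(1 + d)] <- drop(crossprod(X, g_mu)) / n
    if (learn_sigma) {
      dev2 <- outer(z$p$mu, times, "-")^2
      v_p <- rowSums(P * dev2)
      v_q <- rowSums(Q * dev2)
      # d/d log sigma = sigma * d/d sigma
      g[length(par)] <- mean((v_q - v_p) / sig^2)
    }
    g
  }

  list(fn = fn, gr = gr, unpack = unpack)
}

#' Fit a covariate-conditioned event-time model by maximum likelihood
#'
#' Maximises the cohort log-likelihood under the event-conditional
#' (`"centime"`) or classical censoring model over the parameters of a
#' linear location model `mu(x) = intercept + weights . x` with a
#' discretised-Gaussian event distribution. `sigma` is fixed (default 12
#' months, which stabilises fitting) unless `learn_sigma = TRUE`, in which
#' case it is optimised through a log reparameterisation.
#'
#' The event-conditional likelihood is a consistent objective for the event
#' model even when every record is censored; the classical likelihood is
#' fittable on purely censored data too, but is then degenerate — its
#' optimum pushes the event distribution beyond the observed censoring
#' times, inflating the fitted intercept.
#'
#' Optimisation is deterministic monotone gradient ascent from a fixed
#' initialisation (intercept at the grid midpoint, weights zero), so
#' repeated fits are identical.
#'
#' @param cohort a `"survival_cohort"`.
#' @param likelihood `"centime"` or `"classical"`.
#' @param sigma positive scale in months, fixed unless `learn_sigma`.
#' @param learn_sigma logical; optimise sigma as well.
#' @param init optional named list with `intercept`, `weights`, `sigma`
#'   overriding the default initialisation.
#' @param control optional list overriding `max_iter` (2000), `tol` (1e-7),
#'   `patience` (5) and the initial `step0` (1).
#' @return an object of class `"event_model_fit"`: intercept, weights,
#'   sigma, likelihood, `loglik` (mean per observation), `loglik_total`,
#'   `trace` (non-decreasing objective values), `converged`, `n_iter`,
#'   `t_max`, `init`.
#' @examples
#' cfg <- generator_config(200, t_max = 60, covariate_dim = 1,
#'                         true_weights = 5, sigma = 12,
#'                         mechanism = "fixed_proportion",
#'                         censored_fraction = 0.5, seed = 7)
#' fit <- fit_event_model(sample_cohort(cfg), "centime", sigma = 12)
#' coef(fit)
#' @export
fit_event_model <- function(cohort, likelihood = c("centime", "classical"),
                            sigma = 12, learn_sigma = FALSE, init = NULL,
                            control = list()) {
  check_cohort(cohort)
  likelihood <- match.arg(likelihood)
  if (likelihood == "centime") validate_cohort(cohort, "centime")
  control <- default_fit_control(control)
  d <- ncol(cohort$covariates)
  init_intercept <- if (!is.null(init$intercept)) init$intercept else (cohort$t_max + 1) / 2
  init_weights <- if (!is.null(init$weights)) init$weights else rep(0, d)
  init_sigma <- if (!is.null(init$sigma)) init$sigma else sigma
  par <- c(init_intercept, init_weights, if (learn_sigma) log(init_sigma))
  obj <- event_objective(cohort, likelihood, sigma, learn_sigma)
  res <- ascend(par, obj$fn, obj$gr, control)
  p <- obj$unpack(res$par)
  structure(list(intercept = res$par[1],
                 weights = if (d > 0) stats::setNames(res$par[2:(1 + d)],
                                                      colnames(cohort$covariates))
                           else numeric(0),
                 sigma = p$sigma, learn_sigma = learn_sigma,
                 likelihood = likelihood, t_max = cohort$t_max,
                 loglik = res$value, loglik_total = res$value * n_subjects(cohort),
                 trace = res$trace, converged = res$converged,
                 n_iter = res$n_iter,
                 init = list(intercept = init_intercept, weights = init_weights,
                             sigma = init_sigma)),
            class = "event_model_fit")
}

#' @export
print.event_model_fit <- function(x, ...) {
  cat("<event_model_fit> likelihood = ", x$likelihood,
      ", sigma = ", format(x$sigma),
      if (x$learn_sigma) " (learned)" else " (fixed)",
      ", t_max = ", x$t_max, "\n", sep = "")
  cat("  intercept: ", format(x$intercept), "\n", sep = "")
  if (length(x$weights))
    cat("  weights:   ", paste(format(x$weights), collapse = ", "), "\n", sep = "")
  cat("  mean loglik: ", format(x$loglik),
      "  (", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

#' @export
coef.event_model_fit <- function(object, ...) {
  c(intercept = object$intercept, object$weights)
}

#' Per-subject event-time distributions of a fitted event model
#'
#' @param fit an `"event_model_fit"`.
#' @param newdata covariate matrix (or a `"survival_cohort"`, whose
#'   covariates are used).
#' @return list of `"discrete_event_dist"`, one per row.
#' @export
predict_distributions <- function(fit, newdata) {
  if (inherits(newdata, "survival_cohort")) newdata <- newdata$covariates
  newdata <- as.matrix(newdata)
  mu <- drop(fit$intercept + if (length(fit$weights))
    newdata %*% fit$weights else rep(0, nrow(newdata)))
  grid <- time_grid(fit$t_max)
  lapply(mu, discrete_gaussian, sigma = fit$sigma, grid = grid)
}

#' Predicted death times of a fitted event model
#'
#' @inheritParams predict_distributions
#' @param method point-estimate rule, see [point_estimate()].
#' @param ... unused.
#' @param object an `"event_model_fit"`.
#' @return numeric vector of predicted months.
#' @export
predict.event_model_fit <- function(object, newdata, method = "mean", ...) {
  vapply(predict_distributions(object, newdata), point_estimate,
         numeric(1), method = method)
}

# ---------------------------------------------------------------------------
# Risk models (Cox objectives) with a linear score g(x) = beta . x.

cox_grad <- function(beta, X, time, status) {
  scores <- drop(X %*% beta)
  unc <- which(status == 1)
  g <- numeric(length(beta))
  for (a in unc) {
    members <- which(time >= time[a])
    w <- exp(scores[members] - logsumexp(scores[members]))
    g <- g + X[a, ] - drop(crossprod(X[members, , drop = FALSE], w))
  }
  g / length(unc)
}

#' Fit a linear Cox risk model
#'
#' Maximises a Cox partial-likelihood objective over a linear risk score
#' `g(x) = beta . x`. `objective = "cox"` is deterministic full-batch ascent
#' on [cox_partial_loglik()]. `"cox_minibatch"` runs seeded stochastic
#' gradient ascent over within-batch objectives, honouring the skip signal
#' of [minibatch_cox_loglik()] for all-censored batches (when the batch is
#' the whole cohort this reduces to the full-batch path). `"coxmb"`
#' additionally maintains a [memory_bank()] so batch gradients use enlarged
#' risk sets and all-censored batches still contribute.
#'
#' A cohort with no uncensored subject is untrainable under every Cox
#' objective — the partial likelihood has no terms — and is rejected.
#'
#' @param cohort a `"survival_cohort"` with at least one covariate column.
#' @param objective `"cox"`, `"cox_minibatch"` or `"coxmb"`.
#' @param batch_size minibatch size for the stochastic objectives.
#' @param epochs maximum epochs for the stochastic objectives.
#' @param learning_rate SGD step size.
#' @param K memory-bank fraction for `"coxmb"`.
#' @param seed RNG seed for batch shuffling and bank sampling.
#' @param control optional ascent control, as in [fit_event_model()].
#' @return an object of class `"risk_model_fit"`: `beta`, `objective`,
#'   `loglik` (full-cohort partial log-likelihood of the fit), `trace`,
#'   `converged`, `n_iter`, plus the training `scores`, `time`, `status`,
#'   `t_max` needed for Breslow time prediction.
#' @export
fit_risk_model <- function(cohort, objective = c("cox", "cox_minibatch", "coxmb"),
                           batch_size = 32L, epochs = 200L, learning_rate = 0.5,
                           K = 1, seed = 1L, control = list()) {
  check_cohort(cohort)
  objective <- match.arg(objective)
  if (!any(cohort$status == 1))
    stop_usage("Cox objectives are untrainable on a cohort with no uncensored ",
               "subjects: the partial likelihood has no terms")
  X <- cohort$covariates
  if (ncol(X) == 0)
    stop_usage("a Cox risk model needs at least one covariate")
  time <- cohort$time
  status <- cohort$status
  n <- n_subjects(cohort)
  control <- default_fit_control(control)
  full_fn <- function(beta) cox_partial_loglik(drop(X %*% beta), time, status)
  full_gr <- function(beta) cox_grad(beta, X, time, status)
  beta0 <- rep(0, ncol(X))

  if (objective == "cox" || batch_size >= n) {
    res <- ascend(beta0, full_fn, full_gr, control)
    beta <- res$par; trace <- res$trace
    converged <- res$converged; n_iter <- res$n_iter
  } else {
    set.seed(seed)
    beta <- beta0
    trace <- full_fn(beta)
    bank <- if (objective == "coxmb") {
      b <- memory_bank(time, status, K = K)
      memory_bank_update(b, seq_len(n), drop(X %*% beta))
    }
    stable <- 0L; n_iter <- 0L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / batch_size))
      for (b_idx in batches) {
        scores_b <- drop(X[b_idx, , drop = FALSE] %*% beta)
        if (objective == "cox_minibatch") {
          if (is_skip_signal(minibatch_cox_loglik(scores_b, time[b_idx], status[b_idx])))
            next
          g <- cox_grad(beta, X[b_idx, , drop = FALSE], time[b_idx], status[b_idx])
        } else {
          g <- coxmb_grad(beta, X, time, status, b_idx, bank, K)
          bank <- memory_bank_update(bank, b_idx, scores_b)
          if (is.null(g)) next
        }
        beta <- beta + learning_rate / (1 + 0.05 * ep) * g
      }
      f <- full_fn(beta)
      stable <- if (abs(f - trace[length(trace)]) < control$tol) stable + 1L else 0L
      trace <- c(trace, f)
      n_iter <- ep
      if (stable >= control$patience) break
    }
    converged <- stable >= control$patience
  }

  scores <- drop(X %*% beta)
  structure(list(beta = stats::setNames(beta, colnames(X)),
                 objective = objective,
                 loglik = cox_partial_loglik(scores, time, status),
                 trace = trace, converged = converged, n_iter = n_iter,
                 scores = scores, time = time, status = status,
                 t_max = cohort$t_max, seed = seed),
            class = "risk_model_fit")
}

# Gradient of the CoxMB objective w.r.t. beta: bank scores are constants,
# so only batch members carry covariate terms. Returns NULL when the pool
# has no uncensored anchor.
coxmb_grad <- function(beta, X, time, status, batch_idx, bank, K) {
  n <- length(time)
  scores <- bank$scores
  scores[batch_idx] <- drop(X[batch_idx, , drop = FALSE] %*% beta)
  nonbatch <- setdiff(seq_len(n), batch_idx)
  n_draw <- round(K * length(nonbatch))
  drawn <- if (n_draw >= length(nonbatch)) nonbatch
           else sort(sample(nonbatch, n_draw))
  pool <- c(batch_idx, drawn)
  anchors <- pool[status[pool] == 1L]
  if (!length(anchors)) return(NULL)
  in_batch <- logical(n)
  in_batch[batch_idx] <- TRUE
  g <- numeric(ncol(X))
  for (a in anchors) {
    members <- pool[time[pool] >= time[a]]
    w <- exp(scores[members] - logsumexp(scores[members]))
    mb <- members[in_batch[members]]
    if (in_batch[a]) g <- g + X[a, ]
    if (length(mb))
      g <- g - drop(crossprod(X[mb, , drop = FALSE], w[in_batch[members]]))
  }
  g / length(anchors)
}

#' @export
print.risk_model_fit <- function(x, ...) {
  cat("<risk_model_fit> objective = ", x$objective, "\n", sep = "")
  cat("  beta: ", paste(format(x$beta), collapse = ", "), "\n", sep = "")
  cat("  partial loglik: ", format(x$loglik),
      "  (", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

#' @export
coef.risk_model_fit <- function(object, ...) object$beta

#' Risk scores of a fitted Cox model
#'
#' @param object a `"risk_model_fit"`.
#' @param newdata covariate matrix or `"survival_cohort"`.
#' @param type `"risk"` for scores `beta . x`; `"time"` for Breslow
#'   median-crossing death times (see [cox_predict_time()]).
#' @param ... unused.
#' @export
predict.risk_model_fit <- function(object, newdata, type = c("risk", "time"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "survival_cohort")) newdata <- newdata$covariates
  scores <- drop(as.matrix(newdata) %*% object$beta)
  if (type == "risk") return(scores)
  cox_predict_time(object$scores, object$time, object$status, object$t_max, scores)
}

#' Evaluate a fitted model on a cohort
#'
#' Computes the concordance index, MAE and RAE of a fitted model on a
#' cohort. Event models are evaluated through their per-subject predicted
#' death times (`direction = "time"`); risk models through their scores for
#' the concordance index (`direction = "risk"`) and through Breslow
#' median-crossing times for MAE/RAE.
#'
#' @param fit an `"event_model_fit"` or `"risk_model_fit"`.
#' @param cohort evaluation `"survival_cohort"`.
#' @param point_method point-estimate rule for event models.
#' @return a `"metrics_report"`.
#' @export
predict_and_evaluate <- function(fit, cohort, point_method = "mean") {
  check_cohort(cohort)
  if (inherits(fit, "event_model_fit")) {
    t_hat <- predict(fit, cohort, method = point_method)
    ci <- concordance_index(t_hat, cohort$time, cohort$status, direction = "time")
  } else if (inherits(fit, "risk_model_fit")) {
    scores <- predict(fit, cohort, type = "risk")
    ci <- concordance_index(scores, cohort$time, cohort$status, direction = "risk")
    t_hat <- predict(fit, cohort, type = "time")
  } else {
    stop_usage("`fit` must be an event_model_fit or risk_model_fit")
  }
  new_metrics_report(as.numeric(ci),
                     mae(t_hat, cohort$time, cohort$status),
                     rae(t_hat, cohort$time, cohort$status),
                     sum(cohort$status == 1),
                     attr(ci, "n_pairs"))
}
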