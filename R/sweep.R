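# Censoring-sweep experiment: how each estimator degrades as the share of
# uncensored training records shrinks to zero.
#
# For each seeded replicate a training cohort is generated under the
# event-conditional mechanism and a fully uncensored test cohort from the
# same true model. At each uncensored fraction f, all censored training
# records are kept, a random f-fraction of the uncensored ones is added,
# each estimator is fitted on the result, and metrics are computed on the
# held-out test set. Cox objectives have no terms without uncensored
# records, so their rows at f = 0 are recorded as untrainable rather than
# skipped silently.

#' Subset a cohort by subject indices
#'
#' @param cohort a `"survival_cohort"`.
#' @param idx integer subject indices to keep.
#' @return a `"survival_cohort"`.
#' @export
subset_cohort <- function(cohort, idx) {
  check_cohort(cohort)
  survival_cohort(cohort$covariates[idx, , drop = FALSE],
                  cohort$status[idx], cohort$time[idx], cohort$t_max)
}

#' Censoring-sweep experiment
#'
#' Fits each method on training sets containing all censored records plus a
#' growing fraction of the uncensored ones, and evaluates on a held-out
#' uncensored test cohort; repeated over seeded replicates.
#'
#' @param n_train,n_test training / test cohort sizes.
#' @param fractions uncensored fractions to sweep (default 0 to 1 in steps
#'   of 0.2; 0 means purely censored training data).
#' @param methods subset of `"centime"`, `"classical"`, `"cox"`.
#' @param n_replicates number of seeded replicates.
#' @param t_max,covariate_dim,intercept,true_weights,sigma,censoring_prob
#'   generator settings, see [generator_config()].
#' @param seed base seed; replicate r uses `seed + r` for training data and
#'   a disjoint stream for test data and subsampling.
#' @return an object of class `"censoring_sweep"`: list with `replicates`
#'   (one row per replicate x fraction x method, with `c_index`, `mae`,
#'   `rae` and a `trainable` flag; metrics are `NA` on untrainable rows)
#'   and `summary` (long table: fraction, method, metric, mean, sd,
#'   n_replicates, aggregated over trainable replicates).
#' @export
censoring_sweep_experiment <- function(n_train = 600, n_test = 300,
                                       fractions = seq(0, 1, by = 0.2),
                                       methods = c("centime", "classical", "cox"),
                                       n_replicates = 10,
                                       t_max = 60, covariate_dim = 2,
                                       intercept = (t_max + 1) / 2,
                                       true_weights = rep(5, covariate_dim),
                                       sigma = 12, censoring_prob = 0.65,
                                       seed = 1L) {
  methods <- match.arg(methods, c("centime", "classical", "cox"), several.ok = TRUE)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    train_cfg <- generator_config(n_train, t_max = t_max,
                                  covariate_dim = covariate_dim,
                                  intercept = intercept, true_weights = true_weights,
                                  sigma = sigma, mechanism = "event_conditional",
                                  censoring_prob = censoring_prob, seed = seed + r)
    test_cfg <- generator_config(n_test, t_max = t_max,
                                 covariate_dim = covariate_dim,
                                 intercept = intercept, true_weights = true_weights,
                                 sigma = sigma, mechanism = "event_conditional",
                                 censoring_prob = 0, seed = seed + r + 90000L)
    train <- sample_event_conditional(train_cfg)
    test <- sample_event_conditional(test_cfg)
    unc <- uncensored_index(train)
    cens <- censored_index(train)
    for (f in fractions) {
      set.seed(seed + r + 180000L + round(1000 * f))
      n_keep <- round(f * length(unc))
      keep_unc <- if (n_keep > 0) sort(sample(unc, n_keep)) else integer(0)
      sub <- subset_cohort(train, sort(c(cens, keep_unc)))
      for (m in methods) {
        row <- data.frame(replicate = r, fraction = f, method = m,
                          c_index = NA_real_, mae = NA_real_, rae = NA_real_,
                          trainable = TRUE)
        if (m == "cox" && !any(sub$status == 1)) {
          row$trainable <- FALSE
        } else {
          fit <- switch(m,
                        centime = fit_event_model(sub, "centime", sigma = sigma),
                        classical = fit_event_model(sub, "classical", sigma = sigma),
                        cox = fit_risk_model(sub, "cox", seed = seed + r))
          rep_metrics <- predict_and_evaluate(fit, test)
          row$c_index <- rep_metrics$c_index
          row$mae <- rep_metrics$mae
          row$rae <- rep_metrics$rae
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- sweep_summary(replicates)
  structure(list(replicates = replicates, summary = summary,
                 fractions = fractions, methods = methods,
                 n_replicates = n_replicates, seed = seed),
            class = "censoring_sweep")
}

sweep_summary <- function(replicates) {
  long <- do.call(rbind, lapply(c("c_index", "mae", "rae"), function(metric) {
    agg <- stats::aggregate(replicates[[metric]],
                            by = list(fraction = replicates$fraction,
                                      method = replicates$method),
                            FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                                sd = stats::sd(v, na.rm = TRUE),
                                                n = sum(!is.na(v))))
    data.frame(fraction = agg$fraction, method = agg$method, metric = metric,
               mean = agg$x[, "mean"], sd = agg$x[, "sd"],
               n_replicates = agg$x[, "n"])
  }))
  rownames(long) <- NULL
  long
}

#' @export
print.censoring_sweep <- function(x, ...) {
  cat("<censoring_sweep> ", x$n_replicates, " replicates, fractions ",
      paste(x$fractions, collapse = ", "), "\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}
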