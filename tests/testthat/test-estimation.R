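test_that("intercept-only MLE recovers the true location from uncensored data", {
  mu_true <- 22
  cfg <- generator_config(1500, t_max = 60, covariate_dim = 0,
                          intercept = mu_true, sigma = 12,
                          censoring_prob = 0, seed = 51)
  co <- sample_event_conditional(cfg)
  fit <- fit_event_model(co, "centime", sigma = 12)
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept - mu_true), 3 * 12 / sqrt(1500))
})

test_that("the objective trace is monotone and the fit is reproducible", {
  cfg <- generator_config(300, t_max = 60, covariate_dim = 2,
                          true_weights = c(5, -5), sigma = 12,
                          mechanism = "fixed_proportion",
                          censored_fraction = 0.6, seed = 52)
  co <- sample_cohort(cfg)
  fit <- fit_event_model(co, "centime", sigma = 12)
  expect_true(all(diff(fit$trace) > -1e-8))
  expect_equal(fit$trace[length(fit$trace)], fit$loglik)
  fit2 <- fit_event_model(co, "centime", sigma = 12)
  expect_identical(coef(fit), coef(fit2))
  # stated deterministic initialisation is recorded
  expect_equal(fit$init$intercept, (60 + 1) / 2)
  expect_equal(fit$init$weights, c(0, 0))
})

test_that("CenTime fitting rejects censored times at the horizon", {
  co <- survival_cohort(matrix(rnorm(4), 4, 1), status = c(1, 0, 1, 0),
                        time = c(5, 20, 8, 11), t_max = 20)
  expect_error(fit_event_model(co, "centime"), "raise `t_max`")
  # classical assigns such a record probability zero: non-finite at init
  expect_error(fit_event_model(co, "classical"), "not finite")
})

test_that("learned sigma stays positive and lands near the truth on clean data", {
  cfg <- generator_config(1500, t_max = 80, covariate_dim = 0, intercept = 40,
                          sigma = 9, censoring_prob = 0, seed = 53)
  co <- sample_event_conditional(cfg)
  fit <- fit_event_model(co, "centime", sigma = 4, learn_sigma = TRUE)
  expect_gt(fit$sigma, 0)
  expect_lt(abs(fit$sigma - 9), 1)
})

test_that("classical likelihood is degenerate on purely censored data", {
  cfg <- generator_config(400, t_max = 60, covariate_dim = 2,
                          intercept = 30, true_weights = c(5, -5), sigma = 12,
                          mechanism = "fixed_proportion",
                          censored_fraction = 1, seed = 54)
  co <- sample_cohort(cfg)
  cen <- fit_event_model(co, "centime", sigma = 12)
  cla <- fit_event_model(co, "classical", sigma = 12)
  expect_lt(abs(cen$intercept - 30), 5)
  expect_gt(cla$intercept - 30, 5) # drifts toward and past the horizon
})

test_that("the matched likelihood wins: truth scores higher than the classical fit", {
  # on event-conditional censored records, the CenTime log-likelihood at the
  # true parameters should beat its value at the classical fit's parameters
  diffs <- vapply(1:5, function(r) {
    cfg <- generator_config(400, t_max = 60, covariate_dim = 1,
                            intercept = 30, true_weights = 5, sigma = 12,
                            mechanism = "fixed_proportion",
                            censored_fraction = 1, seed = 60 + r)
    co <- sample_cohort(cfg)
    grid <- time_grid(60)
    at <- function(b0, w) {
      mu <- b0 + drop(co$covariates %*% w)
      dists <- lapply(mu, discrete_gaussian, sigma = 12, grid = grid)
      dataset_loglik(co, dists, "centime")$mean
    }
    cla <- fit_event_model(co, "classical", sigma = 12)
    at(30, 5) - at(cla$intercept, cla$weights)
  }, numeric(1))
  expect_gt(median(diffs), 0)
})

test_that("linear Cox fit separates a two-group cohort and recovers signs", {
  # group A (x = 1) always dies before group B (x = 0)
  x <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1)
  tm <- c(sample(1:10), sample(21:30))
  co <- survival_cohort(x, status = rep(1, 20), time = tm, t_max = 40)
  fit <- fit_risk_model(co, "cox")
  expect_gt(coef(fit)[1], 0)
  rep_metrics <- predict_and_evaluate(fit, co)
  # all 100 cross-group pairs concordant; the 90 within-group pairs are
  # prediction ties at half credit, capping the index at 145/190
  expect_equal(rep_metrics$c_index, 145 / 190)

  # fully ordered continuous covariate: training concordance reaches 1
  xo <- matrix(seq(-1, 1, length.out = 12), ncol = 1)
  coo <- survival_cohort(xo, status = rep(1, 12), time = 5 * (12:1), t_max = 60)
  fito <- fit_risk_model(coo, "cox")
  expect_equal(predict_and_evaluate(fito, coo)$c_index, 1)

  # proportional-hazards-compatible truth: earlier deaths for larger x
  cfg <- generator_config(300, t_max = 60, covariate_dim = 2,
                          intercept = 30, true_weights = c(-8, 8), sigma = 12,
                          mechanism = "classical", seed = 55)
  co2 <- sample_classical(cfg)
  fit2 <- fit_risk_model(co2, "cox")
  expect_gt(coef(fit2)[1], 0) # x1 lowers mu(x): higher risk
  expect_lt(coef(fit2)[2], 0)
  expect_gt(abs(coef(fit2)[1]), abs(coef(fit2)[2]) / 3)
})

test_that("Cox fits agree with the survival package on coefficients", {
  skip_if_not_installed("survival")
  cfg <- generator_config(250, t_max = 60, covariate_dim = 2,
                          intercept = 30, true_weights = c(-6, 4), sigma = 12,
                          mechanism = "classical", seed = 56)
  co <- sample_classical(cfg)
  fit <- fit_risk_model(co, "cox", control = list(tol = 1e-9))
  ref <- survival::coxph(survival::Surv(co$time, co$status) ~ co$covariates,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-3)
})

test_that("minibatch and memory-bank objectives train to the full-batch optimum", {
  cfg <- generator_config(120, t_max = 60, covariate_dim = 2,
                          intercept = 30, true_weights = c(-8, 8), sigma = 12,
                          mechanism = "classical", seed = 57)
  co <- sample_classical(cfg)
  full <- fit_risk_model(co, "cox")
  # batch covering the cohort: identical objective, same optimum
  mb_full <- fit_risk_model(co, "cox_minibatch", batch_size = 200)
  expect_lt(abs(mb_full$loglik - full$loglik), 1e-4)
  # genuine minibatches land close in objective value
  mb <- fit_risk_model(co, "cox_minibatch", batch_size = 20, epochs = 120,
                       learning_rate = 0.4, seed = 58)
  expect_lt(full$loglik - mb$loglik, 0.03)
  mbk <- fit_risk_model(co, "coxmb", batch_size = 20, epochs = 120,
                        learning_rate = 0.4, K = 1, seed = 58)
  expect_lt(full$loglik - mbk$loglik, 0.03)
})

test_that("Cox objectives refuse cohorts with no uncensored subjects", {
  co <- survival_cohort(matrix(rnorm(6), 6, 1), status = rep(0, 6),
                        time = rep(10, 6), t_max = 30)
  expect_error(fit_risk_model(co, "cox"), "untrainable")
  expect_error(fit_risk_model(co, "coxmb"), "untrainable")
})

test_that("evaluation is a pure function with the expected degenerate values", {
  cfg <- generator_config(150, t_max = 60, covariate_dim = 2,
                          true_weights = c(5, -5), sigma = 12,
                          censoring_prob = 0.3, seed = 59)
  co <- sample_event_conditional(cfg)
  fit <- fit_event_model(co, "centime", sigma = 12)
  a <- predict_and_evaluate(fit, co)
  b <- predict_and_evaluate(fit, co)
  expect_identical(a, b)
  expect_true(a$c_index >= 0 && a$c_index <= 1)
  expect_gte(a$mae, 0)

  # a constant predictor ties every pair: C-index exactly one half
  flat <- fit
  flat$weights[] <- 0
  expect_equal(predict_and_evaluate(flat, co)$c_index, 0.5)
})

test_that("censoring sweep marks Cox untrainable at 0% and fills the grid", {
  sw <- censoring_sweep_experiment(n_train = 150, n_test = 120,
                                   fractions = c(0, 1),
                                   methods = c("centime", "cox"),
                                   n_replicates = 2, t_max = 60,
                                   covariate_dim = 2, true_weights = c(5, -5),
                                   sigma = 12, seed = 61)
  reps <- sw$replicates
  expect_equal(nrow(reps), 2 * 2 * 2) # replicates x fractions x methods
  cox0 <- reps[reps$method == "cox" & reps$fraction == 0, ]
  expect_true(all(!cox0$trainable))
  expect_true(all(is.na(cox0$mae)))
  cen0 <- reps[reps$method == "centime" & reps$fraction == 0, ]
  expect_true(all(cen0$trainable) && all(is.finite(cen0$mae)))
  expect_equal(sort(unique(sw$summary$metric)), c("c_index", "mae", "rae"))
  expect_equal(nrow(sw$summary), 3 * 2 * 2)
})
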