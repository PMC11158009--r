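test_that("relative death risk is a softmax over the risk set", {
  expect_equal(cox_relative_risk(c(1, 1), 1, 1:2), 0.5)
  expect_equal(cox_relative_risk(c(2.3, 0.1), 1, 1), 1.0)
  expect_equal(cox_relative_risk(c(1, 0, -1), 1, 1:3),
               exp(1) / (exp(1) + 1 + exp(-1)), tolerance = 1e-12)
  expect_error(cox_relative_risk(c(1, 2), 1, integer(0)), "empty")
})

test_that("partial log-likelihood: closed form under equal scores, shift invariance", {
  # equal scores: each term is -log(risk set size)
  time <- c(2, 5, 9, 12, 20)
  status <- c(1, 0, 1, 1, 0)
  scores <- rep(0.7, 5)
  sizes <- c(5, 3, 2) # risk sets of the uncensored subjects at t = 2, 9, 12
  expect_equal(cox_partial_loglik(scores, time, status),
               mean(-log(sizes)), tolerance = 1e-12)

  # single uncensored subject alone in its risk set
  expect_equal(cox_partial_loglik(0.3, 5, 1), 0)

  # translation of all scores leaves the objective unchanged
  set.seed(31)
  s <- rnorm(20); tm <- sample.int(30, 20, TRUE); st <- rbinom(20, 1, 0.6)
  st[1] <- 1
  expect_equal(cox_partial_loglik(s, tm, st),
               cox_partial_loglik(s + 123.4, tm, st), tolerance = 1e-10)
  expect_error(cox_partial_loglik(s, tm, rep(0, 20)), "uncensored")
})

test_that("sweep evaluation equals the naive per-subject form, incl. tied times", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    tm <- sample.int(12, n, replace = TRUE) # many ties
    st <- rbinom(n, 1, 0.5); st[sample(n, 1)] <- 1
    s <- rnorm(n, sd = 2)
    expect_equal(cox_partial_loglik(s, tm, st, method = "sweep"),
                 cox_partial_loglik(s, tm, st, method = "naive"),
                 tolerance = 1e-9)
    expect_equal(cox_partial_loglik(s, tm, st, method = "naive"),
                 naive_cox_pll(s, tm, st), tolerance = 1e-12)
  }
})

test_that("partial log-likelihood agrees with the survival package at fixed beta", {
  skip_if_not_installed("survival")
  set.seed(33)
  n <- 60
  x <- matrix(rnorm(2 * n), n, 2)
  beta <- c(0.8, -0.5)
  tm <- sample.int(50, n, replace = TRUE)
  st <- rbinom(n, 1, 0.6); st[1] <- 1
  fit0 <- survival::coxph(survival::Surv(tm, st) ~ x, ties = "breslow",
                          init = beta, control = survival::coxph.control(iter.max = 0))
  ours <- cox_partial_loglik(drop(x %*% beta), tm, st) * sum(st)
  expect_equal(ours, fit0$loglik[2], tolerance = 1e-8)
})

test_that("minibatch objective skips all-censored batches and matches full batch", {
  set.seed(34)
  s <- rnorm(10); tm <- sample.int(20, 10, TRUE); st <- rbinom(10, 1, 0.5)
  st[3] <- 1
  expect_equal(minibatch_cox_loglik(s, tm, st),
               cox_partial_loglik(s, tm, st))
  skip_sig <- minibatch_cox_loglik(s, tm, rep(0, 10))
  expect_true(is_skip_signal(skip_sig))
  expect_false(is_skip_signal(0))
  expect_equal(minibatch_cox_loglik(1.2, 5, 1), 0) # lone uncensored subject
})

test_that("memory bank stores and refreshes per-subject scores", {
  b <- memory_bank(time = c(3, 7, 9, 12), status = c(1, 0, 1, 0))
  expect_true(all(is.na(b$scores)))
  b <- memory_bank_update(b, c(1, 3), c(0.5, -0.5))
  expect_equal(b$scores, c(0.5, NA, -0.5, NA))
  b <- memory_bank_update(b, c(2, 4), c(1, 2))
  expect_equal(b$scores, c(0.5, 1, -0.5, 2))
  b <- memory_bank_update(b, 1:4, 1:4 / 10)
  expect_equal(b$scores, 1:4 / 10)
  expect_error(memory_bank_update(b, 5, 1), "out of range")
})

test_that("CoxMB reduces to the full partial likelihood and rescues censored batches", {
  set.seed(35)
  n <- 25
  tm <- sample.int(30, n, TRUE); st <- rbinom(n, 1, 0.5); st[2] <- 1
  s <- rnorm(n)
  bank <- memory_bank_update(memory_bank(tm, st, K = 1), seq_len(n), rnorm(n))

  # K = 1, batch = full cohort with fresh scores: bank adds nothing new
  expect_identical(coxmb_loglik(bank, seq_len(n), s, K = 1),
                   cox_partial_loglik(s, tm, st, method = "naive"))

  # all-censored 2-subject batch, bank holding uncensored subjects: finite,
  # hand-computed on a 4-subject toy
  tm4 <- c(2, 4, 6, 8); st4 <- c(1, 0, 1, 0)
  bank4 <- memory_bank_update(memory_bank(tm4, st4, K = 1), 1:4, c(0.1, 0.2, 0.3, 0.4))
  val <- coxmb_loglik(bank4, batch_indices = c(2, 4), batch_scores = c(1, -1), K = 1)
  sc <- c(0.1, 1, 0.3, -1) # bank with batch overrides
  hand <- mean(c(sc[1] - log(sum(exp(sc))), sc[3] - log(sum(exp(sc[3:4])))))
  expect_equal(val, hand, tolerance = 1e-12)

  # K -> 0 disables the bank: batch-only semantics, incl. the skip signal
  expect_true(is_skip_signal(
    coxmb_loglik(bank4, batch_indices = c(2, 4), batch_scores = c(1, -1), K = 1e-9)))
  expect_equal(coxmb_loglik(bank4, batch_indices = c(3, 4),
                            batch_scores = c(0.3, -1), K = 1e-9),
               cox_partial_loglik(c(0.3, -1), tm4[3:4], st4[3:4]))

  # uninitialised slots among drawn members are a usage error
  empty_bank <- memory_bank(tm4, st4, K = 1)
  expect_error(coxmb_loglik(empty_bank, batch_indices = 1, batch_scores = 0, K = 1),
               "uninitialised")
})

test_that("ranking loss rewards correctly ordered cumulative death probabilities", {
  # identical CDFs: every admissible pair contributes exp(0) = 1
  cdf <- matrix(rep(seq(0.1, 1, length.out = 10), each = 4), nrow = 4, byrow = FALSE)
  tm <- c(2, 4, 6, 8); st <- c(1, 1, 1, 1)
  expect_equal(deephit_rank_loss(cdf, tm, st), 6) # 6 ordered pairs

  # one admissible pair with difference d
  cdf2 <- rbind(c(0.9, 1), c(0.3, 1))
  expect_equal(deephit_rank_loss(cdf2, time = c(1, 2), status = c(1, 0)),
               exp(-(0.9 - 0.3) / 0.1), tolerance = 1e-12)
  expect_equal(deephit_rank_loss(cdf2, time = c(1, 2), status = c(1, 0), s = 0.5),
               exp(-(0.9 - 0.3) / 0.5), tolerance = 1e-12)

  # no admissible pair: censored first subject, tied times
  expect_warning(v <- deephit_rank_loss(cdf2, time = c(1, 2), status = c(0, 1)),
                 "no admissible")
  expect_equal(v, 0)
  expect_warning(deephit_rank_loss(cdf2, time = c(2, 2), status = c(1, 1)),
                 "no admissible")

  # monotonicity: a larger margin strictly lowers the loss
  margins <- seq(-0.5, 0.5, by = 0.25)
  losses <- vapply(margins, function(m)
    deephit_rank_loss(rbind(c(0.5 + m, 1), c(0.5, 1)), c(1, 2), c(1, 0)),
    numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("DeepHit total loss = classical likelihood term + weighted rank term", {
  set.seed(36)
  n <- 10
  co <- toy_cohort(n = n, seed = 36, t_max = 15)
  dists <- replicate(n, random_dist(15), simplify = FALSE)
  lik_only <- deephit_total_loss(co, dists, rank_weight = 0)
  expect_equal(lik_only, -dataset_loglik(co, dists, "classical", "omit")$total,
               tolerance = 1e-12)
  cdf <- do.call(rbind, lapply(dists, function(d) cumsum(d$pmf)))
  expect_equal(deephit_total_loss(co, dists, rank_weight = 2),
               lik_only + 2 * deephit_rank_loss(cdf, co$time, co$status),
               tolerance = 1e-10)
})

test_that("Breslow-based time prediction honours score ordering and limits", {
  tm <- c(5, 7, 9); st <- c(1, 0, 0); sc <- c(0, 0, 0); t_max <- 12

  # one-step Breslow: H0 jumps by 1/3 at t = 5; S(t>=5) = exp(-e^g / 3)
  g_cross <- log(3 * log(2)) + 1e-9 # just enough hazard to cross 0.5 at t = 5
  expect_equal(cox_predict_time(sc, tm, st, t_max, g_cross), 5)
  expect_equal(cox_predict_time(sc, tm, st, t_max, 0), t_max) # never crosses

  # extreme scores: immediate death at the earliest event time vs. horizon
  expect_equal(cox_predict_time(sc, tm, st, t_max, 50), 5)
  expect_equal(cox_predict_time(sc, tm, st, t_max, -50), t_max)

  # restricted-mean alternative lies on the grid range and decreases in risk
  means <- cox_predict_time(sc, tm, st, t_max, c(-2, 0, 2), method = "mean")
  expect_true(all(means >= 1 & means <= t_max))
  expect_true(all(diff(means) < 0))

  expect_error(cox_predict_time(sc, tm, c(0, 0, 0), t_max, 0), "uncensored")
})
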