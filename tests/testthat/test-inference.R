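test_that("session log-likelihood matches the step-by-step oracle", {
  log <- five_trial_log()
  models <- list(
    params_for("six_state", eta = 0.2, gamma = 0.81, beta = 2, lapse = 0.1),
    params_for("four_state", eta = 0.2, gamma = 0.81, beta = 2, lapse = 0.1),
    params_for("hybrid_value", eta = 0.2, gamma = 0.81, beta = 2, lapse = 0.1,
               w4 = 0.3),
    params_for("hybrid_learning", eta = 0.3, gamma = 0.9, beta = 2,
               lapse = 0.05, eta_g = 0.06)
  )
  for (p in models) {
    expected_p <- oracle_probs(log, p)
    got <- session_loglik(log, p)
    expect_lt(max(abs(got$p_left - expected_p)), 1e-10)
    chosen_p <- ifelse(log$choice == "left", expected_p, 1 - expected_p)
    expect_lt(abs(got$total - sum(log(chosen_p))), 1e-10)
  }
  # the oracle check extends to a longer simulated log
  long <- small_log(seed = 61, n_animals = 1, n_sessions = 1)
  p <- models[[4]]
  expect_lt(max(abs(session_loglik(long, p)$p_left - oracle_probs(long, p))),
            1e-10)
})

test_that("a pure-lapse model scores N log(1/2) on any log", {
  log <- small_log(seed = 17, n_animals = 1, n_sessions = 2)
  p <- params_for("six_state", lapse = 1)
  expect_equal(session_loglik(log, p)$total, nrow(log) * log(0.5))
})

test_that("likelihood evaluation rejects degenerate input", {
  expect_error(session_loglik(five_trial_log()[0, ], params_for("six_state")),
               "empty")
  bad <- five_trial_log()
  bad$choice[2] <- NA
  expect_error(session_loglik(bad, params_for("six_state")), "missing choice")
  expect_error(fit_mle(five_trial_log()[0, ], "six_state"), "empty")
})

test_that("per-trial probability dumps line up with the log-likelihood", {
  log <- small_log(seed = 19, n_animals = 1, n_sessions = 1)
  p <- params_for("six_state")
  dump <- trial_probabilities(log, p)
  expect_equal(nrow(dump), nrow(log))
  expect_equal(sum(dump$loglik), session_loglik(log, p)$total)
  chosen_p <- ifelse(dump$chosen == "left", dump$p_left, 1 - dump$p_left)
  expect_equal(dump$loglik, log(chosen_p))
})

test_that("MLE attains at least the likelihood of the true parameters", {
  truth <- params_for("six_state", eta = 0.3, beta = 3)
  log <- simulate_cohort(truth, n_animals = 1, n_sessions = 8, seed = 23)
  fit <- fit_mle(log, "six_state", n_restarts = 5, seed = 1)
  expect_gte(fit$estimates$loglik[1], session_loglik(log, truth)$total - 1e-4)
  expect_true(all(fit$estimates$converged))
  # the reported log-likelihood is reproducible from the estimates
  est <- fit$estimates
  p_hat <- model_params("six_state", eta = est$eta, gamma = est$gamma,
                        beta = est$beta, bias = est$bias, persev = est$persev,
                        lapse = est$lapse)
  expect_equal(session_loglik(log, p_hat)$total, est$loglik, tolerance = 1e-8)
})

test_that("WAIC matches the closed form on a toy pointwise matrix", {
  pw <- matrix(c(log(0.5), log(0.25)), nrow = 2)
  w <- compute_waic(pw)
  lppd <- log(0.375)                 # log mean of {0.5, 0.25}
  p_waic <- log(2)^2 / 2             # unbiased variance of the two log-liks
  expect_equal(w$lppd, lppd)
  expect_equal(w$p_waic, p_waic)
  expect_equal(w$waic, -2 * (lppd - p_waic))
  # decomposition identity on a larger random matrix
  set.seed(2)
  pw2 <- matrix(-rexp(200), nrow = 10)
  w2 <- compute_waic(pw2)
  expect_equal(w2$waic, -2 * w2$lppd + 2 * w2$p_waic)
  expect_gte(w2$p_waic, 0)
  # degenerate posteriors: identical samples give p_waic 0; a single sample
  # is rejected
  pw3 <- matrix(rep(c(log(0.5), log(0.8)), each = 4), nrow = 4)
  w3 <- compute_waic(pw3)
  expect_equal(w3$p_waic, 0)
  expect_equal(w3$waic, -2 * (log(0.5) + log(0.8)))
  expect_error(compute_waic(matrix(log(0.5), nrow = 1)), "single")
})

test_that("model comparison is zero against itself and errors on mismatched data", {
  log <- small_log(seed = 37, n_animals = 2, n_sessions = 1)
  f6 <- fit_mle(log, "six_state", n_restarts = 3, seed = 1)
  f6b <- fit_mle(log, "six_state", n_restarts = 3, seed = 2)
  cmp <- compare_models(list(f6, f6b), baseline = "six_state")
  expect_equal(cmp$table$delta_waic[1], 0)
  expect_equal(cmp$table$se_delta[1], 0)
  other <- fit_mle(log[log$animal_id == "animal01", ], "four_state",
                   n_restarts = 2, seed = 1)
  expect_error(compare_models(list(f6, other), baseline = "six_state"),
               "identical trial sets")
  expect_error(compare_models(list(other), baseline = "six_state"),
               "baseline")
})

test_that("limit-equivalent models tie exactly in pointwise likelihood", {
  log <- small_log(seed = 41, n_animals = 1, n_sessions = 1)
  fam <- matched_params()
  ll6 <- session_loglik(log, fam$six_state)$per_trial
  llh <- session_loglik(log, fam$hv0)$per_trial
  expect_equal(ll6, llh, tolerance = 1e-14)
})

test_that("hierarchical fitting recovers the group and shrinks toward it", {
  set.seed(3)
  true_eta <- plogis(rnorm(5, qlogis(0.3), 0.3))
  plist <- lapply(true_eta, function(e)
    params_for("six_state", eta = e, lapse = 0))
  log <- simulate_cohort(plist, n_animals = 5, n_sessions = 4, seed = 71)
  fit <- suppressWarnings(
    fit_hierarchical(log, "six_state", chains = 2, iter = 700, warmup = 400,
                     seed = 4, fit_lapse = FALSE)
  )
  expect_s3_class(fit, "staterep_fit")
  expect_equal(nrow(fit$estimates), 5)
  # group-mean eta interval covers the generating group mean
  draws <- group_mean_draws(fit, "eta")
  h <- hdi_interval(draws)
  expect_gt(0.3, h[1])
  expect_lt(0.3, h[2])
  # WAIC pieces are attached and finite
  expect_true(is.finite(fit$waic) && is.finite(fit$waic_se))
  expect_gte(fit$p_waic, 0)
  # partial pooling: posterior-mean etas are no more dispersed than MLEs
  mle <- fit_mle(log, "six_state", n_restarts = 4, seed = 5,
                 fit_lapse = FALSE)
  disp_h <- mean(abs(fit$estimates$eta - mean(fit$estimates$eta)))
  disp_m <- mean(abs(mle$estimates$eta - mean(mle$estimates$eta)))
  expect_lte(disp_h, disp_m + 1e-6)
  # diagnostics are reported
  expect_true(all(c("accept_rate", "rhat") %in% names(fit$diagnostics)))
  expect_error(fit_hierarchical(log[log$animal_id == "animal01", ],
                                "six_state"), "2 animals")
})

test_that("tidy and glance methods return the documented shapes", {
  log <- small_log(seed = 43, n_animals = 2, n_sessions = 1)
  fit <- fit_mle(log, "six_state", n_restarts = 3, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("animal_id", "term", "estimate") %in% names(td)))
  expect_equal(sort(unique(td$term)),
               sort(c("eta", "gamma", "beta", "bias", "persev", "lapse")))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_animals, 2)
  expect_equal(gl$n_trials, nrow(log))
})

test_that("highest-density intervals behave on known samples", {
  x <- seq(0, 1, length.out = 1001)
  h <- hdi_interval(x, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.01)
  # for a skewed sample the HDI is narrower than the central interval
  set.seed(9)
  y <- rexp(20000)
  h95 <- hdi_interval(y, 0.95)
  ci <- quantile(y, c(0.025, 0.975))
  expect_lt(h95[2] - h95[1], ci[2] - ci[1])
  expect_equal(h95[1], 0, tolerance = 0.02)
})
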