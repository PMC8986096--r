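test_that("parameter constructor enforces ranges and model-specific fields", {
  expect_error(model_params("six_state", eta = 1.2))
  expect_error(model_params("six_state", w4 = 0.5), "hybrid_value")
  expect_error(model_params("hybrid_value"), "w4")
  expect_error(model_params("hybrid_learning", eta = 0.2, eta_g = 0.3),
               "eta_g")
  p <- model_params("hybrid_learning", eta = 0.2, eta_g = 0.2)
  expect_equal(p$eta_g, 0.2)
})

test_that("state maps follow the representations", {
  expect_equal(state_for("free", "left", "four_state"), "Left")
  expect_equal(state_for("left_forced", "left", "four_state"), "Left")
  expect_equal(state_for("left_forced", "right", "four_state"), "Right-NoRwd")
  expect_equal(state_for("right_forced", "left", "four_state"), "Left-NoRwd")
  # six-state map is a bijection over the 6 (odor, action) pairs
  combos <- expand.grid(odor = c("left_forced", "right_forced", "free"),
                        action = c("left", "right"),
                        stringsAsFactors = FALSE)
  labels <- mapply(state_for, combos$odor, combos$action,
                   MoreArgs = list(representation = "six_state"))
  expect_equal(length(unique(labels)), 6)
  # hybrid-value returns both labels
  both <- state_for("free", "right", "hybrid_value")
  expect_equal(both[["four"]], "Right")
  expect_equal(both[["six"]], "Right-Free")
})

test_that("the value update moves one state toward the discounted reward", {
  p <- model_params("four_state", eta = 0.2, gamma = 0.81)
  tab <- state_value_table("four_state")
  tab$v4["Left"] <- 0.5
  out <- update_values(tab, "Left", r = 2, d = 0.5, p)
  expect_equal(out$v4[["Left"]], 0.76)           # 0.5 + 0.2 * (0.9*2 - 0.5)
  expect_equal(out$v4[c("Right", "Left-NoRwd", "Right-NoRwd")],
               tab$v4[c("Right", "Left-NoRwd", "Right-NoRwd")])
  # zero learning rate and zero prediction error both leave the table fixed
  p0 <- model_params("four_state", eta = 0, gamma = 0.81)
  expect_equal(update_values(tab, "Left", 2, 0.5, p0), tab)
  tab$v4["Left"] <- 0.81^2 * 1
  expect_equal(update_values(tab, "Left", 1, 2, p), tab)
})

test_that("the generalization update touches the experienced and paired states", {
  p <- model_params("hybrid_learning", eta = 0.3, gamma = 1, eta_g = 0.03)
  tab <- state_value_table("six_state")
  tab$v6["Left-ForcedL"] <- 0.2
  tab$v6["Left-Free"] <- 0.8
  out <- hybrid_learning_update(tab, "left_forced", "left", r = 1, d = 1, p)
  expect_equal(out$v6[["Left-ForcedL"]], 0.44)   # 0.2 + 0.3 * (1 - 0.2)
  expect_equal(out$v6[["Left-Free"]], 0.806)     # 0.8 + 0.03 * (1 - 0.8)
  expect_equal(out$v6[["Right-Free"]], 0)
  # invalid forced choices update only their own state, toward 0
  tab$v6["Right-ForcedL"] <- 0.5
  out2 <- hybrid_learning_update(tab, "left_forced", "right", r = 0, d = 1, p)
  expect_equal(out2$v6[["Right-ForcedL"]], 0.35)
  expect_equal(out2$v6[["Right-Free"]], 0)
})

test_that("decision variables combine value, bias and perseveration", {
  p <- model_params("four_state", beta = 1, bias = 0.1, persev = 0.2)
  tab <- state_value_table("four_state")
  tab$v4["Left"] <- 0.6
  tab$v4["Right"] <- 0.3
  dv <- decision_variables(tab, list(odor = "free", previous_choice = "left"), p)
  expect_equal(unname(dv), c(0.8, 0.4))
  # no previous choice: perseveration contributes to neither side
  dv0 <- decision_variables(tab, list(odor = "free", previous_choice = NULL), p)
  expect_equal(unname(dv0), c(0.6, 0.4))
  # hybrid-value weighting of the two tables
  ph <- model_params("hybrid_value", w4 = 0.3, bias = 0, persev = 0)
  th <- state_value_table("hybrid_value")
  th$v4["Left"] <- 1
  th$v6["Left-Free"] <- 0.5
  dvh <- decision_variables(th, list(odor = "free", previous_choice = NULL), ph)
  expect_equal(dvh[["left"]], 0.65)
})

test_that("choice probabilities follow the lapse-softmax rule", {
  p <- model_params("six_state", beta = 2, lapse = 0.1)
  expect_equal(choice_probability(1, 1, p), 0.5)
  expect_equal(choice_probability(1.7, 0.7, p),
               0.9 / (1 + exp(-2)) + 0.05)
  p1 <- model_params("six_state", beta = 2, lapse = 1)
  expect_equal(choice_probability(5, -5, p1), 0.5)
  # probabilities stay within [lapse/2, 1 - lapse/2]
  expect_equal(choice_probability(100, -100, p), 0.95)
  expect_equal(choice_probability(-100, 100, p), 0.05)
  # monotone in the decision-variable difference
  dd <- seq(-2, 2, by = 0.25)
  pr <- vapply(dd, function(d) choice_probability(d, 0, p), numeric(1))
  expect_true(all(diff(pr) > 0))
})

test_that("first-trial choice probability is 0.5 for all models", {
  trial <- five_trial_log()[1, ]
  for (m in c("four_state", "six_state", "hybrid_value", "hybrid_learning")) {
    p <- params_for(m, bias = 0, persev = 0,
                    w4 = if (m == "hybrid_value") 0.5 else NULL,
                    eta_g = if (m == "hybrid_learning") 0.1 else NULL)
    st <- model_state(p)
    expect_equal(trial_step(st, trial, p)$p_left, 0.5)
  }
})

test_that("limit equivalences hold exactly per trial on a long synthetic log", {
  log <- simulate_cohort(params_for("six_state"), n_animals = 1,
                         n_sessions = 4, seed = 77)
  expect_gte(nrow(log), 1000)
  fam <- matched_params()
  p6 <- session_loglik(log, fam$six_state)$p_left
  p4 <- session_loglik(log, fam$four_state)$p_left
  expect_lt(max(abs(session_loglik(log, fam$hv0)$p_left - p6)), 1e-12)
  expect_lt(max(abs(session_loglik(log, fam$hv1)$p_left - p4)), 1e-12)
  expect_lt(max(abs(session_loglik(log, fam$hl0)$p_left - p6)), 1e-12)
  expect_lt(max(abs(session_loglik(log, fam$hl_full)$p_left - p4)), 1e-12)
})

test_that("the R reference path and the compiled likelihood agree", {
  log <- small_log(seed = 31, n_animals = 1, n_sessions = 1)
  for (m in c("four_state", "six_state", "hybrid_value", "hybrid_learning")) {
    p <- params_for(m,
                    w4 = if (m == "hybrid_value") 0.35 else NULL,
                    eta_g = if (m == "hybrid_learning") 0.07 else NULL)
    st <- model_state(p)
    pr <- numeric(nrow(log))
    for (i in seq_len(nrow(log))) {
      s <- trial_step(st, log[i, ], p)
      pr[i] <- s$p_left
      st <- s$state
    }
    expect_lt(max(abs(pr - session_loglik(log, p)$p_left)), 1e-12)
  }
})

test_that("values stay in [0, 2] for any parameters and outcomes", {
  set.seed(5)
  for (rep in 1:20) {
    p <- params_for(sample(c("four_state", "six_state"), 1),
                    eta = runif(1), gamma = runif(1))
    st <- model_state(p)
    log <- small_log(seed = rep, n_animals = 1, n_sessions = 1)
    for (i in seq_len(min(nrow(log), 60))) {
      st <- trial_step(st, log[i, ], p)$state
    }
    vals <- c(st$values$v4, st$values$v6)
    expect_true(all(vals >= 0 & vals <= 2))
  }
})

test_that("a pure-lapse agent chooses each side equally often on free trials", {
  p <- params_for("six_state", lapse = 1, bias = 0, persev = 0)
  log <- simulate_cohort(p, n_animals = 1, n_sessions = 10, seed = 55)
  frac <- mean(log$choice[log$odor == "free"] == "left")
  expect_lt(abs(frac - 0.5), 0.05)
})
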