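# shared fixtures: canonical parameter sets and small simulated logs

base_kwargs <- function() {
  list(eta = 0.25, gamma = 0.8, beta = 3, bias = 0.1, persev = 0.2,
       lapse = 0.02)
}

params_for <- function(model, ...) {
  kw <- utils::modifyList(base_kwargs(), list(...))
  do.call(model_params, c(list(model = model), kw))
}

# a matched family of the four models sharing the base parameters
matched_params <- function(...) {
  kw <- list(...)
  list(
    four_state = do.call(params_for, c(list("four_state"), kw)),
    six_state = do.call(params_for, c(list("six_state"), kw)),
    hv0 = do.call(params_for, c(list("hybrid_value", w4 = 0), kw)),
    hv1 = do.call(params_for, c(list("hybrid_value", w4 = 1), kw)),
    hl0 = do.call(params_for, c(list("hybrid_learning", eta_g = 0), kw)),
    hl_full = do.call(params_for,
                      c(list("hybrid_learning",
                             eta_g = utils::modifyList(base_kwargs(), kw)$eta),
                        kw))
  )
}

# small trial log used across tests (~2 animals x 2 sessions)
small_log <- function(seed = 42, n_animals = 2, n_sessions = 2,
                      model = "six_state") {
  simulate_cohort(params_for(model), n_animals = n_animals,
                  n_sessions = n_sessions, seed = seed)
}

# hand-written 5-trial log exercising free/forced, valid/invalid, delays and
# a 2-drop magnitude outcome; block context is irrelevant to the likelihood
five_trial_log <- function() {
  tibble::tibble(
    animal_id = "a1", session_id = "s1", trial_index = 1:5,
    block_index = c(1L, 1L, 1L, 1L, 3L),
    block_type = c("delay", "delay", "delay", "delay", "magnitude"),
    odor = c("free", "left_forced", "right_forced", "free", "free"),
    choice = c("left", "left", "left", "right", "right"),
    valid = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    reward_drops = c(1L, 1L, 0L, 1L, 2L),
    reward_delay_s = c(0.5, 3, NA, 3.5, 0.5),
    correct = c(TRUE, TRUE, FALSE, FALSE, TRUE)
  )
}

# independent step-by-step recomputation of the learning and choice rules,
# written as explicit scalar arithmetic over named states (the oracle the
# C++ likelihood path is checked against)
oracle_probs <- function(records, params) {
  v4 <- c(L = 0, R = 0, LN = 0, RN = 0)
  v6 <- matrix(0, 3, 2, dimnames = list(c("lf", "rf", "fr"), c("L", "R")))
  prev <- "none"
  w4 <- if (is.null(params$w4)) 0 else params$w4
  eta_g <- if (is.null(params$eta_g)) 0 else params$eta_g
  p_left <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    od <- switch(records$odor[i], left_forced = "lf", right_forced = "rf",
                 free = "fr")
    val4 <- function(a) {
      ok <- od == "fr" || (od == "lf" && a == "L") || (od == "rf" && a == "R")
      if (ok) v4[[a]] else v4[[paste0(a, "N")]]
    }
    v_of <- function(a) {
      switch(params$model,
        four_state = val4(a),
        six_state = v6[od, a],
        hybrid_value = w4 * val4(a) + (1 - w4) * v6[od, a],
        hybrid_learning = v6[od, a])
    }
    dvl <- v_of("L") + params$persev * (prev == "left")
    dvr <- v_of("R") + params$bias + params$persev * (prev == "right")
    p_left[i] <- (1 - params$lapse) / (1 + exp(-params$beta * (dvl - dvr))) +
      params$lapse / 2
    a <- if (records$choice[i] == "left") "L" else "R"
    valid <- records$valid[i]
    r <- records$reward_drops[i]
    tgt <- if (!valid || r == 0) 0 else params$gamma^records$reward_delay_s[i] * r
    if (params$model %in% c("four_state", "hybrid_value")) {
      ok <- od == "fr" || (od == "lf" && a == "L") || (od == "rf" && a == "R")
      key <- if (ok) a else paste0(a, "N")
      v4[[key]] <- v4[[key]] + params$eta * (tgt - v4[[key]])
    }
    if (params$model != "four_state") {
      v6[od, a] <- v6[od, a] + params$eta * (tgt - v6[od, a])
      if (params$model == "hybrid_learning" && valid) {
        pair_od <- if (od == "fr") (if (a == "L") "lf" else "rf") else "fr"
        v6[pair_od, a] <- v6[pair_od, a] + eta_g * (tgt - v6[pair_od, a])
      }
    }
    prev <- records$choice[i]
  }
  p_left
}
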