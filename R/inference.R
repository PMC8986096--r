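# integer-encode a trial log for the C++ likelihood core; new_session marks
# trials where value tables and the perseveration memory reset
encode_records <- function(records) {
  if (nrow(records) == 0) abort("empty trial log.")
  if (anyNA(records$choice)) abort("records with missing choice.")
  new_session <- !(records$animal_id == dplyr::lag(records$animal_id) &
                     records$session_id == dplyr::lag(records$session_id))
  new_session[1] <- TRUE
  list(
    odor = odor_code(records$odor),
    choice = side_code(records$choice),
    valid = records$valid,
    drops = as.integer(records$reward_drops),
    delay = records$reward_delay_s,
    new_session = new_session
  )
}

#' Per-trial choice probabilities and log-likelihood
#'
#' Runs a model through a recorded trial log (sessions processed in order,
#' values reset at each session start) and returns the probability of the
#' recorded choice on every trial and the summed log-likelihood.
#'
#' @param records Trial-record tibble (one animal, or several — each
#'   animal/session boundary resets the model).
#' @param params A [model_params()].
#' @param carry_over If `TRUE`, state values persist across session
#'   boundaries (perseveration memory still resets).
#' @return List with `total` (sum of log choice probabilities), `per_trial`
#'   (log-likelihood per trial) and `p_left` (model probability of a left
#'   choice per trial).
#' @examples
#' log <- simulate_cohort(model_params("six_state"), n_sessions = 1, seed = 1)
#' session_loglik(log, model_params("six_state"))$total
#' @export
session_loglik <- function(records, params, carry_over = FALSE) {
  stopifnot(inherits(params, "staterep_params"))
  enc <- encode_records(records)
  out <- cpp_trial_probs(model_id(params$model), param_vector(params),
                         enc$odor, enc$choice, enc$valid, enc$drops,
                         enc$delay, enc$new_session, carry_over)
  list(total = sum(out$loglik), per_trial = out$loglik, p_left = out$p_left)
}

#' Dump per-trial model probabilities for a recorded log
#'
#' @param records Trial-record tibble.
#' @param params A [model_params()].
#' @return A tibble with `animal_id`, `session_id`, `trial_index`, `p_left`,
#'   `chosen` and `loglik`, one row per trial.
#' @export
trial_probabilities <- function(records, params) {
  ll <- session_loglik(records, params)
  tibble(animal_id = records$animal_id, session_id = records$session_id,
         trial_index = records$trial_index, p_left = ll$p_left,
         chosen = records$choice, loglik = ll$per_trial)
}

# ---- parameter transforms (unconstrained scale for optimization / MCMC) ----

# bounded parameters go through logit, beta through log, bias/persev identity
transform_to_unconstrained <- function(values, names) {
  vapply(seq_along(names), function(i) {
    switch(names[i],
      eta = , gamma = , lapse = , w4 = , rho = qlogis(pmin(pmax(values[i], 1e-6), 1 - 1e-6)),
      beta = log(pmax(values[i], 1e-6)),
      values[i])
  }, numeric(1))
}

transform_from_unconstrained <- function(theta, names) {
  vapply(seq_along(names), function(i) {
    switch(names[i],
      eta = , gamma = , lapse = , w4 = , rho = plogis(theta[i]),
      beta = exp(theta[i]),
      theta[i])
  }, numeric(1))
}

# assemble the fixed-order C++ parameter vector from free params on the
# natural scale (rho parameterizes eta_g = eta * rho)
assemble_param_vector <- function(values, names, model, lapse_value = 0) {
  v <- setNames(values, names)
  eta <- v[["eta"]]
  c(eta, v[["gamma"]], v[["beta"]], v[["bias"]], v[["persev"]],
    if ("lapse" %in% names) v[["lapse"]] else lapse_value,
    if (model == "hybrid_value") v[["w4"]] else 0,
    if (model == "hybrid_learning") eta * v[["rho"]] else 0)
}

params_from_free <- function(values, names, model, lapse_value = 0) {
  v <- setNames(as.list(values), names)
  model_params(model, eta = v$eta, gamma = v$gamma, beta = v$beta,
               bias = v$bias, persev = v$persev,
               lapse = v$lapse %||% lapse_value,
               w4 = if (model == "hybrid_value") v$w4,
               eta_g = if (model == "hybrid_learning") v$eta * v$rho)
}

neg_loglik_factory <- function(enc, model, pnames, lapse_value, carry_over) {
  mid <- model_id(model)
  function(theta) {
    values <- transform_from_unconstrained(theta, pnames)
    pv <- assemble_param_vector(values, pnames, model, lapse_value)
    out <- cpp_trial_probs(mid, pv, enc$odor, enc$choice, enc$valid,
                           enc$drops, enc$delay, enc$new_session, carry_over)
    nll <- -sum(out$loglik)
    # keep L-BFGS-B away from non-finite objective values at extreme thetas
    if (!is.finite(nll)) nll <- 1e10
    nll
  }
}

# optimization box on the unconstrained scale (keeps exp/plogis finite)
theta_bounds <- function(pnames) {
  lower <- vapply(pnames, function(p)
    switch(p, beta = log(1e-3), bias = , persev = -5, -7), numeric(1))
  upper <- vapply(pnames, function(p)
    switch(p, beta = log(50), bias = , persev = 5, 7), numeric(1))
  list(lower = lower, upper = upper)
}

random_start <- function(pnames) {
  vapply(pnames, function(p) switch(p,
    eta = qlogis(runif(1, 0.05, 0.6)),
    gamma = qlogis(runif(1, 0.4, 0.95)),
    beta = log(runif(1, 0.5, 8)),
    lapse = qlogis(runif(1, 0.01, 0.2)),
    w4 = , rho = qlogis(runif(1, 0.1, 0.9)),
    rnorm(1, 0, 0.5)), numeric(1))
}

fit_one_animal_mle <- function(records, model, pnames, n_restarts,
                               lapse_value, carry_over) {
  enc <- encode_records(records)
  nll <- neg_loglik_factory(enc, model, pnames, lapse_value, carry_over)
  bb <- theta_bounds(pnames)
  best <- NULL
  any_converged <- FALSE
  try_start <- function(start) {
    tryCatch(
      optim(start, nll, method = "L-BFGS-B",
            lower = bb$lower, upper = bb$upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
  }
  for (r in seq_len(n_restarts)) {
    opt <- try_start(random_start(pnames))
    if (is.null(opt)) next
    if (opt$convergence == 0) any_converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # deterministic fallback from the neutral origin if every restart errored
  if (is.null(best)) best <- try_start(rep(0, length(pnames)))
  if (is.null(best)) abort("all optimizer restarts failed.")
  values <- transform_from_unconstrained(best$par, pnames)
  list(theta = best$par, values = setNames(values, pnames),
       loglik = -best$value, converged = any_converged,
       params = params_from_free(values, pnames, model, lapse_value))
}

#' Per-animal maximum-likelihood fitting
#'
#' Fits a model to each animal in the trial log independently by bounded
#' quasi-Newton optimization (L-BFGS-B on transformed parameters) with
#' multistart. Bounded parameters are logit-transformed, `beta` is
#' log-transformed; the hybrid-learning model is fit through
#' `rho = eta_g / eta` so `eta_g <= eta` holds by construction.
#'
#' @param records Trial-record tibble (any number of animals).
#' @param model Model name.
#' @param n_restarts Number of random restarts per animal.
#' @param seed Optional seed for the restart draws.
#' @param fit_lapse Fit the lapse rate (default) or freeze it.
#' @param lapse_value Fixed lapse when `fit_lapse = FALSE`.
#' @param carry_over Carry values across sessions (default `FALSE`).
#' @return A `staterep_fit` object: per-animal estimates, the pointwise
#'   log-likelihood at the optimum, and an AIC-style WAIC surrogate
#'   (`-2 * (loglik - k)` spread over trials) used for desk-scale model
#'   comparison.
#' @export
fit_mle <- function(records, model, n_restarts = 10, seed = NULL,
                    fit_lapse = TRUE, lapse_value = 0, carry_over = FALSE) {
  model <- match_model(model)
  if (nrow(records) == 0) abort("empty trial log.")
  pnames <- free_param_names(model, fit_lapse)
  with_seed(seed, {
    animals <- unique(records$animal_id)
    fits <- lapply(animals, function(a) {
      fit_one_animal_mle(dplyr::filter(records, .data$animal_id == a),
                         model, pnames, n_restarts, lapse_value, carry_over)
    })
    names(fits) <- animals
    estimates <- purrr::map_dfr(animals, function(a) {
      f <- fits[[a]]
      est <- as_tibble(as.list(f$values))
      if (model == "hybrid_learning") est$eta_g <- est$eta * est$rho
      dplyr::bind_cols(tibble(animal_id = a), est,
                       tibble(loglik = f$loglik, converged = f$converged))
    })
    if (!all(estimates$converged))
      warn("optimizer did not converge for some animals; see `converged` column.")
    # pointwise log-likelihood at the per-animal optima, in record order
    per_trial <- unlist(lapply(animals, function(a) {
      session_loglik(dplyr::filter(records, .data$animal_id == a),
                     fits[[a]]$params, carry_over)$per_trial
    }))
    ord <- order(match(records$animal_id, animals))
    key <- records[ord, c("animal_id", "session_id", "trial_index")]
    n <- length(per_trial)
    k_total <- length(pnames) * length(animals)
    pointwise_ic <- -2 * per_trial + 2 * k_total / n
    new_staterep_fit(
      model = model, method = "mle",
      estimates = estimates,
      pointwise = matrix(per_trial, nrow = 1),
      pointwise_ic = pointwise_ic,
      trial_key = key,
      waic = sum(pointwise_ic), waic_se = NA_real_, p_waic = k_total,
      n_params = k_total,
      diagnostics = list(converged = all(estimates$converged)),
      draws = NULL, param_names = pnames,
      settings = list(n_restarts = n_restarts, seed = seed,
                      fit_lapse = fit_lapse, lapse_value = lapse_value,
                      carry_over = carry_over)
    )
  })
}

new_staterep_fit <- function(...) structure(list(...), class = "staterep_fit")

#' @export
print.staterep_fit <- function(x, ...) {
  cat("<staterep_fit>", x$model, "via", x$method, "\n")
  cat("  animals:", nrow(x$estimates), " trials:", nrow(x$trial_key), "\n")
  cat("  WAIC:", round(x$waic, 1),
      if (!is.na(x$waic_se)) paste0("(se ", round(x$waic_se, 1), ")"),
      if (x$method == "mle") "[AIC-style surrogate]", "\n")
  invisible(x)
}

#' Watanabe-Akaike information criterion from pointwise log-likelihood
#'
#' `lppd = sum_i log(mean_s exp(ll_si))`, `p_waic = sum_i var_s(ll_si)`
#' (unbiased variance across posterior samples), and
#' `waic = -2 * (lppd - p_waic)`. The standard error is
#' `sqrt(n) * sd` of the per-trial contributions
#' `-2 * (lppd_i - p_i)`.
#'
#' @param pointwise Matrix of log-likelihood values, posterior samples in
#'   rows, trials in columns (at least 2 rows).
#' @return List with `waic`, `waic_se`, `p_waic` and `lppd`.
#' @export
compute_waic <- function(pointwise) {
  stopifnot(is.matrix(pointwise))
  if (nrow(pointwise) < 2)
    abort("p_waic is undefined for a single posterior sample.")
  S <- nrow(pointwise)
  # stable log-mean-exp per trial
  m <- apply(pointwise, 2, max)
  lppd_i <- m + log(colMeans(exp(sweep(pointwise, 2, m))))
  p_i <- apply(pointwise, 2, var)
  waic_i <- -2 * (lppd_i - p_i)
  n <- length(waic_i)
  list(waic = sum(waic_i), waic_se = sqrt(n * var(waic_i)),
       p_waic = sum(p_i), lppd = sum(lppd_i), pointwise = waic_i)
}

#' Highest-density interval of a sample
#'
#' @param x Numeric sample.
#' @param prob Interval mass (default 0.95).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hdi_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Compare fitted models by WAIC
#'
#' Computes WAIC differences of each fit against a baseline model on the
#' identical trial set, with the difference standard error from paired
#' per-trial contributions (`se = sqrt(n) * sd(delta_i)`), plus each
#' animal's mean per-trial WAIC difference. Lower WAIC means a better fit,
#' so a positive `delta_waic` means the model fits worse than the baseline.
#'
#' @param fits List of `staterep_fit` objects over the same trials.
#' @param baseline Model name of the baseline fit (default `"six_state"`).
#' @return A `staterep_comparison`: list with `table` (model, waic,
#'   delta_waic, se_delta) and `per_animal` (mean per-trial delta per
#'   animal).
#' @export
compare_models <- function(fits, baseline = "six_state") {
  models <- vapply(fits, function(f) f$model, character(1))
  if (!baseline %in% models) abort("baseline model not among the fits.")
  base <- fits[[match(baseline, models)]]
  keys <- lapply(fits, function(f) f$trial_key)
  for (k in keys) {
    if (!identical(dim(k), dim(base$trial_key)) ||
        !all(k == base$trial_key))
      abort("fits were not computed on identical trial sets.")
  }
  pw <- lapply(fits, fit_pointwise_ic)
  base_pw <- pw[[match(baseline, models)]]
  n <- length(base_pw)
  table <- purrr::map_dfr(seq_along(fits), function(i) {
    delta_i <- pw[[i]] - base_pw
    tibble(model = models[i],
           waic = sum(pw[[i]]),
           delta_waic = sum(delta_i),
           se_delta = if (models[i] == baseline) 0
                      else sqrt(n * var(delta_i)))
  })
  per_animal <- purrr::map_dfr(seq_along(fits), function(i) {
    tibble(model = models[i], animal_id = base$trial_key$animal_id,
           delta = pw[[i]] - base_pw) |>
      dplyr::group_by(.data$model, .data$animal_id) |>
      dplyr::summarise(delta_waic_per_trial = mean(.data$delta),
                       .groups = "drop")
  })
  structure(list(table = table, per_animal = per_animal,
                 baseline = baseline),
            class = "staterep_comparison")
}

# per-trial information-criterion contributions: WAIC pointwise terms for
# MCMC fits; AIC spread over trials for MLE fits (desk-scale surrogate).
# Both fit constructors store these in `pointwise_ic`, so serialized fits
# (which drop the posterior draws) still compare correctly.
fit_pointwise_ic <- function(fit) {
  if (!is.null(fit$pointwise_ic)) return(fit$pointwise_ic)
  compute_waic(fit$pointwise)$pointwise
}

#' @export
print.staterep_comparison <- function(x, ...) {
  cat("<staterep_comparison> baseline:", x$baseline, "\n")
  print(x$table)
  invisible(x)
}
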