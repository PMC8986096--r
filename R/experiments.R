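# default generating-parameter population for recovery / identifiability
# studies: plausible ranges centered on typical fitted values for this task
# (eta near 0.25); documented in the methods vignette
default_population <- function(model) {
  force(model)
  function() {
    eta <- runif(1, 0.1, 0.5)
    model_params(
      model, eta = eta, gamma = runif(1, 0.6, 0.95), beta = runif(1, 1, 5),
      bias = rnorm(1, 0, 0.3), persev = rnorm(1, 0, 0.3),
      lapse = runif(1, 0, 0.1),
      w4 = if (model == "hybrid_value") runif(1, 0.1, 0.9),
      eta_g = if (model == "hybrid_learning") eta * runif(1, 0.1, 0.9))
  }
}

params_as_row <- function(p) {
  tibble(eta = p$eta, gamma = p$gamma, beta = p$beta, bias = p$bias,
         persev = p$persev, lapse = p$lapse,
         w4 = p$w4 %||% NA_real_, eta_g = p$eta_g %||% NA_real_)
}

#' Reward earned as a function of the four-state weight
#'
#' Simulates the hybrid-value model over a grid of `w4` values (all other
#' parameters fixed) and reports the mean reward per trial, in drops. The
#' grid endpoints reproduce pure six-state (`w4 = 0`) and four-state
#' (`w4 = 1`) agents exactly. Each grid point restarts from the same seed,
#' so the whole table is a deterministic function of
#' (`params`, `w4_grid`, `n_sessions`, `seed`).
#'
#' @param params A [model_params()] for the hybrid-value model (its `w4` is
#'   overridden by the grid).
#' @param w4_grid Grid of weights in \[0, 1\].
#' @param n_sessions Sessions simulated per grid point.
#' @param seed Integer seed.
#' @param config A [session_config()].
#' @return A `staterep_reward_curve` tibble: `w4`, `mean_reward`, `sem`
#'   (across sessions).
#' @export
reward_vs_w4 <- function(params, w4_grid = seq(0, 1, by = 0.1),
                         n_sessions = 50, seed = 1,
                         config = session_config()) {
  stopifnot(all(w4_grid >= 0 & w4_grid <= 1))
  out <- purrr::map_dfr(w4_grid, function(g) {
    p <- params
    p$w4 <- g
    p$model <- "hybrid_value"
    log <- simulate_cohort(p, n_animals = 1, n_sessions = n_sessions,
                           config = config, seed = seed)
    per_session <- log |>
      dplyr::group_by(.data$session_id) |>
      dplyr::summarise(reward = mean(.data$reward_drops), .groups = "drop")
    tibble(w4 = g, mean_reward = mean(per_session$reward),
           sem = sd(per_session$reward) / sqrt(n_sessions))
  })
  class(out) <- c("staterep_reward_curve", class(out))
  out
}

#' Parameter-recovery study
#'
#' Draws true parameters per synthetic animal from a generating population,
#' simulates each animal performing the task, refits the model by
#' per-animal MLE, and summarises recovery (true-vs-recovered correlation
#' and mean bias per parameter).
#'
#' @param model Model name.
#' @param n_animals,n_sessions Study size.
#' @param seed Integer seed (recorded in the output).
#' @param population Optional generator `function()` returning a
#'   [model_params()]; defaults to a documented plausible population.
#' @param n_restarts MLE restarts per animal.
#' @param config A [session_config()].
#' @return A `staterep_recovery`: list with `table` (animal, parameter,
#'   true, recovered), `summary` (parameter, correlation, bias) and the
#'   seed manifest.
#' @export
recovery_study <- function(model, n_animals = 20, n_sessions = 20, seed = 1,
                           population = NULL, n_restarts = 5,
                           config = session_config()) {
  model <- match_model(model)
  population <- population %||% default_population(model)
  true_params <- with_seed(seed, lapply(seq_len(n_animals), function(i) population()))
  log <- simulate_cohort(true_params, n_animals = n_animals,
                         n_sessions = n_sessions, config = config,
                         seed = seed + 1L)
  fit <- fit_mle(log, model, n_restarts = n_restarts, seed = seed + 2L)
  truth <- purrr::map_dfr(seq_along(true_params), function(i) {
    dplyr::bind_cols(tibble(animal_id = sprintf("animal%02d", i)),
                     params_as_row(true_params[[i]]))
  }) |>
    tidyr::pivot_longer(-"animal_id", names_to = "parameter",
                        values_to = "true") |>
    dplyr::filter(!is.na(.data$true))
  recovered <- fit$estimates |>
    dplyr::select(-dplyr::any_of(c("loglik", "converged", "rho"))) |>
    tidyr::pivot_longer(-"animal_id", names_to = "parameter",
                        values_to = "recovered")
  table <- dplyr::inner_join(truth, recovered,
                             by = c("animal_id", "parameter"))
  summary <- table |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      correlation = stats::cor(.data$true, .data$recovered),
      bias = mean(.data$recovered - .data$true), .groups = "drop")
  structure(list(table = table, summary = summary, model = model,
                 seeds = c(population = seed, simulate = seed + 1L,
                           fit = seed + 2L),
                 n_animals = n_animals, n_sessions = n_sessions),
            class = "staterep_recovery")
}

#' @export
print.staterep_recovery <- function(x, ...) {
  cat("<staterep_recovery>", x$model, "-", x$n_animals, "animals x",
      x$n_sessions, "sessions\n")
  print(x$summary)
  invisible(x)
}

#' Model-identifiability confusion matrix
#'
#' For each generating model, simulates replicate single-animal datasets and
#' fits every candidate model by MLE; the winner has the lowest information
#' criterion (the AIC-style WAIC surrogate of [fit_mle()]). Returns the
#' row-stochastic confusion matrix of winning fractions.
#'
#' @param models Generating (and candidate) model names.
#' @param n_replicates Replicate datasets per generator.
#' @param n_sessions Sessions per dataset.
#' @param seed Integer seed.
#' @param gen_params Optional named list of [model_params()] per generating
#'   model; defaults to representative values (eta 0.25, gamma 0.8, beta 3,
#'   persev 0.2, lapse 0.02).
#' @param n_restarts MLE restarts.
#' @param config A [session_config()].
#' @return A `staterep_identifiability`: list with `matrix` (tibble:
#'   generator, winner, fraction), `deltas` (per replicate, candidate ICs
#'   relative to the generator's), and the seed manifest.
#' @export
identifiability_matrix <- function(models = c("four_state", "six_state"),
                                   n_replicates = 20, n_sessions = 30,
                                   seed = 1, gen_params = NULL,
                                   n_restarts = 5,
                                   config = session_config()) {
  models <- vapply(models, match_model, character(1), USE.NAMES = FALSE)
  default_gen <- function(m)
    model_params(m, eta = 0.25, gamma = 0.8, beta = 3, bias = 0,
                 persev = 0.2, lapse = 0.02,
                 w4 = if (m == "hybrid_value") 0.5,
                 eta_g = if (m == "hybrid_learning") 0.1)
  raw <- purrr::map_dfr(seq_along(models), function(gi) {
    gen <- models[gi]
    gp <- if (!is.null(gen_params)) gen_params[[gen]] else default_gen(gen)
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      s <- seed + 1000L * gi + r
      log <- simulate_cohort(gp, n_animals = 1, n_sessions = n_sessions,
                             config = config, seed = s)
      ics <- vapply(models, function(m) {
        fit_mle(log, m, n_restarts = n_restarts, seed = s + 1L)$waic
      }, numeric(1))
      tibble(generator = gen, replicate = r, candidate = models,
             ic = ics, winner = models[which.min(ics)], seed = s)
    })
  })
  wins <- raw |>
    dplyr::distinct(.data$generator, .data$replicate, .data$winner) |>
    dplyr::count(.data$generator, .data$winner) |>
    dplyr::group_by(.data$generator) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::complete(generator = models, winner = models,
                    fill = list(fraction = 0))
  structure(list(matrix = wins, deltas = raw, models = models, seed = seed),
            class = "staterep_identifiability")
}

#' @export
print.staterep_identifiability <- function(x, ...) {
  cat("<staterep_identifiability>\n")
  print(tidyr::pivot_wider(x$matrix, names_from = "winner",
                           values_from = "fraction"))
  invisible(x)
}

#' Split-half refitting per animal
#'
#' Splits each animal's sessions chronologically in half, fits a pair of
#' models (by default six-state and hybrid-value) to each half by MLE, and
#' reports per-half WAIC differences (second model minus first) and the
#' hybrid-value weight `w4` per half, plus the cross-animal correlation
#' between the change in `w4` and the change in the WAIC difference. Animals
#' with fewer than 2 sessions are excluded with a notice.
#'
#' @param records Trial-record tibble.
#' @param models Character vector of two model names; the second model's
#'   `w4` estimate is reported when it is `hybrid_value`.
#' @param n_restarts MLE restarts.
#' @param seed Integer seed.
#' @return A `staterep_split_half`: list with `per_animal` (animal, half,
#'   delta_waic, w4), `correlation` (between the across-half changes) and
#'   the excluded animals.
#' @export
split_half_analysis <- function(records, models = c("six_state", "hybrid_value"),
                                n_restarts = 5, seed = 1) {
  stopifnot(length(models) == 2)
  n_sess <- records |>
    dplyr::distinct(.data$animal_id, .data$session_id) |>
    dplyr::count(.data$animal_id)
  excluded <- n_sess$animal_id[n_sess$n < 2]
  if (length(excluded) > 0)
    inform(paste("excluding animals with < 2 sessions:",
                 paste(excluded, collapse = ", ")))
  keep <- setdiff(n_sess$animal_id, excluded)
  if (length(keep) == 0) abort("no animal has at least 2 sessions.")
  per_animal <- purrr::map_dfr(keep, function(a) {
    ra <- dplyr::filter(records, .data$animal_id == a)
    sessions <- unique(ra$session_id)
    first <- sessions[seq_len(length(sessions) %/% 2)]
    purrr::map_dfr(c("first", "second"), function(half) {
      rh <- dplyr::filter(ra, if (half == "first") .data$session_id %in% first
                          else !(.data$session_id %in% first))
      f1 <- fit_mle(rh, models[1], n_restarts = n_restarts, seed = seed)
      f2 <- fit_mle(rh, models[2], n_restarts = n_restarts, seed = seed + 1L)
      tibble(animal_id = a, half = half,
             delta_waic = f2$waic - f1$waic,
             w4 = if ("w4" %in% names(f2$estimates)) f2$estimates$w4[1]
                  else NA_real_)
    })
  })
  wide <- tidyr::pivot_wider(per_animal, names_from = "half",
                             values_from = c("delta_waic", "w4"))
  correlation <- if (nrow(wide) >= 3 && !anyNA(wide$w4_first)) {
    stats::cor(wide$w4_second - wide$w4_first,
               wide$delta_waic_second - wide$delta_waic_first)
  } else NA_real_
  structure(list(per_animal = per_animal, wide = wide,
                 correlation = correlation, excluded = excluded,
                 models = models),
            class = "staterep_split_half")
}

#' @export
print.staterep_split_half <- function(x, ...) {
  cat("<staterep_split_half>", paste(x$models, collapse = " vs "), "\n")
  print(x$per_animal)
  if (!is.na(x$correlation))
    cat("cor(delta w4, delta delta-WAIC):", round(x$correlation, 3), "\n")
  invisible(x)
}
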