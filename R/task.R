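#' Configure the adaptive delay staircase
#'
#' The long-reward delay in delay blocks is titrated by a weighted up/down
#' staircase: every free choice of the long side raises the delay by
#' `step_s * 2 * (1 - target_long_fraction)` seconds and every free choice of
#' the short side lowers it by `step_s * 2 * target_long_fraction`, clamped to
#' `[min_delay_s, max_delay_s]`. At the default target of 0.5 this is the
#' symmetric 1-up/1-down rule with step `step_s`; for other targets the step
#' asymmetry makes the long-choice fraction converge to
#' `target_long_fraction` (weighted up/down equilibrium). Forced long trials
#' use the current delay but never move the staircase.
#'
#' @param start_delay_s Initial long delay, seconds.
#' @param step_s Base step size, seconds.
#' @param target_long_fraction Equilibrium fraction of long free choices.
#' @param min_delay_s,max_delay_s Clamping range for the long delay.
#' @return A list of class `staterep_staircase_config`.
#' @export
staircase_config <- function(start_delay_s = 3, step_s = 0.5,
                             target_long_fraction = 0.5,
                             min_delay_s = 1, max_delay_s = 7) {
  stopifnot(step_s > 0, target_long_fraction > 0, target_long_fraction < 1,
            min_delay_s > 0, max_delay_s > min_delay_s,
            start_delay_s >= min_delay_s, start_delay_s <= max_delay_s)
  structure(
    list(start_delay_s = start_delay_s, step_s = step_s,
         target_long_fraction = target_long_fraction,
         min_delay_s = min_delay_s, max_delay_s = max_delay_s,
         step_up = 2 * step_s * (1 - target_long_fraction),
         step_down = 2 * step_s * target_long_fraction),
    class = "staterep_staircase_config"
  )
}

#' Initialize staircase state
#'
#' @param config A [staircase_config()].
#' @return A list of class `staterep_staircase` with the current delay and
#'   running counts of long vs short free choices.
#' @export
staircase_state <- function(config = staircase_config()) {
  structure(
    list(current_delay_s = config$start_delay_s, config = config,
         n_long = 0L, n_short = 0L),
    class = "staterep_staircase"
  )
}

#' Update the staircase after a trial
#'
#' Only free-choice trials in delay blocks move the staircase: choosing the
#' long (worse) side increases the delay, choosing the short side decreases
#' it, always clamped to the configured range. All other trials return the
#' state unchanged.
#'
#' @param staircase A [staircase_state()].
#' @param trial A one-row trial record (as produced by [resolve_trial()]).
#' @return The updated staircase state.
#' @export
staircase_update <- function(staircase, trial) {
  stopifnot(inherits(staircase, "staterep_staircase"))
  if (trial$odor != "free" || trial$block_type != "delay") return(staircase)
  cfg <- staircase$config
  # on free trials in delay blocks, correct == chose the short (better) side
  if (trial$correct) {
    staircase$current_delay_s <- staircase$current_delay_s - cfg$step_down
    staircase$n_short <- staircase$n_short + 1L
  } else {
    staircase$current_delay_s <- staircase$current_delay_s + cfg$step_up
    staircase$n_long <- staircase$n_long + 1L
  }
  staircase$current_delay_s <- min(max(staircase$current_delay_s,
                                       cfg$min_delay_s), cfg$max_delay_s)
  staircase
}

#' Configure a simulated session
#'
#' Defaults reproduce the task's published structure: four blocks per session
#' (two delay blocks then two magnitude blocks), block lengths drawn from a
#' rounded Gaussian with mean 70 and SD 14 trials (truncated below at
#' `block_length_min`), and a pseudorandom odor sequence in which exactly 7
#' of every 20 trials are free choices and the 13 forced trials split 7/6
#' between sides, the side with 7 alternating across windows.
#'
#' @param block_length_mean,block_length_sd Moments of the block-length
#'   distribution, in trials.
#' @param block_length_min Lower truncation bound for block lengths.
#' @param n_blocks Number of blocks (the task uses 4).
#' @param free_per_window Free-choice trials per window.
#' @param window_length Window size for odor-sequence construction.
#' @param staircase A [staircase_config()].
#' @return A list of class `staterep_session_config`.
#' @export
session_config <- function(block_length_mean = 70, block_length_sd = 14,
                           block_length_min = 20, n_blocks = 4,
                           free_per_window = 7, window_length = 20,
                           staircase = staircase_config()) {
  stopifnot(n_blocks >= 1, free_per_window >= 1,
            window_length > free_per_window,
            inherits(staircase, "staterep_staircase_config"))
  if (block_length_mean <= 0 || block_length_sd < 0)
    abort("block-length mean must be positive and sd non-negative.")
  if (block_length_min < 1)
    abort("block_length_min must be at least 1: untruncated Gaussian block lengths admit non-positive values.")
  if (block_length_sd == 0 && round(block_length_mean) < block_length_min)
    abort("degenerate block length falls below block_length_min.")
  structure(
    list(block_length_mean = block_length_mean,
         block_length_sd = block_length_sd,
         block_length_min = block_length_min,
         n_blocks = n_blocks, free_per_window = free_per_window,
         window_length = window_length, staircase = staircase),
    class = "staterep_session_config"
  )
}

#' Draw block lengths
#'
#' Rounded Gaussian draws with the given mean and SD, redrawn (not clipped)
#' while below `min_length` so the truncation does not pile mass on the
#' floor. With `sd = 0` every draw equals `round(mean)`.
#'
#' @param n Number of lengths to draw.
#' @param mean,sd Mean and SD in trials.
#' @param min_length Lower truncation bound (trials).
#' @return Integer vector of length `n`.
#' @export
sample_block_length <- function(n, mean = 70, sd = 14, min_length = 20) {
  if (mean <= 0 || sd < 0) abort("mean must be positive and sd non-negative.")
  if (min_length < 1)
    abort("min_length must be at least 1: untruncated draws admit non-positive lengths.")
  if (sd == 0) {
    len <- round(mean)
    if (len < min_length) abort("degenerate block length falls below min_length.")
    return(rep(as.integer(len), n))
  }
  out <- as.integer(round(rnorm(n, mean, sd)))
  bad <- which(out < min_length)
  while (length(bad) > 0) {
    out[bad] <- as.integer(round(rnorm(length(bad), mean, sd)))
    bad <- which(out < min_length)
  }
  out
}

# odor sequence: per window of `window_length` trials, `free_per_window` free
# choices; forced trials split as evenly as possible, the majority side
# alternating across windows; order shuffled within each window
build_odor_sequence <- function(n_trials, config) {
  wl <- config$window_length
  nf <- config$free_per_window
  n_windows <- ceiling(n_trials / wl)
  maj_first <- sample(side_levels(), 1)
  n_forced <- wl - nf
  n_maj <- ceiling(n_forced / 2)
  n_min <- n_forced - n_maj
  odors <- character(0)
  for (w in seq_len(n_windows)) {
    maj <- if ((w %% 2) == 1) maj_first else setdiff(side_levels(), maj_first)
    minr <- setdiff(side_levels(), maj)
    win <- c(rep("free", nf),
             rep(paste0(maj, "_forced"), n_maj),
             rep(paste0(minr, "_forced"), n_min))
    odors <- c(odors, sample(win))
  }
  odors[seq_len(n_trials)]
}

#' Build a session schedule
#'
#' Lays out one session: block lengths, block types (delay, delay, magnitude,
#' magnitude for the standard four-block session), the better side per block
#' (randomized for block 1, then reversed at every block transition — the
#' well that was short at the end of block 2 becomes small in block 3), and
#' the pseudorandom odor sequence. The same `config` and `seed` always yield
#' the identical schedule.
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An object of class `staterep_schedule`: a list with `blocks` (a
#'   tibble of per-block specs), `trials` (a per-trial tibble with
#'   `trial_index`, `block_index`, `block_type`, `odor`, `better_side`), the
#'   `config` and the `seed`.
#' @examples
#' sched <- build_session_schedule(seed = 1)
#' sched$blocks
#' @export
build_session_schedule <- function(config = session_config(), seed = NULL) {
  stopifnot(inherits(config, "staterep_session_config"))
  with_seed(seed, {
    lengths <- sample_block_length(config$n_blocks, config$block_length_mean,
                                   config$block_length_sd,
                                   config$block_length_min)
    # first two blocks manipulate delay, the rest magnitude; the better side
    # alternates at every block switch (contingency reversal)
    types <- ifelse(seq_len(config$n_blocks) <= 2, "delay", "magnitude")
    first_better <- sample(side_levels(), 1)
    better <- ifelse(seq_len(config$n_blocks) %% 2 == 1,
                     first_better, setdiff(side_levels(), first_better))
    n_trials <- sum(lengths)
    odors <- build_odor_sequence(n_trials, config)
    blocks <- tibble(
      index = seq_len(config$n_blocks), block_type = types,
      better_side = better, length = lengths
    )
    trials <- tibble(
      trial_index = seq_len(n_trials),
      block_index = rep(blocks$index, lengths),
      block_type = rep(blocks$block_type, lengths),
      odor = odors,
      better_side = rep(blocks$better_side, lengths)
    )
    structure(
      list(blocks = blocks, trials = trials, config = config, seed = seed),
      class = "staterep_schedule"
    )
  })
}

#' @export
print.staterep_schedule <- function(x, ...) {
  cat("<staterep_schedule>", nrow(x$trials), "trials\n")
  print(x$blocks)
  invisible(x)
}

#' Resolve one trial against the schedule
#'
#' Given a schedule, a trial index, the agent's choice and the current
#' staircase state, determines validity, reward amount and delay, and
#' correctness. Invalid choices (the wrong well on a forced trial) terminate
#' the trial unrewarded. On valid trials the chosen side's reward spec for
#' the current block applies; the long side's delay is the staircase's
#' current delay.
#'
#' @param schedule A [build_session_schedule()] result.
#' @param trial_index Trial number within the session.
#' @param choice `"left"` or `"right"`.
#' @param staircase A [staircase_state()].
#' @param animal_id,session_id Identifiers copied into the record.
#' @return A one-row tibble trial record.
#' @export
resolve_trial <- function(schedule, trial_index, choice,
                          staircase = staircase_state(),
                          animal_id = "a1", session_id = "s1") {
  stopifnot(inherits(schedule, "staterep_schedule"),
            trial_index >= 1, trial_index <= nrow(schedule$trials),
            choice %in% side_levels())
  tr <- schedule$trials[trial_index, ]
  valid <- tr$odor == "free" || tr$odor == paste0(choice, "_forced")
  chose_better <- choice == tr$better_side
  if (!valid) {
    drops <- 0L; delay <- NA_real_
  } else if (tr$block_type == "magnitude") {
    drops <- if (chose_better) 2L else 1L
    delay <- 0.5
  } else {
    drops <- 1L
    delay <- if (chose_better) 0.5 else staircase$current_delay_s
  }
  tibble(
    animal_id = animal_id, session_id = session_id,
    trial_index = as.integer(trial_index),
    block_index = tr$block_index, block_type = tr$block_type,
    odor = tr$odor, choice = choice, valid = valid,
    reward_drops = drops, reward_delay_s = delay,
    correct = if (tr$odor == "free") chose_better else valid
  )
}

#' Simulate an agent performing one session
#'
#' Runs the closed loop: on every trial the model's choice probability is
#' computed from its current state values, a choice is sampled, the outcome
#' is resolved against the schedule (with the adaptive staircase supplying
#' long delays), and the model's values are updated by the outcome.
#'
#' @param schedule A [build_session_schedule()] result.
#' @param params A [model_params()] object (its `model` field selects the
#'   state representation).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param animal_id,session_id Identifiers for the emitted records.
#' @return A tibble of trial records, one row per trial, in the trial-log
#'   column layout (see [write_trial_log()]).
#' @examples
#' sched <- build_session_schedule(seed = 1)
#' log <- simulate_agent(sched, model_params("six_state"), seed = 1)
#' head(log)
#' @export
simulate_agent <- function(schedule, params, seed = NULL,
                           animal_id = "a1", session_id = "s1") {
  stopifnot(inherits(schedule, "staterep_schedule"),
            inherits(params, "staterep_params"))
  sc <- schedule$config$staircase
  tr <- schedule$trials
  with_seed(seed, {
    sim <- cpp_simulate_session(
      model_id(params$model), param_vector(params),
      odor_code(tr$odor),
      as.integer(tr$block_type == "magnitude"),
      tr$better_side == "left",
      sc$start_delay_s, sc$step_up, sc$step_down,
      sc$min_delay_s, sc$max_delay_s
    )
    tibble(
      animal_id = animal_id, session_id = session_id,
      trial_index = tr$trial_index,
      block_index = tr$block_index, block_type = tr$block_type,
      odor = tr$odor,
      choice = side_levels()[sim$choice + 1L],
      valid = sim$valid,
      reward_drops = as.integer(sim$reward_drops),
      reward_delay_s = sim$reward_delay_s,
      correct = sim$correct
    )
  })
}

#' Simulate a cohort of agents
#'
#' Generates `n_sessions` sessions for each of `n_animals` agents. Each
#' animal uses either the shared `params` or its own entry of a list of
#' [model_params()]. Values reset at every session start (no carry-over).
#'
#' @param params A [model_params()] object, or a list of them (one per
#'   animal).
#' @param n_animals,n_sessions Cohort size.
#' @param config A [session_config()].
#' @param seed Integer seed for the whole cohort; the full trial log is a
#'   deterministic function of (`params`, `n_animals`, `n_sessions`,
#'   `config`, `seed`).
#' @return A tibble of trial records for all animals and sessions.
#' @export
simulate_cohort <- function(params, n_animals = 1, n_sessions = 1,
                            config = session_config(), seed = NULL) {
  plist <- if (inherits(params, "staterep_params")) {
    rep(list(params), n_animals)
  } else {
    stopifnot(length(params) == n_animals)
    params
  }
  with_seed(seed, {
    out <- vector("list", n_animals * n_sessions)
    k <- 0L
    for (i in seq_len(n_animals)) {
      for (j in seq_len(n_sessions)) {
        sched <- build_session_schedule(config)
        k <- k + 1L
        out[[k]] <- simulate_agent(
          sched, plist[[i]],
          animal_id = sprintf("animal%02d", i),
          session_id = sprintf("session%03d", j)
        )
      }
    }
    dplyr::bind_rows(out)
  })
}
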