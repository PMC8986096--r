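#' Map a trial's odor and action to the state(s) of a representation
#'
#' The four-state representation shares `"Left"`/`"Right"` states between
#' free-choice and correct forced-choice trials and routes incorrect forced
#' choices to the chosen side's `"-NoRwd"` state. The six-state
#' representation keeps one state per (odor, action) pair. The hybrid-value
#' representation carries both tables (10 states) and returns the pair of
#' labels.
#'
#' @param odor `"left_forced"`, `"right_forced"` or `"free"`.
#' @param action `"left"` or `"right"`.
#' @param representation `"four_state"`, `"six_state"` or `"hybrid_value"`.
#'   (The hybrid-learning model uses the six-state map.)
#' @return A state label, or for `"hybrid_value"` a named character vector
#'   with elements `four` and `six`.
#' @examples
#' state_for("free", "left", "four_state")        # "Left"
#' state_for("left_forced", "right", "four_state") # "Right-NoRwd"
#' @export
state_for <- function(odor, action,
                      representation = c("four_state", "six_state", "hybrid_value")) {
  representation <- match.arg(representation)
  stopifnot(odor %in% odor_levels(), action %in% side_levels())
  side <- if (action == "left") "Left" else "Right"
  four <- if (odor == "free" || odor == paste0(action, "_forced")) side
          else paste0(side, "-NoRwd")
  six <- paste0(side, "-", switch(odor, left_forced = "ForcedL",
                                  right_forced = "ForcedR", free = "Free"))
  switch(representation,
    four_state = four,
    six_state = six,
    hybrid_value = c(four = four, six = six))
}

four_state_labels <- function() c("Left", "Right", "Left-NoRwd", "Right-NoRwd")
six_state_labels <- function() {
  c("Left-ForcedL", "Right-ForcedL", "Left-ForcedR", "Right-ForcedR",
    "Left-Free", "Right-Free")
}

# the same-side partner state for generalization; NA for invalid states
paired_state <- function(six_label) {
  switch(six_label,
    "Left-ForcedL" = "Left-Free", "Right-ForcedR" = "Right-Free",
    "Left-Free" = "Left-ForcedL", "Right-Free" = "Right-ForcedR",
    NA_character_)
}

#' Create a zero-initialized state-value table
#'
#' Values start at 0 at the beginning of every session (symmetric
#' initialization: the first trial's choice probability is 0.5 when bias and
#' perseveration are 0).
#'
#' @param representation `"four_state"`, `"six_state"` or `"hybrid_value"`.
#' @return An object of class `staterep_values` holding the four-state table
#'   (`v4`), the six-state table (`v6`), or both.
#' @export
state_value_table <- function(representation = c("four_state", "six_state", "hybrid_value")) {
  representation <- match.arg(representation)
  v4 <- if (representation != "six_state")
    setNames(numeric(4), four_state_labels())
  v6 <- if (representation != "four_state")
    setNames(numeric(6), six_state_labels())
  structure(list(representation = representation, v4 = v4, v6 = v6),
            class = "staterep_values")
}

lookup_table <- function(table, state) {
  if (!is.null(table$v4) && state %in% names(table$v4)) return("v4")
  if (!is.null(table$v6) && state %in% names(table$v6)) return("v6")
  abort(paste0("state '", state, "' not in this representation"))
}

#' Rescorla-Wagner value update with delay discounting
#'
#' Moves the given state's value toward the discounted reward
#' `gamma^d * r` by a fraction `eta`: `V <- V + eta * (gamma^d * r - V)`.
#' All other states are untouched. When `r = 0` the target is 0 and the
#' delay is irrelevant.
#'
#' @param table A [state_value_table()].
#' @param state A state label of the table.
#' @param r Reward amount in drops (0, 1 or 2).
#' @param d Delay to reward in seconds (any positive placeholder when
#'   `r = 0`).
#' @param params A [model_params()] (uses `eta` and `gamma`).
#' @return The updated table.
#' @examples
#' tab <- state_value_table("four_state")
#' tab$v4["Left"] <- 0.5
#' p <- model_params("four_state", eta = 0.2, gamma = 0.81)
#' update_values(tab, "Left", r = 2, d = 0.5, p)$v4[["Left"]]  # 0.76
#' @export
update_values <- function(table, state, r, d, params) {
  stopifnot(inherits(table, "staterep_values"), r %in% 0:2,
            r == 0 || d > 0)
  slot <- lookup_table(table, state)
  target <- if (r == 0) 0 else params$gamma^d * r
  v <- table[[slot]][[state]]
  table[[slot]][[state]] <- v + params$eta * (target - v)
  table
}

#' Six-state update with cross-trial generalization
#'
#' The hybrid-learning model's update: the experienced (odor, action) state
#' moves toward `gamma^d * r` at rate `eta`; on valid trials the same-side
#' partner state (valid forced and free states pair up) moves toward the same
#' target at rate `eta_g`, each relative to its own current value. Invalid
#' forced choices update only their own state, with `r = 0` and no
#' generalization.
#'
#' @param table A six-state [state_value_table()].
#' @param odor,action The trial's odor and chosen action.
#' @param r,d Reward drops and delay (seconds).
#' @param params A [model_params()] for the hybrid-learning model.
#' @return The updated table.
#' @export
hybrid_learning_update <- function(table, odor, action, r, d, params) {
  stopifnot(inherits(table, "staterep_values"), !is.null(table$v6))
  valid <- odor == "free" || odor == paste0(action, "_forced")
  own <- state_for(odor, action, "six_state")
  if (!valid) {
    return(update_values(table, own, 0, 1, params))
  }
  target <- if (r == 0) 0 else params$gamma^d * r
  v <- table$v6[[own]]
  table$v6[[own]] <- v + params$eta * (target - v)
  pair <- paired_state(own)
  eta_g <- params$eta_g %||% 0
  vp <- table$v6[[pair]]
  table$v6[[pair]] <- vp + eta_g * (target - vp)
  table
}

#' Decision variables for left and right
#'
#' `DV(a) = V(s_a) + bias * [a = right] + persev * [a = previous choice]`,
#' where `s_a` is the state action `a` would lead to under the current odor.
#' For the hybrid-value model `V(s_a) = w4 * V4(s_a) + (1 - w4) * V6(s_a)`.
#' On the first trial of a session (`previous_choice = NULL` or `"none"`)
#' the perseveration term is 0 for both actions.
#'
#' @param table A [state_value_table()] matching the model's representation.
#' @param context List with `odor` and `previous_choice`.
#' @param params A [model_params()].
#' @return Named numeric vector `c(left = , right = )`.
#' @export
decision_variables <- function(table, context, params) {
  stopifnot(inherits(table, "staterep_values"))
  prev <- context$previous_choice %||% "none"
  av <- function(action) {
    switch(params$model,
      four_state = table$v4[[state_for(context$odor, action, "four_state")]],
      hybrid_value = {
        s <- state_for(context$odor, action, "hybrid_value")
        params$w4 * table$v4[[s[["four"]]]] +
          (1 - params$w4) * table$v6[[s[["six"]]]]
      },
      table$v6[[state_for(context$odor, action, "six_state")]])
  }
  c(left = av("left") + params$persev * (prev == "left"),
    right = av("right") + params$bias + params$persev * (prev == "right"))
}

#' Softmax choice probability with lapse
#'
#' `P(left) = (1 - lapse) / (1 + exp(-beta * (DV_left - DV_right))) +
#' lapse / 2`, so the probability always lies in
#' `[lapse / 2, 1 - lapse / 2]` and `P(right) = 1 - P(left)`.
#'
#' @param dv_left,dv_right Decision variables.
#' @param params A [model_params()] (uses `beta` and `lapse`).
#' @return `P(left)`.
#' @export
choice_probability <- function(dv_left, dv_right, params) {
  (1 - params$lapse) * plogis(params$beta * (dv_left - dv_right)) +
    params$lapse / 2
}

#' Initialize a model state for sequential evaluation
#'
#' @param params A [model_params()].
#' @return A list with the value table(s) for the model's representation and
#'   `previous_choice = NULL`.
#' @export
model_state <- function(params) {
  rep_for <- switch(params$model,
    four_state = "four_state",
    hybrid_value = "hybrid_value",
    "six_state")
  list(values = state_value_table(rep_for), previous_choice = NULL)
}

#' One model step on a recorded trial
#'
#' Returns the model's probability of choosing left on the trial (computed
#' before observing its choice), then applies the value update implied by
#' the recorded choice and outcome. Forced trials use the same choice rule
#' as free trials; the unavailable reward is simply never delivered for
#' wrong choices. The hybrid-value model updates its four- and six-state
#' tables in parallel, the four-state component learning on invalid trials
#' too (NoRwd states updated toward 0).
#'
#' @param state A [model_state()].
#' @param trial A one-row trial record (`odor`, `choice`, `valid`,
#'   `reward_drops`, `reward_delay_s`).
#' @param params A [model_params()].
#' @return List with `p_left` and the updated `state`.
#' @export
trial_step <- function(state, trial, params) {
  dv <- decision_variables(state$values,
                           list(odor = trial$odor,
                                previous_choice = state$previous_choice),
                           params)
  p <- choice_probability(dv[["left"]], dv[["right"]], params)
  r <- if (trial$valid) trial$reward_drops else 0L
  d <- if (is.na(trial$reward_delay_s)) 1 else trial$reward_delay_s
  tab <- state$values
  if (params$model == "hybrid_learning") {
    tab <- hybrid_learning_update(tab, trial$odor, trial$choice, r, d, params)
  } else {
    if (params$model %in% c("four_state", "hybrid_value"))
      tab <- update_values(tab, state_for(trial$odor, trial$choice, "four_state"),
                           r, d, params)
    if (params$model %in% c("six_state", "hybrid_value"))
      tab <- update_values(tab, state_for(trial$odor, trial$choice, "six_state"),
                           r, d, params)
  }
  list(p_left = p,
       state = list(values = tab, previous_choice = trial$choice))
}
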