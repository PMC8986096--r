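trial_log_columns <- function() {
  c("animal_id", "session_id", "trial_index", "block_index", "block_type",
    "odor", "choice", "valid", "reward_drops", "reward_delay_s", "correct")
}

#' Write a trial log to CSV
#'
#' Fixed dialect: header row, UTF-8, `"."` decimal separator, columns exactly
#' `animal_id, session_id, trial_index, block_index, block_type, odor,
#' choice, valid, reward_drops, reward_delay_s, correct` in this order.
#' Records must be sorted by animal, session and trial index.
#'
#' @param records A trial-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  missing_cols <- setdiff(trial_log_columns(), names(records))
  if (length(missing_cols) > 0)
    abort(paste("trial log missing columns:", paste(missing_cols, collapse = ", ")))
  readr::write_csv(records[, trial_log_columns()], path)
  invisible(path)
}

#' Read a trial log from CSV
#'
#' Validates the closed vocabularies (`odor`, `choice`, `block_type`), value
#' ranges (`reward_drops` in 0..2, `block_index` positive) and that trial
#' indices increase within each animal/session; violations raise an error
#' naming the offending data row.
#'
#' @param path CSV file written by [write_trial_log()] (or matching its
#'   layout).
#' @return A trial-record tibble.
#' @export
read_trial_log <- function(path) {
  rec <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      session_id = readr::col_character(),
      trial_index = readr::col_integer(),
      block_index = readr::col_integer(),
      block_type = readr::col_character(),
      odor = readr::col_character(),
      choice = readr::col_character(),
      valid = readr::col_logical(),
      reward_drops = readr::col_integer(),
      reward_delay_s = readr::col_double(),
      correct = readr::col_logical()
    )
  )
  missing_cols <- setdiff(trial_log_columns(), names(rec))
  if (length(missing_cols) > 0)
    abort(paste("trial log missing columns:", paste(missing_cols, collapse = ", ")))
  rec <- as_tibble(rec)[, trial_log_columns()]
  if (nrow(rec) == 0) return(rec)
  check_vocab <- function(col, allowed) {
    bad <- which(!(rec[[col]] %in% allowed))
    if (length(bad) > 0)
      abort(sprintf("row %d: invalid %s value '%s'", bad[1], col, rec[[col]][bad[1]]))
  }
  check_vocab("odor", odor_levels())
  check_vocab("choice", side_levels())
  check_vocab("block_type", block_type_levels())
  bad <- which(is.na(rec$reward_drops) | rec$reward_drops < 0 | rec$reward_drops > 2)
  if (length(bad) > 0)
    abort(sprintf("row %d: reward_drops out of range", bad[1]))
  bad <- which(is.na(rec$block_index) | rec$block_index < 1)
  if (length(bad) > 0)
    abort(sprintf("row %d: block_index out of range", bad[1]))
  bad <- which(is.na(rec$trial_index))
  if (length(bad) > 0)
    abort(sprintf("row %d: missing trial_index", bad[1]))
  same <- rec$animal_id == dplyr::lag(rec$animal_id) &
    rec$session_id == dplyr::lag(rec$session_id)
  nonmono <- which(same & rec$trial_index <= dplyr::lag(rec$trial_index))
  if (length(nonmono) > 0)
    abort(sprintf("row %d: trial_index not increasing within session", nonmono[1]))
  rec
}
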