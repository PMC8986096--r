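test_that("block-length sampler has the configured moments and floor", {
  expect_identical(sample_block_length(5, mean = 70, sd = 0), rep(70L, 5))
  set.seed(1)
  draws <- sample_block_length(10000, mean = 70, sd = 14, min_length = 20)
  se <- 14 / sqrt(10000)
  expect_lt(abs(mean(draws) - 70), 3 * se)
  expect_lt(abs(sd(draws) - 14), 0.5)
  expect_true(all(draws >= 20))
  expect_error(sample_block_length(1, mean = -5), "positive")
  expect_error(sample_block_length(1, mean = 70, sd = 14, min_length = 0),
               "non-positive")
})

test_that("session schedules satisfy the block and odor-sequence invariants", {
  sched <- build_session_schedule(seed = 11)
  blocks <- sched$blocks
  expect_equal(nrow(blocks), 4)
  expect_equal(blocks$block_type, c("delay", "delay", "magnitude", "magnitude"))
  # reversal at every switch; the short well of block 2 becomes small in
  # block 3, so block 3's better side equals block 1's
  expect_true(all(blocks$better_side[2:4] != blocks$better_side[1:3]))
  expect_equal(blocks$better_side[3], blocks$better_side[1])
  expect_equal(nrow(sched$trials), sum(blocks$length))
  # every full 20-trial window aligned to session start has exactly 7 free
  # choices and a 7/6 forced split
  odors <- sched$trials$odor
  n_win <- length(odors) %/% 20
  for (w in seq_len(n_win)) {
    win <- odors[((w - 1) * 20 + 1):(w * 20)]
    expect_equal(sum(win == "free"), 7)
    expect_equal(sort(as.integer(table(win[win != "free"]))), c(6, 7))
  }
})

test_that("schedules and simulated logs are deterministic in the seed", {
  s1 <- build_session_schedule(seed = 3)
  s2 <- build_session_schedule(seed = 3)
  expect_identical(s1$trials, s2$trials)
  p <- params_for("six_state")
  l1 <- simulate_agent(s1, p, seed = 9)
  l2 <- simulate_agent(s2, p, seed = 9)
  expect_identical(l1, l2)
  c1 <- simulate_cohort(p, n_animals = 2, n_sessions = 2, seed = 5)
  c2 <- simulate_cohort(p, n_animals = 2, n_sessions = 2, seed = 5)
  expect_identical(c1, c2)
})

test_that("a fixed-length-20 four-block session has 80 trials, 28 free", {
  cfg <- session_config(block_length_mean = 20, block_length_sd = 0,
                        block_length_min = 20)
  sched <- build_session_schedule(cfg, seed = 2)
  expect_equal(nrow(sched$trials), 80)
  expect_equal(sum(sched$trials$odor == "free"), 28)
})

test_that("resolve_trial applies validity, reward specs and the staircase delay", {
  cfg <- session_config(block_length_mean = 20, block_length_sd = 0,
                        block_length_min = 20)
  sched <- build_session_schedule(cfg, seed = 4)
  st <- staircase_state(staircase_config(start_delay_s = 4))
  # forced trial, wrong side: invalid and unrewarded
  i_lf <- which(sched$trials$odor == "left_forced")[1]
  tr <- resolve_trial(sched, i_lf, "right", st)
  expect_false(tr$valid)
  expect_equal(tr$reward_drops, 0L)
  expect_true(is.na(tr$reward_delay_s))
  expect_false(tr$correct)
  # free trial: either choice valid, reward by chosen side
  i_fr <- which(sched$trials$odor == "free")[1]
  for (ch in c("left", "right")) {
    tr <- resolve_trial(sched, i_fr, ch, st)
    expect_true(tr$valid)
    expect_equal(tr$reward_drops, 1L)
  }
  # delay block: worse side uses the staircase's current delay
  worse <- setdiff(c("left", "right"), sched$trials$better_side[i_fr])
  expect_equal(resolve_trial(sched, i_fr, worse, st)$reward_delay_s, 4)
  # magnitude block: big side gives 2 drops at 0.5 s
  i_mag <- which(sched$trials$block_type == "magnitude" &
                   sched$trials$odor == "free")[1]
  tr <- resolve_trial(sched, i_mag, sched$trials$better_side[i_mag], st)
  expect_equal(tr$reward_drops, 2L)
  expect_equal(tr$reward_delay_s, 0.5)
})

test_that("staircase steps are clamped to [1, 7] and ignore other trials", {
  cfg <- staircase_config(start_delay_s = 7, step_s = 0.5)
  st <- staircase_state(cfg)
  long_trial <- tibble::tibble(odor = "free", block_type = "delay",
                               correct = FALSE)
  short_trial <- tibble::tibble(odor = "free", block_type = "delay",
                                correct = TRUE)
  expect_equal(staircase_update(st, long_trial)$current_delay_s, 7)
  st2 <- staircase_state(staircase_config(start_delay_s = 1))
  expect_equal(staircase_update(st2, short_trial)$current_delay_s, 1)
  # forced trials and magnitude blocks leave the staircase unchanged
  forced <- tibble::tibble(odor = "left_forced", block_type = "delay",
                           correct = TRUE)
  mag <- tibble::tibble(odor = "free", block_type = "magnitude",
                        correct = TRUE)
  expect_equal(staircase_update(st, forced)$current_delay_s, 7)
  expect_equal(staircase_update(st, mag)$current_delay_s, 7)
})

test_that("the staircase drives the long-choice fraction to its target", {
  # delay-averse chooser: P(long) falls with the current delay, crossing the
  # target fraction somewhere inside [1, 7]
  for (target in c(0.4, 0.5)) {
    cfg <- staircase_config(start_delay_s = 2, step_s = 0.5,
                            target_long_fraction = target)
    st <- staircase_state(cfg)
    set.seed(8)
    picks <- logical(4000)
    for (i in seq_along(picks)) {
      p_long <- stats::plogis(2 - 0.8 * st$current_delay_s)
      long <- runif(1) < p_long
      picks[i] <- long
      trial <- tibble::tibble(odor = "free", block_type = "delay",
                              correct = !long)
      st <- staircase_update(st, trial)
    }
    expect_lt(abs(mean(picks[-(1:500)]) - target), 0.05)
  }
})

test_that("simulated logs respect reward-spec and validity invariants", {
  log <- small_log(seed = 13, n_animals = 2, n_sessions = 3)
  expect_true(all(log$valid == (log$odor == "free" |
                                  log$odor == paste0(log$choice, "_forced"))))
  expect_true(all((log$reward_drops == 0) == (!log$valid)))
  expect_true(all(is.na(log$reward_delay_s) == (log$reward_drops == 0)))
  # 2 drops only in magnitude blocks; delays above 0.5 only in delay blocks
  expect_true(all(log$block_type[log$reward_drops == 2] == "magnitude"))
  long <- !is.na(log$reward_delay_s) & log$reward_delay_s > 0.5
  expect_true(all(log$block_type[long] == "delay"))
  expect_true(all(log$reward_delay_s[long] >= 1 & log$reward_delay_s[long] <= 7))
  # forced correctness is validity; free correctness is choosing the better side
  forced <- log$odor != "free"
  expect_identical(log$correct[forced], log$valid[forced])
})

test_that("trial logs round-trip through CSV and malformed rows are rejected", {
  log <- small_log(seed = 21, n_animals = 1, n_sessions = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(log, path)
  back <- read_trial_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log))
  # closed vocabulary: an unknown odor names its row
  bad <- log
  bad$odor[7] <- "centre"
  write_trial_log(bad, path)
  expect_error(read_trial_log(path), "row 7.*odor")
  # non-monotone trial indices are named too
  bad <- log
  bad$trial_index[5] <- 3L
  write_trial_log(bad, path)
  expect_error(read_trial_log(path), "row 5.*trial_index")
  # header-only file yields an empty log
  readr::write_csv(log[0, ], path)
  expect_equal(nrow(read_trial_log(path)), 0)
})
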