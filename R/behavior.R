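#' Extract generalization cases from a trial log
#'
#' A case opens at an incorrect free-choice trial (the animal chose the worse
#' well) and closes at the next free-choice trial, whose accuracy is the
#' case's outcome; `n_rewarded_forced` counts the valid (rewarded)
#' forced-choice trials strictly between the two. Invalid forced trials are
#' not counted. By default cases never span sessions or block boundaries
#' (the "better option" changes meaning at a block switch); set
#' `span_blocks = TRUE` to let cases cross block switches within a session.
#'
#' @param records Trial-record tibble, ordered within sessions.
#' @param span_blocks Allow cases to cross block boundaries.
#' @return A tibble with one row per case: `animal_id`, `session_id`,
#'   `outcome` (accuracy of the closing free-choice trial),
#'   `n_rewarded_forced`, and `trial_index_in_block` of the closing trial.
#' @export
extract_generalization_cases <- function(records, span_blocks = FALSE) {
  unit_cols <- if (span_blocks) c("animal_id", "session_id")
               else c("animal_id", "session_id", "block_index")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit_cols))) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::group_modify(~ scan_cases(.x)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("animal_id", "session_id", "outcome",
                                  "n_rewarded_forced", "trial_index_in_block")))
}

scan_cases <- function(tr) {
  open <- FALSE
  n_forced <- 0L
  out <- list()
  # position within the current block (rows are ordered; when the group is a
  # single block the grouping column is absent and trials are contiguous)
  tib <- if ("block_index" %in% names(tr)) {
    stats::ave(seq_len(nrow(tr)), tr$block_index, FUN = seq_along)
  } else {
    tr$trial_index - tr$trial_index[1] + 1L
  }
  for (i in seq_len(nrow(tr))) {
    if (tr$odor[i] == "free") {
      if (open) {
        out[[length(out) + 1]] <- tibble(
          outcome = tr$correct[i], n_rewarded_forced = n_forced,
          trial_index_in_block = tib[i])
      }
      open <- !tr$correct[i]
      n_forced <- 0L
    } else if (open && tr$valid[i]) {
      n_forced <- n_forced + 1L
    }
  }
  if (length(out) == 0)
    return(tibble(outcome = logical(), n_rewarded_forced = integer(),
                  trial_index_in_block = integer()))
  dplyr::bind_rows(out)
}

#' Hierarchical logistic regression for cross-trial generalization
#'
#' Models the probability that the free-choice trial closing a case is
#' accurate: `logit P(outcome) = alpha_animal + theta_animal *
#' n_rewarded_forced` (plus `kappa_animal * trial_index_in_block` when
#' `with_trial_index = TRUE`), with per-animal coefficients drawn from
#' Normal group distributions. A positive group-mean `theta` indicates that
#' rewarded forced-choice experience improves subsequent free choices — the
#' signature of a shared (generalizing) state representation. Fitting uses
#' the package's adaptive Metropolis-within-Gibbs sampler
#' (`method = "mcmc"`, the default, reporting 95% highest-density
#' intervals), or `lme4::glmer` as a fast non-Bayesian fallback
#' (`method = "glmer"`, Wald intervals).
#'
#' @param cases Output of [extract_generalization_cases()].
#' @param with_trial_index Include the trial-index-in-block covariate.
#' @param method `"mcmc"` or `"glmer"`.
#' @param chains,iter,warmup Sampler settings for `method = "mcmc"`.
#' @param seed Integer seed.
#' @return A `staterep_regression`: list with `group` (tibble of group-mean
#'   posterior summaries per coefficient), `animals` (per-animal coefficient
#'   summaries), the raw group-mean draws, and diagnostics.
#' @export
fit_generalization_regression <- function(cases, with_trial_index = FALSE,
                                          method = c("mcmc", "glmer"),
                                          chains = 2, iter = 1500,
                                          warmup = 750, seed = NULL) {
  method <- match.arg(method)
  if (nrow(cases) == 0) abort("no generalization cases supplied.")
  animals <- unique(cases$animal_id)
  terms <- c("intercept", "n_rewarded_forced",
             if (with_trial_index) "trial_index_in_block")
  degenerate <- vapply(animals, function(a) {
    y <- cases$outcome[cases$animal_id == a]
    length(unique(y)) == 1
  }, logical(1))
  if (any(degenerate))
    warn(paste("animals with all-identical outcomes (weakly identified intercepts):",
               paste(animals[degenerate], collapse = ", ")))
  if (method == "glmer") {
    return(regression_glmer(cases, with_trial_index, animals, terms, degenerate))
  }
  X <- lapply(animals, function(a) {
    ca <- cases[cases$animal_id == a, ]
    cbind(1, ca$n_rewarded_forced,
          if (with_trial_index) ca$trial_index_in_block)
  })
  y <- lapply(animals, function(a) as.numeric(cases$outcome[cases$animal_id == a]))
  unit_loglik <- function(u, theta) {
    eta <- drop(X[[u]] %*% theta)
    -log1p(exp(-(2 * y[[u]] - 1) * eta))
  }
  res <- hier_mh(unit_loglik, length(animals), terms, chains = chains,
                 iter = iter, warmup = warmup, seed = seed,
                 init = matrix(0, length(animals), length(terms)))
  group <- purrr::map_dfr(seq_along(terms), function(k) {
    mu <- res$group[, paste0("mu_", terms[k])]
    h <- hdi_interval(mu)
    tibble(term = terms[k], estimate = mean(mu),
           hdi_low = h[1], hdi_high = h[2])
  })
  per_animal <- purrr::map_dfr(seq_along(animals), function(u) {
    purrr::map_dfr(seq_along(terms), function(k) {
      dr <- res$units[, u, k]
      h <- hdi_interval(dr)
      tibble(animal_id = animals[u], term = terms[k],
             estimate = mean(dr), hdi_low = h[1], hdi_high = h[2])
    })
  })
  structure(list(method = "mcmc", group = group, animals = per_animal,
                 group_draws = res$group, diagnostics = res$diagnostics,
                 degenerate = animals[degenerate]),
            class = "staterep_regression")
}

regression_glmer <- function(cases, with_trial_index, animals, terms, degenerate) {
  if (!requireNamespace("lme4", quietly = TRUE))
    abort("method = 'glmer' requires the lme4 package.")
  fml <- if (with_trial_index)
    outcome ~ n_rewarded_forced + trial_index_in_block +
      (1 + n_rewarded_forced | animal_id)
  else outcome ~ n_rewarded_forced + (1 + n_rewarded_forced | animal_id)
  fit <- lme4::glmer(fml, data = cases, family = binomial())
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  group <- tibble(term = terms, estimate = as.numeric(fe),
                  hdi_low = as.numeric(fe - 1.96 * se),
                  hdi_high = as.numeric(fe + 1.96 * se))
  co <- coef(fit)$animal_id
  per_animal <- purrr::map_dfr(seq_len(nrow(co)), function(i) {
    tibble(animal_id = rownames(co)[i],
           term = terms[seq_len(min(length(terms), ncol(co)))],
           estimate = as.numeric(co[i, seq_len(min(length(terms), ncol(co)))]),
           hdi_low = NA_real_, hdi_high = NA_real_)
  })
  structure(list(method = "glmer", group = group, animals = per_animal,
                 group_draws = NULL, diagnostics = list(fit = fit),
                 degenerate = animals[degenerate]),
            class = "staterep_regression")
}

#' @export
print.staterep_regression <- function(x, ...) {
  cat("<staterep_regression>", x$method, "\n")
  print(x$group)
  invisible(x)
}

#' Block-aligned learning curves
#'
#' Accuracy around block starts: offsets 1..`n_trials` are the first trials
#' of each block and offsets -`n_trials`..-1 the last. Forced-choice
#' accuracy is the fraction of valid choices; free-choice accuracy the
#' fraction choosing the better well. Offsets with no trials for an animal
#' are missing, not zero; the dispersion is the s.e.m. across animals.
#'
#' @param records Trial-record tibble.
#' @param n_trials Trials shown on each side of a block boundary.
#' @return A `staterep_curves` tibble: `block_index`, `offset`,
#'   `trial_type` (`"forced"`/`"free"`), `accuracy`, `sem`, `n_animals`.
#' @export
compute_learning_curves <- function(records, n_trials = 10) {
  offsets <- records |>
    dplyr::group_by(.data$animal_id, .data$session_id, .data$block_index) |>
    dplyr::mutate(
      pos = dplyr::row_number(),
      offset = dplyr::case_when(
        .data$pos <= n_trials ~ .data$pos,
        .data$pos > dplyr::n() - n_trials ~ .data$pos - dplyr::n() - 1L,
        TRUE ~ NA_integer_
      ),
      trial_type = ifelse(.data$odor == "free", "free", "forced"),
      acc = ifelse(.data$odor == "free", .data$correct, .data$valid)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$offset))
  per_animal <- offsets |>
    dplyr::group_by(.data$animal_id, .data$block_index, .data$offset,
                    .data$trial_type) |>
    dplyr::summarise(acc = mean(.data$acc), .groups = "drop")
  out <- per_animal |>
    dplyr::group_by(.data$block_index, .data$offset, .data$trial_type) |>
    dplyr::summarise(
      accuracy = mean(.data$acc),
      sem = if (dplyr::n() > 1) sd(.data$acc) / sqrt(dplyr::n()) else NA_real_,
      n_animals = dplyr::n(), .groups = "drop") |>
    # offsets with no trials anywhere are missing, never zero
    tidyr::complete(
      block_index = unique(records$block_index),
      offset = c(-(n_trials:1), 1:n_trials),
      trial_type = c("forced", "free"),
      fill = list(accuracy = NA_real_, sem = NA_real_, n_animals = 0L)) |>
    dplyr::arrange(.data$block_index, .data$offset)
  class(out) <- c("staterep_curves", class(out))
  out
}
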