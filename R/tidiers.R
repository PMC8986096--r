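#' Tidy a fitted model
#'
#' One row per animal and parameter, on the natural scale. For hierarchical
#' fits, 95% highest-density intervals from the per-animal posterior draws
#' are attached.
#'
#' @param x A `staterep_fit`.
#' @param ... Unused.
#' @return A tibble with `animal_id`, `term`, `estimate` (and `hdi_low`,
#'   `hdi_high` for MCMC fits).
#' @export
tidy.staterep_fit <- function(x, ...) {
  long <- x$estimates |>
    dplyr::select(-dplyr::any_of(c("loglik", "converged"))) |>
    tidyr::pivot_longer(-"animal_id", names_to = "term",
                        values_to = "estimate")
  if (x$method != "mcmc") return(long)
  hdis <- purrr::map_dfr(seq_along(x$draws$animals), function(u) {
    purrr::map_dfr(seq_along(x$param_names), function(k) {
      nat <- vapply(x$draws$units[, u, k], transform_from_unconstrained,
                    numeric(1), names = x$param_names[k])
      h <- hdi_interval(nat)
      tibble(animal_id = x$draws$animals[u], term = x$param_names[k],
             hdi_low = h[1], hdi_high = h[2])
    })
  })
  dplyr::left_join(long, hdis, by = c("animal_id", "term"))
}

#' One-row summary of a fitted model
#'
#' @param x A `staterep_fit`.
#' @param ... Unused.
#' @return A tibble with the model, method, animal and trial counts, WAIC
#'   (AIC-style surrogate for MLE fits), its standard error and the
#'   effective number of parameters.
#' @export
glance.staterep_fit <- function(x, ...) {
  tibble(model = x$model, method = x$method,
         n_animals = nrow(x$estimates), n_trials = nrow(x$trial_key),
         waic = x$waic, waic_se = x$waic_se, p_waic = x$p_waic)
}

#' @export
tidy.staterep_comparison <- function(x, ...) x$table

#' @export
tidy.staterep_regression <- function(x, ...) x$group

#' @export
glance.staterep_regression <- function(x, ...) {
  th <- x$group[x$group$term == "n_rewarded_forced", ]
  tibble(method = x$method, theta = th$estimate,
         theta_low = th$hdi_low, theta_high = th$hdi_high,
         excludes_zero = th$hdi_low > 0 | th$hdi_high < 0)
}

#' @export
tidy.staterep_recovery <- function(x, ...) x$summary
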