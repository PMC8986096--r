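# Generic adaptive Metropolis-within-Gibbs sampler for two-level models:
# unit-level parameter vectors theta_u (on unconstrained scales) drawn from
# independent Normal(mu_k, sigma_k) group distributions per coordinate, with
# conjugate Normal / inverse-gamma hyperpriors. Unit likelihoods are supplied
# as closures returning per-observation log-likelihood vectors, so the same
# machinery drives both the RL model fits and the hierarchical logistic
# regression. Proposals are joint random walks per unit, scaled by the
# current group SD and a per-unit step size adapted during warmup toward a
# target acceptance rate.
hier_mh <- function(unit_loglik, n_units, param_names,
                    chains = 4, iter = 2000, warmup = 1500, thin = 1,
                    seed = NULL, init = NULL,
                    prior = list(mu0 = 0, tau0 = 2, a0 = 1, b0 = 0.02),
                    target_accept = 0.25) {
  K <- length(param_names)
  stopifnot(iter > warmup, n_units >= 2)
  if (is.null(init)) init <- matrix(0, n_units, K)
  n_keep <- floor((iter - warmup) / thin)
  all_group <- vector("list", chains)
  all_units <- vector("list", chains)
  all_pw <- vector("list", chains)
  accept_rate <- numeric(chains)

  for (ch in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1L)
    theta <- init + matrix(rnorm(n_units * K, 0, 0.3), n_units, K)
    cur_pw <- lapply(seq_len(n_units), function(u) unit_loglik(u, theta[u, ]))
    cur_tot <- vapply(cur_pw, sum, numeric(1))
    mu <- colMeans(theta)
    sigma2 <- pmax(apply(theta, 2, var), 0.05)
    step <- rep(0.5, n_units)
    g_draws <- matrix(NA_real_, n_keep, 2 * K)
    u_draws <- array(NA_real_, c(n_keep, n_units, K))
    pw_draws <- matrix(NA_real_, n_keep, sum(lengths(cur_pw)))
    n_acc <- 0; n_prop <- 0; kept <- 0L

    for (t in seq_len(iter)) {
      sd_prop <- sqrt(sigma2)
      n_acc_t <- 0
      for (u in seq_len(n_units)) {
        prop <- theta[u, ] + step[u] * rnorm(K) * sd_prop
        pw_new <- unit_loglik(u, prop)
        tot_new <- sum(pw_new)
        logr <- tot_new - cur_tot[u] +
          sum(dnorm(prop, mu, sd_prop, log = TRUE)) -
          sum(dnorm(theta[u, ], mu, sd_prop, log = TRUE))
        if (is.finite(logr) && log(runif(1)) < logr) {
          theta[u, ] <- prop
          cur_pw[[u]] <- pw_new
          cur_tot[u] <- tot_new
          n_acc_t <- n_acc_t + 1
        }
        if (t <= warmup) {
          acc <- min(1, exp(logr))
          if (!is.finite(acc)) acc <- 0
          step[u] <- exp(log(step[u]) + (acc - target_accept) / max(1, t)^0.6)
        }
      }
      n_acc <- n_acc + n_acc_t; n_prop <- n_prop + n_units
      # conjugate group-level updates
      for (k in seq_len(K)) {
        post_var <- 1 / (n_units / sigma2[k] + 1 / prior$tau0^2)
        post_mean <- post_var * (sum(theta[, k]) / sigma2[k] +
                                   prior$mu0 / prior$tau0^2)
        mu[k] <- rnorm(1, post_mean, sqrt(post_var))
        sigma2[k] <- 1 / rgamma(1, prior$a0 + n_units / 2,
                                prior$b0 + 0.5 * sum((theta[, k] - mu[k])^2))
      }
      if (t > warmup && (t - warmup) %% thin == 0) {
        kept <- kept + 1L
        g_draws[kept, ] <- c(mu, sqrt(sigma2))
        u_draws[kept, , ] <- theta
        pw_draws[kept, ] <- unlist(cur_pw)
      }
    }
    colnames(g_draws) <- c(paste0("mu_", param_names),
                           paste0("sigma_", param_names))
    all_group[[ch]] <- g_draws
    all_units[[ch]] <- u_draws
    all_pw[[ch]] <- pw_draws
    accept_rate[ch] <- n_acc / n_prop
  }

  group <- do.call(rbind, all_group)
  units <- do.call(abind1, all_units)
  pointwise <- do.call(rbind, all_pw)
  rhat_group <- apply_rhat(all_group)
  list(group = group, units = units, pointwise = pointwise,
       chain = rep(seq_len(chains), each = n_keep),
       param_names = param_names,
       diagnostics = list(accept_rate = accept_rate, rhat = rhat_group,
                          chains = chains, iter = iter, warmup = warmup))
}

# bind 3-d arrays along the first dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], numeric(1))),
                           d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# split-Rhat per column across a list of per-chain draw matrices
apply_rhat <- function(chain_mats) {
  halves <- list()
  for (m in chain_mats) {
    n <- nrow(m)
    if (n < 4) return(setNames(rep(NA_real_, ncol(m)), colnames(m)))
    halves <- c(halves, list(m[1:(n %/% 2), , drop = FALSE]),
                list(m[(n %/% 2 + 1):n, , drop = FALSE]))
  }
  vapply(seq_len(ncol(chain_mats[[1]])), function(k) {
    x <- vapply(halves, function(h) c(mean(h[, k]), var(h[, k])), numeric(2))
    m <- ncol(x); n <- nrow(halves[[1]])
    B <- n * var(x[1, ])
    W <- mean(x[2, ])
    if (W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1)) |> setNames(colnames(chain_mats[[1]]))
}

#' Hierarchical Bayesian model fitting
#'
#' Fits a model to all animals jointly: each animal's free parameters (on
#' unconstrained scales — logit for \[0,1\]-bounded parameters, log for
#' `beta`, identity for bias and perseveration) are drawn from per-parameter
#' Normal group distributions with weakly-informative conjugate hyperpriors
#' (`mu ~ N(0, tau0^2)`, `sigma^2 ~ Inv-Gamma(a0, b0)`). Sampling uses an
#' adaptive Metropolis-within-Gibbs scheme: joint random-walk proposals per
#' animal with conjugate Gibbs updates of the group mean and variance.
#' Chains are initialized at a cheap per-animal MLE plus chain-specific
#' jitter. Defaults mirror a 4-chain, 2000-iteration, 1500-warmup run;
#' reduced settings are appropriate for desk-scale studies.
#'
#' @param records Trial-record tibble with at least 2 animals.
#' @param model Model name.
#' @param chains,iter,warmup,thin Sampler settings.
#' @param seed Integer seed (each chain offsets it).
#' @param fit_lapse Fit the lapse rate (default) or freeze it at
#'   `lapse_value`.
#' @param lapse_value Fixed lapse when `fit_lapse = FALSE`.
#' @param carry_over Carry values across sessions.
#' @param prior Hyperprior constants (`mu0`, `tau0`, `a0`, `b0`).
#' @return A `staterep_fit` with posterior draws (group level and per
#'   animal, on both scales), pointwise log-likelihood, WAIC and sampler
#'   diagnostics (split-Rhat, acceptance rates). Unconverged chains flag the
#'   diagnostics but still return the result.
#' @export
fit_hierarchical <- function(records, model, chains = 4, iter = 2000,
                             warmup = 1500, thin = 1, seed = NULL,
                             fit_lapse = TRUE, lapse_value = 0,
                             carry_over = FALSE,
                             prior = list(mu0 = 0, tau0 = 2, a0 = 1, b0 = 0.02)) {
  model <- match_model(model)
  if (nrow(records) == 0) abort("empty trial log.")
  animals <- unique(records$animal_id)
  if (length(animals) < 2) abort("hierarchical fitting needs at least 2 animals.")
  pnames <- free_param_names(model, fit_lapse)
  encs <- lapply(animals, function(a)
    encode_records(dplyr::filter(records, .data$animal_id == a)))
  mid <- model_id(model)
  unit_loglik <- function(u, theta) {
    values <- transform_from_unconstrained(theta, pnames)
    pv <- assemble_param_vector(values, pnames, model, lapse_value)
    e <- encs[[u]]
    cpp_trial_probs(mid, pv, e$odor, e$choice, e$valid, e$drops, e$delay,
                    e$new_session, carry_over)$loglik
  }
  # initialize at a cheap per-animal MLE for fast convergence
  init <- with_seed(seed, {
    t(vapply(seq_along(animals), function(u) {
      fit_one_animal_mle(dplyr::filter(records, .data$animal_id == animals[u]),
                         model, pnames, 2, lapse_value, carry_over)$theta
    }, numeric(length(pnames))))
  })
  res <- hier_mh(unit_loglik, length(animals), pnames, chains = chains,
                 iter = iter, warmup = warmup, thin = thin, seed = seed,
                 init = init, prior = prior)
  # posterior-mean estimates per animal on the natural scale
  estimates <- purrr::map_dfr(seq_along(animals), function(u) {
    nat <- t(apply(res$units[, u, , drop = TRUE], 1,
                   transform_from_unconstrained, names = pnames))
    est <- setNames(as.list(colMeans(nat)), pnames)
    est <- as_tibble(est)
    if (model == "hybrid_learning") est$eta_g <- est$eta * est$rho
    dplyr::bind_cols(tibble(animal_id = animals[u]), est)
  })
  ord <- order(match(records$animal_id, animals))
  key <- records[ord, c("animal_id", "session_id", "trial_index")]
  w <- compute_waic(res$pointwise)
  rhat <- res$diagnostics$rhat
  if (any(is.finite(rhat) & rhat > 1.1))
    warn("some group-level split-Rhat values exceed 1.1; chains may not have converged.")
  new_staterep_fit(
    model = model, method = "mcmc",
    estimates = estimates,
    pointwise = res$pointwise, pointwise_ic = w$pointwise,
    trial_key = key,
    waic = w$waic, waic_se = w$waic_se, p_waic = w$p_waic,
    n_params = length(pnames),
    diagnostics = res$diagnostics,
    draws = list(group = res$group, units = res$units, chain = res$chain,
                 animals = animals, param_names = pnames),
    param_names = pnames,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    thin = thin, seed = seed, fit_lapse = fit_lapse,
                    lapse_value = lapse_value, carry_over = carry_over,
                    prior = prior)
  )
}

#' Posterior draws of a group-level parameter on the natural scale
#'
#' Transforms draws of the group mean back through the parameter's link
#' (inverse logit for bounded parameters, exp for `beta`), giving the
#' population-typical value.
#'
#' @param fit A hierarchical `staterep_fit`.
#' @param parameter Free-parameter name (e.g. `"eta"`, `"w4"`, `"rho"`).
#' @return Numeric vector of draws.
#' @export
group_mean_draws <- function(fit, parameter) {
  if (is.null(fit$draws)) abort("not a hierarchical (MCMC) fit.")
  stopifnot(parameter %in% fit$param_names)
  mu <- fit$draws$group[, paste0("mu_", parameter)]
  vapply(mu, transform_from_unconstrained, numeric(1), names = parameter)
}
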