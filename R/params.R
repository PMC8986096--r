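#' Model parameters for the reinforcement-learning models
#'
#' Bundles the free parameters shared by all four models — learning rate
#' `eta`, discount rate `gamma` (applied per second of reward delay), inverse
#' temperature `beta`, side bias `bias` (positive favors right), perseveration
#' `persev` (positive repeats the previous choice) and lapse rate `lapse` —
#' plus the representation parameter of the hybrid models: `w4`, the weight
#' of the four-state value table at decision time (hybrid-value), or `eta_g`,
#' the generalization learning rate applied to the paired same-side state
#' (hybrid-learning, constrained to `eta_g <= eta`).
#'
#' @param model One of `"four_state"`, `"six_state"`, `"hybrid_value"`,
#'   `"hybrid_learning"`.
#' @param eta Learning rate in \[0, 1\].
#' @param gamma Per-second discount rate in \[0, 1\]; a reward of `r` drops
#'   delivered after `d` seconds has learning target `gamma^d * r`.
#' @param beta Inverse temperature, non-negative.
#' @param bias Additive decision-variable bonus for the right side.
#' @param persev Additive bonus for repeating the previous trial's choice.
#' @param lapse Lapse rate in \[0, 1\]: probability of a uniformly random choice.
#' @param w4 Four-state weight in \[0, 1\] (hybrid-value model only).
#' @param eta_g Generalization rate in \[0, eta\] (hybrid-learning model only).
#'
#' @return An object of class `staterep_params`.
#' @examples
#' model_params("six_state", eta = 0.25, beta = 3)
#' model_params("hybrid_value", eta = 0.25, beta = 3, w4 = 0.3)
#' @export
model_params <- function(model, eta = 0.25, gamma = 0.8, beta = 3,
                         bias = 0, persev = 0, lapse = 0,
                         w4 = NULL, eta_g = NULL) {
  model <- match_model(model)
  stopifnot(is.numeric(eta), length(eta) == 1, eta >= 0, eta <= 1)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1)
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0)
  stopifnot(is.numeric(lapse), length(lapse) == 1, lapse >= 0, lapse <= 1)
  if (model == "hybrid_value") {
    if (is.null(w4)) abort("hybrid_value requires `w4`.")
    if (w4 < 0 || w4 > 1) abort("`w4` must lie in [0, 1].")
  } else if (!is.null(w4)) {
    abort("`w4` is only a parameter of the hybrid_value model.")
  }
  if (model == "hybrid_learning") {
    if (is.null(eta_g)) abort("hybrid_learning requires `eta_g`.")
    if (eta_g < 0 || eta_g > eta)
      abort("`eta_g` must lie in [0, eta].")
  } else if (!is.null(eta_g)) {
    abort("`eta_g` is only a parameter of the hybrid_learning model.")
  }
  structure(
    list(model = model, eta = eta, gamma = gamma, beta = beta,
         bias = bias, persev = persev, lapse = lapse,
         w4 = w4, eta_g = eta_g),
    class = "staterep_params"
  )
}

#' @export
print.staterep_params <- function(x, ...) {
  cat("<staterep_params>", x$model, "\n")
  vals <- param_vector(x)
  keep <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
            x$model == "hybrid_value", x$model == "hybrid_learning")
  print(round(vals[keep], 4))
  invisible(x)
}

# fixed-order numeric vector for the C++ core:
# eta, gamma, beta, b, p, lambda, w4, eta_g
param_vector <- function(params) {
  stopifnot(inherits(params, "staterep_params"))
  c(eta = params$eta, gamma = params$gamma, beta = params$beta,
    b = params$bias, p = params$persev, lambda = params$lapse,
    w4 = params$w4 %||% 0, eta_g = params$eta_g %||% 0)
}

# names of the free parameters of a model (lapse optional in fitting)
free_param_names <- function(model, fit_lapse = TRUE) {
  model <- match_model(model)
  base <- c("eta", "gamma", "beta", "bias", "persev")
  if (fit_lapse) base <- c(base, "lapse")
  switch(model,
    four_state = base,
    six_state = base,
    hybrid_value = c(base, "w4"),
    # rho = eta_g / eta, so eta_g <= eta holds by construction
    hybrid_learning = c(base, "rho")
  )
}
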