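#' Plot block-aligned learning curves
#'
#' Accuracy for forced- and free-choice trials over the first and last
#' trials of each block, with s.e.m. ribbons across animals.
#'
#' @param object A [compute_learning_curves()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staterep_curves <- function(object, ...) {
  df <- dplyr::mutate(object,
                      side = ifelse(.data$offset > 0, "start", "end"),
                      x = ifelse(.data$offset > 0, .data$offset,
                                 .data$offset))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$accuracy,
                                   color = .data$trial_type)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$accuracy - .data$sem,
                   ymax = .data$accuracy + .data$sem,
                   fill = .data$trial_type),
      alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(~ .data$block_index + .data$side,
                        scales = "free_x") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "trial relative to block boundary", y = "accuracy",
                  color = "trial type", fill = "trial type") +
    ggplot2::ylim(0, 1)
}

#' Plot a parameter-recovery study
#'
#' True vs recovered scatter per parameter with the identity line.
#'
#' @param object A [recovery_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staterep_recovery <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free") +
    ggplot2::labs(title = paste("Parameter recovery:", object$model),
                  x = "true", y = "recovered")
}

#' Plot WAIC differences against the baseline model
#'
#' @param object A [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staterep_comparison <- function(object, ...) {
  df <- dplyr::filter(object$table, .data$model != object$baseline)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$delta_waic)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta_waic - .data$se_delta,
                   ymax = .data$delta_waic + .data$se_delta), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(y = paste("WAIC difference vs", object$baseline), x = NULL)
}

#' Plot reward earned against the four-state weight
#'
#' @param object A [reward_vs_w4()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staterep_reward_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$w4, y = .data$mean_reward)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_reward - .data$sem,
                   ymax = .data$mean_reward + .data$sem),
      alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "four-state weight w4",
                  y = "mean reward per trial (drops)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
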