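#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ensemble selection curve
#'
#' Best-so-far selection lower bound across candidate models, with a ribbon
#' showing the up-to-the-point cumulative standard deviation of the
#' per-model criterion.
#'
#' @param object An `ensemble_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ensemble_result <- function(object, ...) {
  cv <- object$curve
  cv$cum_sd[is.na(cv$cum_sd)] <- 0
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$model, y = .data$best_so_far)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$best_so_far - .data$cum_sd,
                                      ymax = .data$best_so_far + .data$cum_sd),
                         alpha = 0.2) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "models built", y = "best selection lower bound",
                  title = "Ensemble model selection") +
    ggplot2::theme_minimal()
}

#' Plot an action-frequency comparison
#'
#' Side-by-side clinician vs AI action counts per dimension and bin.
#'
#' @param object An `action_frequency_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.action_frequency_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("clinician_n", "ai_n"),
                              names_to = "policy", values_to = "n")
  long$policy <- ifelse(long$policy == "ai_n", "AI", "clinician")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$bin), y = .data$n,
                                     fill = .data$policy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~dimension, scales = "free_y") +
    ggplot2::labs(x = "action bin", y = "decision instances") +
    ggplot2::theme_minimal()
}

#' Plot per-step action-change rates
#'
#' @param object An `action_change_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.action_change_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_step, c("clinician_rel", "ai_rel"),
                              names_to = "policy", values_to = "rate")
  long$policy <- ifelse(long$policy == "ai_rel", "AI", "clinician")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$rate,
                                     colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "4-h time step", y = "relative action changes") +
    ggplot2::theme_minimal()
}

#' Plot out-of-bag feature importance
#'
#' @param object A `feature_importance_result`.
#' @param top_n Show the top features per dimension.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_importance_result <- function(object, top_n = 15, ...) {
  imp <- dplyr::filter(object$importance, .data$rank <= top_n)
  ggplot2::ggplot(imp, ggplot2::aes(x = stats::reorder(.data$feature,
                                                       .data$weight),
                                    y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~dimension, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative OOB importance") +
    ggplot2::theme_minimal()
}

#' Plot a return-versus-mortality curve
#'
#' @param curve Output of [return_vs_mortality()].
#' @return A ggplot.
#' @export
plot_return_mortality <- function(curve) {
  cv <- dplyr::filter(curve, !.data$empty)
  mid <- (cv$return_lo + cv$return_hi) / 2
  cv$mid <- mid
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$mid, y = .data$mortality)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "performance return", y = "observed mortality") +
    ggplot2::theme_minimal()
}
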