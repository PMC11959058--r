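#' Plot the steady-state concentration profiles of a simulation
#'
#' @param object a `sweat_simulation` object.
#' @param ... unused.
#' @return A ggplot: concentration versus position for the ISF and gland
#'   domains (free x scales; the two domains differ in length by two orders
#'   of magnitude).
#' @export
autoplot.sweat_simulation <- function(object, ...) {
  df <- tidy.sweat_simulation(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y * 1e3, y = .data$C)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~compartment, scales = "free_x") +
    ggplot2::labs(x = "position (mm)", y = "urea concentration (mmol/L)",
                  title = sprintf("blood %.3g -> sweat %.3g mmol/L",
                                  object$C_blood, object$C_sweat)) +
    ggplot2::theme_minimal()
}

#' Plot the error trace of a double-loop estimation
#'
#' @param object a `sweat_estimate` object.
#' @param ... unused.
#' @return A ggplot of the running best squared error per outer iteration
#'   (log scale).
#' @export
autoplot.sweat_estimate <- function(object, ...) {
  df <- tidy.sweat_estimate(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = pmax(.data$error, 1e-30))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "outer iteration",
                  y = expression(squared~error~(mmol^2 ~ L^-2)),
                  title = sprintf("final estimate %.3g mmol/L (%s mode)",
                                  object$C_blood_final, object$mode)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of estimated versus measured blood urea
#'
#' @param estimates tibble with `C_blood_est`, `blood_urea_mmol_per_L` and
#'   `timepoint`.
#' @return A ggplot with the identity line.
#' @export
plot_estimates <- function(estimates) {
  df <- dplyr::filter(tibble::as_tibble(estimates),
                      !is.na(.data$C_blood_est),
                      !is.na(.data$blood_urea_mmol_per_L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$blood_urea_mmol_per_L,
                                   y = .data$C_blood_est,
                                   colour = .data$timepoint)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "measured blood urea (mmol/L)",
                  y = "estimated blood urea (mmol/L)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of estimated versus measured blood urea
#'
#' @param estimates tibble with `C_blood_est`, `blood_urea_mmol_per_L` and
#'   `timepoint`.
#' @return A ggplot of difference against mean with bias and 95% limits of
#'   agreement as dashed lines.
#' @export
plot_bland_altman <- function(estimates) {
  df <- dplyr::filter(tibble::as_tibble(estimates),
                      !is.na(.data$C_blood_est),
                      !is.na(.data$blood_urea_mmol_per_L))
  ba <- bland_altman(df$C_blood_est, df$blood_urea_mmol_per_L)
  df <- dplyr::mutate(df,
                      avg = (.data$C_blood_est +
                               .data$blood_urea_mmol_per_L) / 2,
                      diff = .data$C_blood_est - .data$blood_urea_mmol_per_L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff,
                                   colour = .data$timepoint)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$loa_lo, ba$loa_hi),
                        linetype = c(1, 2, 2), colour = "grey40") +
    ggplot2::labs(x = "mean of estimate and measurement (mmol/L)",
                  y = "estimate - measurement (mmol/L)") +
    ggplot2::theme_minimal()
}

#' Bar chart of parameter-perturbation sensitivity
#'
#' @param sens a tibble from [sensitivity_analysis()].
#' @return A ggplot of output CV per perturbed parameter.
#' @export
plot_sensitivity <- function(sens) {
  ggplot2::ggplot(sens,
                  ggplot2::aes(x = stats::reorder(.data$parameter,
                                                  .data$cv_output),
                               y = .data$cv_output)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "CV of simulated sweat urea (%)") +
    ggplot2::theme_minimal()
}
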