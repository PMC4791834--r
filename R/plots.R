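#' Density plot of within- versus between-complex correlations
#'
#' @param correlations A [within_between_correlations()] result.
#' @return A ggplot object.
#' @export
plot_coexpression <- function(correlations) {
  correlations %>%
    dplyr::mutate(pair_type = ifelse(.data$same_complex,
                                     "same complex", "different complexes")) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$r, fill = .data$pair_type)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "Pearson correlation", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a decoy benchmark
#'
#' Variable-member counts against the number of conditions analysed, for the
#' real resource and the decoy mean with a +/- 3 SD ribbon.
#'
#' @param bench A [decoy_benchmark()] result.
#' @return A ggplot object.
#' @export
plot_decoy_benchmark <- function(bench) {
  ggplot2::ggplot(bench, ggplot2::aes(x = .data$n_conditions)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$decoy_mean - 3 * .data$decoy_sd,
      ymax = .data$decoy_mean + 3 * .data$decoy_sd
    ), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$decoy_mean), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$real_variable_count),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$real_variable_count),
                        colour = "firebrick") +
    ggplot2::labs(x = "conditions analysed", y = "variable members",
                  title = "Real complexes (red) vs decoy null (grey)") +
    ggplot2::theme_minimal()
}

#' Accuracy-versus-size plot for a signature evaluation
#'
#' @param object A [feature_sampling_eval()] result.
#' @param ... Unused.
#' @return A ggplot object (mean accuracy with standard-error bars, per
#'   feature pool).
#' @export
autoplot.signature_eval <- function(object, ...) {
  object$draws %>%
    dplyr::group_by(.data$size, .data$pool) %>%
    dplyr::summarise(mean = mean(.data$accuracy),
                     se = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$size, y = .data$mean,
                                 colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::scale_colour_manual(values = c(signature = "firebrick",
                                            random = "grey30")) +
    ggplot2::labs(x = "feature-set size", y = "mean LOO accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
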