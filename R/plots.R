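#' Predicted-confidence curves across the cue grid
#'
#' Plots a model's predicted logit confidence as a function of the logit
#' likelihood, one line per prior level, with the Simple Bayes
#' predictions as a grey reference — the standard way to visualise how
#' weighting and reverberation bend the cue-integration surface.
#'
#' @param model Observer model identifier.
#' @param params Rescaled parameters ([model_params()]).
#' @param levels Cue probability levels to plot.
#' @return A ggplot object.
#' @examples
#' plot_model_curves("CINI", model_params(0.8, 0.06, 0.02, 0.05))
#' @export
plot_model_curves <- function(model, params = model_params(),
                              levels = seq(0.1, 0.9, by = 0.1)) {
  grid <- tidyr::expand_grid(prior_p = levels, like_p = levels) |>
    dplyr::mutate(
      L_p = logit(.data$prior_p),
      L_s = logit(.data$like_p)
    )
  grid$prediction <- predict_confidence(grid, model, params)
  grid$sb <- predict_confidence(grid, "SB")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$L_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sb, group = .data$prior_p),
                       colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$prediction,
                                    colour = factor(.data$prior_p))) +
    ggplot2::labs(
      x = "Logit likelihood", y = "Predicted logit confidence",
      colour = "Prior", title = model
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn parameter_recovery Generating-vs-recovered scatter per
#'   parameter.
#' @param object A `cf_recovery` object.
#' @method autoplot cf_recovery
#' @export
autoplot.cf_recovery <- function(object, ...) {
  long <- object$draws |>
    dplyr::mutate(.sim = dplyr::row_number()) |>
    tidyr::pivot_longer(-".sim",
                        names_to = c("role", "parameter"),
                        names_pattern = "(gen|rec)_(.*)") |>
    tidyr::pivot_wider(names_from = "role", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gen, y = .data$rec)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Generating (rescaled)", y = "Recovered (rescaled)",
                  title = sprintf("Parameter recovery: %s", object$model)) +
    ggplot2::theme_minimal()
}

#' @describeIn model_recovery Heat-map of the confusion matrix.
#' @param object A `cf_confusion` object.
#' @param ... Unused.
#' @method autoplot cf_confusion
#' @export
autoplot.cf_confusion <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$recovered, y = .data$simulated,
                                    fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey40", high = "firebrick") +
    ggplot2::labs(x = "Recovered model", y = "Simulated model") +
    ggplot2::theme_minimal()
}
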