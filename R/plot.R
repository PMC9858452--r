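#' Plot digestograms
#'
#' Digestion extent versus time, one line per replicate, faceted by sample.
#'
#' @param d Digestogram tibble.
#' @return A ggplot object.
#' @export
plot_digestogram <- function(d) {
  d <- as_tibble(d)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$value,
                                  group = .data$replicate,
                                  colour = factor(.data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ sample_id) +
    ggplot2::labs(x = "Time (min)",
                  y = if (all(d$basis == "PERCENT_STARCH"))
                        "Starch digested (%)" else "Normalized reducing sugar",
                  colour = "Replicate") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_digestogram Autoplot method for a fitted kinetics
#'   model: observed points with the fitted curve overlaid.
#' @param object A `kinetics_fit`.
#' @param ... Unused.
#' @method autoplot kinetics_fit
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  obs <- object$data
  grid <- tibble(time_min = seq(0, max(obs$time_min), length.out = 200))
  grid$value <- predict(object, grid$time_min)
  ggplot2::ggplot(obs, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Time (min)", y = "Digestion extent",
                  title = sprintf("%s fit (R² = %.3f)", object$model,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_digestogram Autoplot method for a LOS result:
#'   log-slope points and, when present, the fitted linear segments.
#' @method autoplot los_result
#' @export
autoplot.los_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$points, ggplot2::aes(.data$t_mid, .data$ln_slope)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "ln(dC/dt)", title = "LOS plot") +
    ggplot2::theme_minimal()
  if (nrow(object$segments)) {
    seg <- object$segments %>%
      mutate(y_start = .data$intercept + .data$slope * .data$t_start,
             y_end = .data$intercept + .data$slope * .data$t_end)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                   y = .data$y_start, yend = .data$y_end),
      colour = "firebrick", inherit.aes = FALSE)
  }
  p
}

#' @describeIn plot_digestogram Autoplot method for a calibration model:
#'   calibration points with the fitted GI line.
#' @method autoplot gi_calibration
#' @export
autoplot.gi_calibration <- function(object, ...) {
  if (is.null(object$lm)) {
    abort("No calibration data stored; plot requires a model from fit_calibration().")
  }
  df <- tibble(aucr180 = object$lm$model$x, gi = object$lm$model$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$aucr180, .data$gi)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "AUCR180", y = "Clinical GI",
                  title = sprintf("GI = %.3f + %.4g × AUCR180 (R² = %.3f)",
                                  object$intercept, object$slope,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}
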