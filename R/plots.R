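# ggplot2 layers for the result objects. Calibration plots mirror the
# conventional observed-vs-predicted scatter with the identity line and
# dotted 25% under/over-estimation bands, on a linear or logarithmic scale.

#' Calibration scatter of a validation report
#'
#' @param object A `mur_calibration` (one variant of a [validate()] result).
#' @param scale `"linear"` or `"log"` axes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mur_calibration
#' @export
autoplot.mur_calibration <- function(object, scale = c("linear", "log"),
                                     ...) {
  scale <- match.arg(scale)
  tab <- object$table
  if (scale == "log") {
    tab <- tab |> filter(.data$observed > 0, .data$predicted > 0)
  }
  band <- object$band
  p <- ggplot(tab, aes(x = .data$observed, y = .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    geom_abline(slope = 1 - band, intercept = 0, colour = "red",
                linetype = "dotted") +
    geom_abline(slope = 1 + band, intercept = 0, colour = "red",
                linetype = "dotted") +
    geom_point(alpha = 0.7) +
    labs(
      x = sprintf("Observed rate per 10,000 (%s)", object$mode),
      y = sprintf("Predicted rate per 10,000 (%s)", object$variant),
      title = if (is.na(object$r2)) "Calibration"
              else sprintf("Calibration: R2 = %.2f, %d/%d within %.0f%%",
                           object$r2, object$n_within_25pct,
                           object$n_events - object$n_undefined, 100 * band)
    )
  if (scale == "log") {
    p <- p + scale_x_log10() + scale_y_log10()
  }
  p
}

#' Variable-importance bar chart of a fitted tree
#'
#' @param object A `mur_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mur_tree
#' @export
autoplot.mur_tree <- function(object, ...) {
  vi <- variable_importance(object)
  ggplot(vi, aes(x = stats::reorder(.data$variable, .data$importance),
                 y = .data$importance)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Variable importance (%)",
         title = sprintf("Tree for '%s' (%d terminal nodes)",
                         object$outcome, object$n_terminal))
}

#' Daily temperature fit of the reference event
#'
#' @param object A `mur_linfit` together with its observations.
#' @param observations The day-level table the fit was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_temperature_fit <- function(object, observations, ...) {
  tcol <- object$which
  ggplot(observations, aes(x = .data[[tcol]], y = .data$ppr_day)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "blue") +
    labs(x = sprintf("%s (deg C)", tcol), y = "Daily PPR per 10,000",
         title = sprintf("slope %.1f PPR/degC, R2 = %.2f, p = %.3g",
                         object$slope, object$r2, object$p_slope))
}
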