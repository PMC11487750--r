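# ggplot2 displays for the main result types.

#' Hypnogram-aligned relative band power
#'
#' Tile display of per-epoch relative PSD by band with the stage sequence
#' along the top, the usual way sleep spectral summaries are inspected.
#'
#' @param features Long tibble from [compute_band_features()].
#' @return A ggplot object.
#' @export
plot_band_features <- function(features) {
  ggplot(features, aes(x = .data$epoch_index, y = .data$band, fill = .data$rel_psd)) +
    geom_tile() +
    scale_fill_viridis_c(name = "relative\nPSD (%)", na.value = "grey85") +
    labs(x = "30-s epoch", y = NULL,
         title = "Relative power spectral density per epoch") +
    theme_minimal()
}

#' Detected half-waves over the detection signal
#'
#' Plots a window of the smoothed detection signal with descending
#' zero-crossings and troughs of the detected waves.
#'
#' @param x Smoothed, filtered signal (the one passed to
#'   [detect_halfwaves()]).
#' @param fs Sampling rate (Hz).
#' @param halfwaves Detection tibble from [detect_halfwaves()].
#' @param t_lim Length-2 window in seconds (default first 30 s).
#' @return A ggplot object.
#' @export
plot_halfwaves <- function(x, fs, halfwaves, t_lim = c(0, 30)) {
  t <- (seq_along(x) - 1) / fs
  keep <- t >= t_lim[1] & t <= t_lim[2]
  hw <- filter(halfwaves, .data$t_trough >= t_lim[1], .data$t_trough <= t_lim[2])
  ggplot(tibble(t = t[keep], x = x[keep]), aes(.data$t, .data$x)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line(linewidth = 0.3) +
    geom_point(data = hw, aes(.data$t_zero_cross, 0), colour = "red", size = 1.5) +
    geom_point(data = hw, aes(.data$t_trough, .data$trough_amp, colour = .data$band),
               size = 1.5) +
    geom_segment(data = hw,
                 aes(x = .data$t_zero_cross, y = 0, xend = .data$t_trough,
                     yend = .data$trough_amp, colour = .data$band),
                 linetype = "dashed") +
    labs(x = "time (s)", y = expression(paste("amplitude (", mu, "V)")),
         colour = "band", title = "Slow-wave negative half-wave detections") +
    theme_minimal()
}

#' Forest plot of per-SD model coefficients
#'
#' @param object A `swa_ols` fit.
#' @param drop_intercept Hide the intercept row (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swa_ols <- function(object, drop_intercept = TRUE, ...) {
  tt <- tidy(object)
  if (drop_intercept) tt <- filter(tt, .data$term != "(Intercept)")
  ggplot(tt, aes(x = .data$estimate, y = stats::reorder(.data$term, .data$estimate))) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_pointrange(aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    labs(x = "coefficient (95% CI)", y = NULL,
         title = paste("Association model:", object$outcome)) +
    theme_minimal()
}

#' Predicted accumulation at feature quantiles
#'
#' @param pred Tibble from [predict_at_quantiles()].
#' @param feature_label Axis label for the feature.
#' @return A ggplot object.
#' @export
plot_quantile_predictions <- function(pred, feature_label = "feature quantile") {
  ggplot(pred, aes(x = factor(.data$quantile), y = .data$predicted)) +
    geom_col(fill = "steelblue") +
    labs(x = feature_label, y = "predicted annualized accumulation",
         title = "Model-predicted accumulation at feature quantiles") +
    theme_minimal()
}
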