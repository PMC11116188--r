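# Report figures: radial profiles, volume-impedance regression panels,
# confusion heat maps, modality comparison bars.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_text
#'   geom_col geom_smooth facet_wrap labs scale_fill_gradient theme_minimal
#'   position_dodge autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a radial intensity profile
#' @param object A `cyto_radial_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyto_radial_profile <- function(object, ...) {
  ggplot(object[!is.na(object$mean_intensity), ],
         aes(x = .data$radius_px, y = .data$mean_intensity)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "radius from centre [px]", y = "mean difference intensity",
         title = "Radial intensity profile") +
    theme_minimal()
}

#' Volume vs peak intensity regression panels
#'
#' Log-log scatter of peak intensity against optical volume with the fitted
#' regression line, one panel per frequency.
#'
#' @param events Fused events (columns `vol_um3` and `pi_*`).
#' @return A ggplot.
#' @export
plot_regression_panels <- function(events) {
  cols <- grep("^pi_", names(events), value = TRUE)
  long <- tidyr::pivot_longer(as_tibble(events)[, c("vol_um3", cols)],
                              dplyr::all_of(cols),
                              names_to = "frequency", values_to = "pi")
  long <- long[long$pi > 0 & long$vol_um3 > 0, ]
  long$frequency <- factor(long$frequency, levels = cols)
  ggplot(long, aes(x = log10(.data$vol_um3), y = log10(.data$pi))) +
    geom_point(alpha = 0.4, size = 0.7) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.5) +
    facet_wrap(~frequency, nrow = 2) +
    labs(x = "log10 volume [um^3]", y = "log10 peak intensity") +
    theme_minimal()
}

#' Confusion-matrix heat map
#' @param object A `cyto_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyto_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted class", y = "true class",
         title = sprintf("accuracy %.1f%% (n = %d)",
                         100 * object$accuracy, object$n)) +
    theme_minimal()
}

#' Modality comparison accuracy bars
#' @param object A `cyto_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyto_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("mode", "frequency_set", "train_acc", "test_acc")],
    c("train_acc", "test_acc"), names_to = "split", values_to = "accuracy")
  long$mode <- factor(long$mode, levels = c("electrical", "optical", "multimodal"))
  ggplot(long, aes(x = .data$mode, y = .data$accuracy, fill = .data$split)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~.data$frequency_set) +
    labs(x = NULL, y = "accuracy", title = "Modality comparison") +
    theme_minimal()
}
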