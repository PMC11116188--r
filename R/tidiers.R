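# broom-style tidiers for fitted objects

#' @describeIn regress_vol_pi Tidy coefficient table of the log-log fit.
#' @param x A `cyto_regression`.
#' @param ... Unused.
#' @export
tidy.cyto_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "log10(vol_um3)"),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @describeIn regress_vol_pi One-row model summary.
#' @export
glance.cyto_regression <- function(x, ...) {
  tibble(frequency_hz = x$frequency_hz, r.squared = x$r_squared,
         slope = x$slope, intercept = x$intercept, n = x$n, log_base = x$log_base)
}

#' @describeIn evaluate_predictions Per-class metric rows.
#' @param x A `cyto_eval`.
#' @param ... Unused.
#' @export
tidy.cyto_eval <- function(x, ...) x$metrics

#' @describeIn evaluate_predictions One-row summary (overall accuracy, n).
#' @export
glance.cyto_eval <- function(x, ...) tibble(accuracy = x$accuracy, n = x$n)

#' @describeIn train_fine_tree Node table of the fitted tree.
#' @param x A `cyto_tree`.
#' @param ... Unused.
#' @export
tidy.cyto_tree <- function(x, ...) rpart_node_table(x$fit)

#' @describeIn train_fine_tree One-row fit summary.
#' @export
glance.cyto_tree <- function(x, ...) {
  tibble(n_splits = n_internal_splits(x$fit), max_splits = x$max_splits,
         cv_acc = x$cv_acc, cv_folds = x$cv_folds, n_train = x$n_train)
}
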