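# Fusing optical and electrical events in time, feature tables, and the
# volume-impedance regression validation.

#' Match optical and electrical events in time
#'
#' One-to-one greedy pairing by nearest time offset: candidate pairs within
#' `tolerance_s` are accepted in order of increasing `|dt|`, each event used
#' at most once. Unmatched events of either modality are reported, never
#' silently dropped. The pairing is symmetric in the two inputs.
#'
#' @param optical_events,electrical_events Event tibbles with `event_id` and
#'   `time_s`, time-sorted.
#' @param tolerance_s Maximum |time offset| of an accepted pair.
#' @return List of class `cyto_match` with tibbles `matched`
#'   (`optical_event_id`, `electrical_event_id`, `time_offset_s`),
#'   `unmatched_optical`, `unmatched_electrical`.
#' @export
match_events <- function(optical_events, electrical_events, tolerance_s = 0.05) {
  to <- optical_events$time_s
  te <- electrical_events$time_s
  pairs <- tidyr::expand_grid(i = seq_along(to), j = seq_along(te))
  pairs$dt <- te[pairs$j] - to[pairs$i]
  pairs <- pairs[abs(pairs$dt) <= tolerance_s, ]
  pairs <- pairs[order(abs(pairs$dt), pairs$i, pairs$j), ]
  used_o <- logical(length(to)); used_e <- logical(length(te))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_o[i] && !used_e[j]) {
      keep[k] <- TRUE; used_o[i] <- TRUE; used_e[j] <- TRUE
    }
  }
  m <- pairs[keep, ]
  matched <- tibble(
    optical_event_id = optical_events$event_id[m$i],
    electrical_event_id = electrical_events$event_id[m$j],
    time_optical_s = to[m$i], time_electrical_s = te[m$j],
    time_offset_s = m$dt)
  matched <- matched[order(matched$time_optical_s), ]
  structure(list(
    matched = matched,
    unmatched_optical = optical_events[!used_o, ],
    unmatched_electrical = electrical_events[!used_e, ]),
    class = "cyto_match")
}

#' @export
print.cyto_match <- function(x, ...) {
  cat(sprintf("<cyto_match>: %d matched, %d optical-only, %d electrical-only\n",
              nrow(x$matched), nrow(x$unmatched_optical),
              nrow(x$unmatched_electrical)))
  invisible(x)
}

#' Fuse optical and electrical events into multimodal rows
#'
#' Matches the two event streams in time and joins volume, velocity and the
#' per-frequency peak intensities into one row per multimodal event. If a
#' ground-truth table is supplied (synthetic runs), each event is labelled
#' with the class of the nearest true transit within the tolerance.
#'
#' @param optical_events,electrical_events Event tibbles.
#' @param truth Optional ground-truth tibble (`transit_time_s`, `class_id`).
#' @param tolerance_s Matching tolerance, seconds.
#' @param run_id Provenance label attached to every row.
#' @return Tibble with `vol_um3`, `vel_um_s`, `pi_*` columns, `label`
#'   (integer or `NA`), `time_offset_s`, `run_id`.
#' @export
fuse_events <- function(optical_events, electrical_events, truth = NULL,
                        tolerance_s = 0.05, run_id = "run-1") {
  mt <- match_events(optical_events, electrical_events, tolerance_s)
  m <- mt$matched
  oe <- optical_events[match(m$optical_event_id, optical_events$event_id), ]
  ee <- electrical_events[match(m$electrical_event_id, electrical_events$event_id), ]
  pi_cols <- grep("^pi_", names(ee), value = TRUE)
  out <- dplyr::bind_cols(
    tibble(event_id = seq_len(nrow(m)),
           time_s = m$time_optical_s,
           time_offset_s = m$time_offset_s,
           vol_um3 = oe$total_volume_um3,
           vel_um_s = oe$velocity_um_s),
    ee[, pi_cols])
  out$label <- NA_integer_
  if (!is.null(truth) && nrow(truth) && nrow(out)) {
    nearest <- vapply(out$time_s, function(tt) {
      k <- which.min(abs(truth$transit_time_s - tt))
      if (abs(truth$transit_time_s[k] - tt) <= tolerance_s) truth$class_id[k]
      else NA_integer_
    }, integer(1))
    out$label <- nearest
  }
  out$run_id <- run_id
  attr(out, "match") <- mt
  out
}

#' Build a feature table for classification
#'
#' Selects the feature columns for one modality: `"electrical"` uses the
#' peak intensities at the chosen frequencies, `"optical"` the particle
#' volume, `"multimodal"` both. Only complete cases are kept.
#'
#' @param events Fused event tibble from [fuse_events()] (rows may also come
#'   from several runs bound together).
#' @param mode One of `"electrical"`, `"optical"`, `"multimodal"`.
#' @param frequencies_hz Frequencies whose peak intensities enter the table;
#'   e.g. `500e3` (single representative frequency) or all eight. Ignored for
#'   `mode = "optical"`.
#' @param include_velocity Add the velocity column as a feature.
#' @return Tibble of class `cyto_features` with the selected feature columns
#'   plus `label` and `run_id`; feature column names in the
#'   `"feature_cols"` attribute, the mode in `"mode"`.
#' @export
build_feature_table <- function(events,
                                mode = c("multimodal", "electrical", "optical"),
                                frequencies_hz = NULL,
                                include_velocity = FALSE) {
  mode <- match.arg(mode)
  # volume first: CART engines resolve exact split ties by column order, and
  # among training-equivalent splits the optical volume is the drift-robust
  # choice (impedance gain varies run to run)
  feat <- if (mode %in% c("optical", "multimodal")) "vol_um3" else character()
  if (mode %in% c("electrical", "multimodal")) {
    have <- grep("^pi_", names(events), value = TRUE)
    want <- if (is.null(frequencies_hz)) have else pi_label(frequencies_hz)
    missing_f <- setdiff(want, have)
    if (length(missing_f)) {
      abort(sprintf("requested frequencies absent from events: %s",
                    paste(missing_f, collapse = ", ")))
    }
    feat <- c(feat, want)
  }
  if (include_velocity) {
    if (!"vel_um_s" %in% names(events)) abort("no velocity column in events.")
    feat <- c(feat, "vel_um_s")
  }
  keep_cols <- c(feat, intersect(c("label", "run_id"), names(events)))
  tab <- as_tibble(events)[, keep_cols]
  cc <- stats::complete.cases(tab[, feat])
  dropped <- sum(!cc)
  tab <- tab[cc, ]
  structure(tab, class = c("cyto_features", class(tibble())),
            feature_cols = feat, mode = mode, n_dropped = dropped)
}

#' Log-log regression of peak intensity on volume
#'
#' Ordinary least squares of `log10(PI)` on `log10(VOL)` at one frequency,
#' the standard validation that optical volume and impedance peak intensity
#' follow a power law.
#'
#' @param events Tibble with `vol_um3` and the requested `pi_*` column
#'   (fused events or a multimodal feature table).
#' @param frequency_hz Frequency whose peak intensity is regressed.
#' @return Object of class `cyto_regression` with `frequency_hz`, `slope`,
#'   `intercept`, `r_squared`, `n`, `log_base = 10` and the underlying `lm`
#'   fit. Supports [tidy()] and [glance()].
#' @export
regress_vol_pi <- function(events, frequency_hz) {
  col <- pi_label(frequency_hz)
  if (!col %in% names(events)) {
    abort(sprintf("column %s absent from events.", col))
  }
  vol <- events$vol_um3
  pi_v <- events[[col]]
  ok <- !is.na(vol) & !is.na(pi_v)
  vol <- vol[ok]; pi_v <- pi_v[ok]
  if (length(vol) < 2L) abort("need at least 2 events for the regression.")
  if (any(vol <= 0) || any(pi_v <= 0)) {
    abort("volumes and peak intensities must be positive for the log-log fit.")
  }
  dat <- tibble(lv = log10(vol), lp = log10(pi_v))
  fit <- lm(lp ~ lv, data = dat)
  # exact power-law inputs make summary() warn about a perfect fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(frequency_hz = frequency_hz,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n = nrow(dat), log_base = 10, fit = fit),
            class = "cyto_regression")
}

#' @export
print.cyto_regression <- function(x, ...) {
  cat(sprintf("<cyto_regression> %g kHz: log10(PI) = %.3f + %.3f log10(VOL), R^2 = %.3f (n = %d)\n",
              x$frequency_hz / 1e3, x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Per-frequency regression summary
#'
#' Runs [regress_vol_pi()] at every frequency present and returns one tidy
#' row per frequency. Events whose peak intensity at a given frequency is not
#' positive (weak transits swamped by baseline residue in that channel) are
#' excluded from that frequency's fit, since the log-log regression is only
#' defined for positive values.
#'
#' @param events Fused events / multimodal feature table.
#' @return Tibble with `frequency_hz`, `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_all_frequencies <- function(events) {
  cols <- grep("^pi_", names(events), value = TRUE)
  freqs <- as.numeric(sub("pi_([0-9.]+)kHz", "\\1", cols)) * 1e3
  purrr::map_dfr(seq_along(freqs), function(i) {
    f <- freqs[i]
    ok <- !is.na(events[[cols[i]]]) & events[[cols[i]]] > 0 &
      !is.na(events$vol_um3) & events$vol_um3 > 0
    r <- regress_vol_pi(events[ok, ], f)
    tibble(frequency_hz = f, slope = r$slope, intercept = r$intercept,
           r_squared = r$r_squared, n = r$n)
  })
}

#' Does velocity add explanatory power?
#'
#' Compares the coefficient of determination of the base `log10(PI) ~
#' log10(VOL)` regression with a two-predictor fit adding velocity.
#'
#' @param events Tibble with `vol_um3`, `vel_um_s` and the `pi_*` column.
#' @param frequency_hz Frequency of interest.
#' @return Tibble with `frequency_hz`, `r2_base`, `r2_with_velocity` and
#'   their difference `increment`.
#' @export
velocity_increment <- function(events, frequency_hz) {
  if (!"vel_um_s" %in% names(events)) abort("no `vel_um_s` column in events.")
  col <- pi_label(frequency_hz)
  ok <- !is.na(events$vol_um3) & !is.na(events[[col]]) & !is.na(events$vel_um_s) &
    events$vol_um3 > 0 & events[[col]] > 0
  dat <- tibble(lv = log10(events$vol_um3[ok]),
                lp = log10(events[[col]][ok]),
                vel = events$vel_um_s[ok])
  base <- suppressWarnings(summary(lm(lp ~ lv, data = dat))$r.squared)
  with_v <- suppressWarnings(summary(lm(lp ~ lv + vel, data = dat))$r.squared)
  tibble(frequency_hz = frequency_hz, r2_base = base,
         r2_with_velocity = with_v, increment = with_v - base)
}
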