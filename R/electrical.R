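# Impedance trace handling: baseline normalization, prominence-based peak
# calling, per-frequency peak intensity extraction.

amp_cols <- function(trace) grep("^amp_", names(trace), value = TRUE)

#' Normalize an impedance trace to its baseline
#'
#' Maps each channel to `(Z - Z0) / Z0` where `Z0` is a rolling-median
#' baseline (default window 1 s), robust to transit pulses and slow drift.
#' Constant channels map to all-zero. A trace already carrying the
#' `"normalized"` units flag is returned unchanged (idempotent).
#'
#' @param trace Tibble with `time_s` and `amp_*` channel columns.
#' @param window_s Baseline window, seconds.
#' @return The normalized trace (units attribute `"normalized"`).
#' @export
normalize_trace <- function(trace, window_s = 1) {
  if (identical(attr(trace, "units"), "normalized")) return(trace)
  cols <- amp_cols(trace)
  if (!length(cols)) abort("no `amp_*` channel columns in trace.")
  sr <- 1 / median(diff(trace$time_s))
  k <- odd_window(window_s * sr)
  k <- min(k, odd_window(nrow(trace) - 2L))
  for (cn in cols) {
    x <- trace[[cn]]
    z0 <- stats::runmed(x, k, endrule = "median")
    if (any(z0 <= 0)) abort(sprintf("non-positive baseline in channel %s.", cn))
    trace[[cn]] <- (x - z0) / z0
  }
  attr(trace, "units") <- "normalized"
  trace
}

# robust noise scale of a (detrended) channel from first differences
robust_sigma <- function(x) mad(diff(x)) / sqrt(2)

# topographic prominence of peaks at indices `pk` in signal x
peak_prominence <- function(x, pk) {
  vapply(pk, function(i) {
    h <- x[i]
    left <- if (i > 1L) {
      seg <- x[(i - 1L):1L]
      higher <- which(seg > h)
      if (length(higher)) min(seg[seq_len(higher[1] - 1L)]) else min(seg)
    } else h
    right <- if (i < length(x)) {
      seg <- x[(i + 1L):length(x)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[seq_len(higher[1] - 1L)]) else min(seg)
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Detect transit peaks on a normalized trace
#'
#' Local maxima on the reference channel (lowest frequency by default) with
#' topographic prominence at least `prominence_k` times the robust noise
#' scale (MAD of first differences), at least `min_separation_s` apart.
#' Candidates discarded by the separation rule flag the surviving peak as
#' `"merged"`. For each event the peak intensity at every frequency is the
#' maximum of that channel within `+-width_s` of the reference peak time.
#'
#' @param trace Normalized trace (see [normalize_trace()]).
#' @param reference_frequency_hz Channel used for timing; default the lowest.
#' @param prominence_k Prominence threshold in units of the noise scale.
#' @param min_separation_s Minimum peak separation, seconds.
#' @param width_s Half-width of the per-channel intensity search window.
#' @param polarity `"positive"` (impedance increases during transit) or
#'   `"negative"` (the channel is sign-flipped before detection).
#'
#' @return Tibble of class `cyto_electrical_events`: `event_id`, `time_s`,
#'   one `pi_*` column per frequency, `prominence`, `width_s`,
#'   `quality_flags`.
#' @export
detect_peaks <- function(trace, reference_frequency_hz = NULL,
                         prominence_k = 5, min_separation_s = 0.05,
                         width_s = 0.03, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!identical(attr(trace, "units"), "normalized")) {
    abort("`trace` must be normalized first (see normalize_trace()).")
  }
  cols <- amp_cols(trace)
  freqs_khz <- as.numeric(sub("amp_([0-9.]+)kHz", "\\1", cols))
  ref_hz <- reference_frequency_hz %||% (min(freqs_khz) * 1e3)
  ref_col <- freq_label(ref_hz)
  if (!ref_col %in% cols) {
    abort(sprintf("reference frequency %g Hz not present in trace.", ref_hz))
  }
  t <- trace$time_s
  x <- trace[[ref_col]]
  if (polarity == "negative") x <- -x
  sigma <- robust_sigma(x)
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  # height gate on a short-window detrended copy (removes residual baseline
  # curvature): peaks must rise k sigma above the LOCAL baseline; topographic
  # prominence below then rejects shoulder artefacts. In white noise the
  # prominence of a local maximum is inflated by the depth of far-away
  # valleys, so the local height gate is what controls the false-positive
  # rate.
  k_short <- min(odd_window(0.15 * length(x) / (max(t) - t[1])),
                 odd_window(n - 2L))
  xd <- x - stats::runmed(x, k_short, endrule = "median")
  cand <- cand[xd[cand] >= prominence_k * sigma]
  empty <- structure(
    tibble(event_id = integer(), time_s = numeric()) |>
      dplyr::bind_cols(as_tibble(stats::setNames(
        as.list(rep(list(numeric()), length(cols))), pi_label(freqs_khz * 1e3)))) |>
      dplyr::bind_cols(tibble(prominence = numeric(), width_s = numeric(),
                              quality_flags = character())),
    class = c("cyto_electrical_events", class(tibble())))
  if (!length(cand)) return(empty)
  prom <- peak_prominence(x, cand)
  keep <- prom >= prominence_k * sigma
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # enforce separation: strongest first; dropped neighbours mark the keeper
  ord <- order(x[cand], decreasing = TRUE)
  kept <- integer(); merged <- logical()
  for (i in ord) {
    dt <- abs(t[cand[i]] - t[cand[kept]])
    if (!length(kept) || all(dt >= min_separation_s)) {
      kept <- c(kept, i); merged <- c(merged, FALSE)
    } else {
      merged[which.min(dt)] <- TRUE
    }
  }
  o <- order(cand[kept])
  idx <- cand[kept][o]
  prom <- prom[kept][o]
  merged <- merged[o]

  # per-frequency peak intensity within +-width_s of each reference peak,
  # measured above the local sideband baseline (median of the surrounding
  # +-3 width_s annulus) so that residual baseline curvature cancels
  nch <- length(cols)
  pi_mat <- matrix(NA_real_, length(idx), nch)
  half_w <- numeric(length(idx))
  for (e in seq_along(idx)) {
    tp <- t[idx[e]]
    win <- which(t >= tp - width_s & t <= tp + width_s)
    left <- which(t >= tp - 3 * width_s & t < tp - width_s)
    right <- which(t > tp + width_s & t <= tp + 3 * width_s)
    for (j in seq_len(nch)) {
      ch <- trace[[cols[j]]]
      # local baseline: the cleaner (lower-median) sideband, so that a
      # neighbouring transit sitting in one sideband cannot bias the height
      meds <- c(if (length(left)) median(ch[left]),
                if (length(right)) median(ch[right]))
      base_j <- if (length(meds)) min(meds) else 0
      pi_mat[e, j] <- max(ch[win]) - base_j
    }
    # full width at half maximum on the reference channel, interpolated
    half <- x[idx[e]] / 2
    li <- idx[e]; while (li > 1L && x[li] > half) li <- li - 1L
    ri <- idx[e]; while (ri < n && x[ri] > half) ri <- ri + 1L
    tl <- if (x[li] <= half && li < idx[e]) {
      t[li] + (half - x[li]) / (x[li + 1L] - x[li]) * (t[li + 1L] - t[li])
    } else t[li]
    tr_ <- if (x[ri] <= half && ri > idx[e]) {
      t[ri - 1L] + (x[ri - 1L] - half) / (x[ri - 1L] - x[ri]) * (t[ri] - t[ri - 1L])
    } else t[ri]
    half_w[e] <- tr_ - tl
  }
  colnames(pi_mat) <- pi_label(freqs_khz * 1e3)
  out <- dplyr::bind_cols(
    tibble(event_id = seq_along(idx), time_s = t[idx]),
    as_tibble(pi_mat),
    tibble(prominence = prom, width_s = half_w,
           quality_flags = ifelse(merged, "merged", "")))
  structure(out, class = c("cyto_electrical_events", class(tibble())))
}

#' Average peak intensity across frequencies
#'
#' Arithmetic mean of the per-frequency peak intensities of each event.
#'
#' @param events A `cyto_electrical_events` tibble.
#' @return Numeric vector, one value per event.
#' @export
average_pi <- function(events) {
  cols <- grep("^pi_", names(events), value = TRUE)
  if (!length(cols)) abort("no `pi_*` columns in events.")
  rowMeans(as.matrix(events[, cols]))
}
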