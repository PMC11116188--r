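# Optical sizing: rolling background, difference image, threshold
# segmentation, centroid, radial intensity profile, half-maximum diameter,
# sphere volume, aggregates and velocity.

#' Rolling background model
#'
#' Pixelwise arithmetic mean of the frames preceding `anchor_index`. The
#' standard window is the 50 previous frames; in lenient mode (the default)
#' anchors with a shorter history fall back to all available previous frames
#' provided at least `min_window` exist.
#'
#' @param frames rows x cols x n array of frames.
#' @param anchor_index Index of the frame the background applies to.
#' @param window Number of previous frames to average (default 50).
#' @param min_window Minimum acceptable history in lenient mode.
#' @param strict If `TRUE`, require the full `window` of history.
#'
#' @return An object of class `cyto_background` with elements `image`,
#'   `window` (frames actually averaged) and `anchor_index`.
#' @export
compute_background <- function(frames, anchor_index, window = 50L,
                               min_window = 10L, strict = FALSE) {
  if (length(dim(frames)) != 3L) abort("`frames` must be a 3-d array.")
  avail <- as.integer(anchor_index) - 1L
  if (strict && avail < window) {
    abort(sprintf("insufficient history: %d frames before anchor, %d required.",
                  avail, window))
  }
  use <- as.integer(min(window, avail))
  if (use < min_window) {
    abort(sprintf("insufficient history: %d frames before anchor, need >= %d.",
                  avail, min_window))
  }
  idx <- (anchor_index - use):(anchor_index - 1L)
  img <- rowSums(frames[, , idx, drop = FALSE], dims = 2L) / use
  structure(list(image = img, window = use, anchor_index = anchor_index),
            class = "cyto_background")
}

#' Absolute difference image
#'
#' @param frame Numeric matrix.
#' @param background A `cyto_background` or a plain matrix.
#' @return Non-negative matrix `|frame - background|`.
#' @export
difference_image <- function(frame, background) {
  bg <- if (inherits(background, "cyto_background")) background$image else background
  if (!all(dim(frame) == dim(bg))) abort("frame/background shape mismatch.")
  abs(frame - bg)
}

# 8-connectivity labeling by frontier BFS over the foreground pixels.
# Returns a list of integer matrices (row, col), one per component.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  remaining <- mask
  fg <- which(mask)
  comps <- list()
  while (length(fg)) {
    fg <- fg[remaining[fg]]
    if (!length(fg)) break
    seedpix <- fg[1]
    remaining[seedpix] <- FALSE
    members <- seedpix
    frontier <- seedpix
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nbr_r <- c(r - 1L, r - 1L, r - 1L, r, r, r + 1L, r + 1L, r + 1L)
      nbr_c <- c(c - 1L, c, c + 1L, c - 1L, c + 1L, c - 1L, c, c + 1L)
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      idx <- unique((nbr_c[ok] - 1L) * nr + nbr_r[ok])
      idx <- idx[remaining[idx]]
      remaining[idx] <- FALSE
      members <- c(members, idx)
      frontier <- idx
    }
    comps[[length(comps) + 1L]] <-
      cbind(row = ((members - 1L) %% nr) + 1L,
            col = ((members - 1L) %/% nr) + 1L)
  }
  comps
}

#' Segment particles in a difference image
#'
#' Thresholds the difference image inside the region of interest and returns
#' the 8-connected components as a tibble, smallest speckles removed.
#' Components whose pixels touch the ROI border are flagged, since their
#' extent (and hence any diameter read from them) is unreliable.
#'
#' @param diff Difference image matrix.
#' @param threshold Intensity threshold (> 0); pixels strictly above it are
#'   particle candidates.
#' @param roi ROI list as in [acquisition_config()]; `NULL` uses the full
#'   frame.
#' @param min_area_px Minimum component area kept.
#'
#' @return Tibble with one row per component: `component_id`, `area_px`,
#'   `touches_border`, and a `pixels` list-column of (row, col) matrices.
#' @export
segment_particles <- function(diff, threshold, roi = NULL, min_area_px = 4L) {
  if (!is_scalar_num(threshold) || threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  mask <- diff > threshold
  if (!is.null(roi)) {
    keep <- matrix(FALSE, nrow(diff), ncol(diff))
    keep[roi$row[1]:roi$row[2], roi$col[1]:roi$col[2]] <- TRUE
    mask <- mask & keep
  }
  comps <- label_components8(mask)
  comps <- comps[vapply(comps, nrow, 1L) >= min_area_px]
  if (!length(comps)) {
    return(tibble(component_id = integer(), area_px = integer(),
                  touches_border = logical(), pixels = list()))
  }
  border <- function(p) {
    if (is.null(roi)) {
      any(p[, 1] == 1L | p[, 1] == nrow(diff) |
          p[, 2] == 1L | p[, 2] == ncol(diff))
    } else {
      any(p[, 1] <= roi$row[1] | p[, 1] >= roi$row[2] |
          p[, 2] <= roi$col[1] | p[, 2] >= roi$col[2])
    }
  }
  tibble(component_id = seq_along(comps),
         area_px = vapply(comps, nrow, 1L),
         touches_border = vapply(comps, border, TRUE),
         pixels = comps)
}

#' Auto-select an intensity threshold for a difference image
#'
#' Background-noise median plus `k` times the median absolute deviation,
#' computed inside the ROI.
#'
#' @param diff Difference image.
#' @param roi Optional ROI.
#' @param k MAD multiplier (default 5).
#' @return A positive scalar threshold.
#' @export
auto_threshold <- function(diff, roi = NULL, k = 5) {
  v <- if (is.null(roi)) diff else
    diff[roi$row[1]:roi$row[2], roi$col[1]:roi$col[2]]
  max(median(v) + k * mad(v), 1e-6)
}

#' Particle centre from marked pixels
#'
#' Unweighted mean of the row and column coordinates of the component's
#' pixels; optionally intensity-weighted by the difference image.
#'
#' @param pixels (row, col) matrix of marked pixels, or a logical mask matrix.
#' @param diff Difference image (needed only for `weighted = TRUE`).
#' @param weighted Intensity-weighted centroid instead of the plain average.
#' @return Named numeric `c(row, col)`, sub-pixel.
#' @export
locate_center <- function(pixels, diff = NULL, weighted = FALSE) {
  if (is.logical(pixels) && is.matrix(pixels)) {
    pixels <- which(pixels, arr.ind = TRUE)
    colnames(pixels) <- c("row", "col")
  }
  if (!nrow(pixels)) abort("empty mask: no marked pixels.")
  if (weighted) {
    if (is.null(diff)) abort("`diff` required for weighted centroid.")
    w <- diff[pixels]
    c(row = sum(pixels[, 1] * w) / sum(w), col = sum(pixels[, 2] * w) / sum(w))
  } else {
    c(row = mean(pixels[, 1]), col = mean(pixels[, 2]))
  }
}

#' Radial intensity profile around a centre
#'
#' Average difference-image intensity as a function of distance from the
#' (sub-pixel) centre, in bins of `bin_width_px`. Bins with no pixels carry
#' `NA` and are excluded by downstream read-offs.
#'
#' @param diff Difference image.
#' @param center `c(row, col)` sub-pixel centre.
#' @param max_radius_px Largest radius binned.
#' @param bin_width_px Bin width, pixels.
#' @return Tibble of class `cyto_radial_profile` with `radius_px`,
#'   `mean_intensity` and `n_px` per bin, radii starting at 0.
#' @export
radial_profile <- function(diff, center, max_radius_px, bin_width_px = 1) {
  if (max_radius_px <= 0) abort("`max_radius_px` must be > 0.")
  nr <- nrow(diff); nc <- ncol(diff)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    abort("`center` must lie inside the image.")
  }
  r0 <- max(1L, floor(center[1] - max_radius_px))
  r1 <- min(nr, ceiling(center[1] + max_radius_px))
  c0 <- max(1L, floor(center[2] - max_radius_px))
  c1 <- min(nc, ceiling(center[2] + max_radius_px))
  rr <- r0:r1; cc <- c0:c1
  dist <- sqrt(outer((rr - center[1])^2, (cc - center[2])^2, "+"))
  bin <- round(dist / bin_width_px)
  nbin <- round(max_radius_px / bin_width_px)
  keep <- bin <= nbin
  vals <- diff[rr, cc, drop = FALSE][keep]
  binv <- bin[keep]
  sums <- tapply(vals, binv, sum)
  cnts <- tapply(vals, binv, length)
  out <- tibble(radius_px = (0:nbin) * bin_width_px,
                mean_intensity = NA_real_, n_px = 0L)
  at <- as.integer(names(sums)) + 1L
  out$mean_intensity[at] <- as.numeric(sums / cnts)
  out$n_px[at] <- as.integer(cnts)
  class(out) <- c("cyto_radial_profile", class(out))
  out
}

#' Diameter from a radial profile
#'
#' Reads the particle diameter off the radial intensity profile as twice the
#' outer radius at which the profile first falls below half of its peak value,
#' with linear interpolation between bins. Profiles without a clear peak above
#' the noise floor (peak < `noise_floor_k` times the profile median) signal
#' "no particle".
#'
#' Reported diameters honour the camera's resolution: the interpolated edge
#' radius selects the nearest point of the `resolution_px` pixel grid, so
#' estimates land on an (approximately) one-pixel diameter grid, as a
#' pixel-limited camera delivers. Set `resolution_px = 0` for the raw
#' sub-pixel read-off.
#'
#' @param profile A `cyto_radial_profile`.
#' @param pixel_size_um Pixel size, micrometres.
#' @param noise_floor_k Peak-to-floor ratio below which the profile is
#'   considered particle-free.
#' @param resolution_px Grid (in pixels) on which reported diameters lie;
#'   0 disables the snap.
#' @return Diameter in micrometres.
#' @export
estimate_diameter <- function(profile, pixel_size_um, noise_floor_k = 3,
                              resolution_px = 1) {
  pr <- profile[!is.na(profile$mean_intensity), ]
  if (!nrow(pr)) abort("no particle: empty profile.")
  v <- pr$mean_intensity
  r <- pr$radius_px
  peak <- max(v)
  floor_est <- max(median(v), 1e-9)
  if (peak <= 0 || peak < noise_floor_k * floor_est) {
    abort("no particle: profile peak not above noise floor.")
  }
  ip <- which.max(v)
  half <- peak / 2
  below <- which(v[seq(ip, length(v))] < half)
  if (!length(below)) abort("no particle: profile never falls below half-maximum.")
  j <- ip + below[1] - 1L            # first bin below half, after the peak
  frac <- (v[j - 1L] - half) / (v[j - 1L] - v[j])
  r_edge <- r[j - 1L] + frac * (r[j] - r[j - 1L])
  d_px <- 2 * r_edge
  if (resolution_px > 0) d_px <- round(d_px / resolution_px) * resolution_px
  d_px * pixel_size_um
}

#' Sphere volume from diameter
#'
#' `V = (pi/6) d^3`, equivalently `4/3 pi r^3` with `r = d/2`. Vectorized.
#'
#' @param diameter_um Diameter(s), micrometres.
#' @return Volume(s), cubic micrometres.
#' @examples
#' compute_volume(2)   # 4*pi/3
#' @export
compute_volume <- function(diameter_um) {
  if (any(diameter_um < 0)) abort("diameter must be >= 0.")
  sphere_volume_um3(diameter_um)
}

#' Transit velocity from a centre track
#'
#' Mean frame-to-frame centroid displacement converted to micrometres per
#' second. Single-frame tracks return `NA` (velocity undefined).
#'
#' @param track Data frame with `row`, `col` per tracked frame, time-ordered.
#' @param timestamps Frame timestamps, seconds; must be strictly increasing.
#' @param pixel_size_um Pixel size, micrometres.
#' @return Velocity in micrometres per second, or `NA_real_`.
#' @export
estimate_velocity <- function(track, timestamps, pixel_size_um) {
  if (any(diff(timestamps) <= 0)) abort("timestamps must be strictly increasing.")
  if (nrow(track) < 2L) return(NA_real_)
  steps <- sqrt(diff(track$row)^2 + diff(track$col)^2)
  mean(steps) * pixel_size_um / mean(diff(timestamps))
}

#' Extract optical events from a frame stack
#'
#' Runs the full sizing chain over a stack: rolling background, difference
#' image, threshold segmentation inside the ROI, grouping of consecutive
#' detection frames into events, per-event best-frame selection (largest
#' component fully inside the ROI), per-component diameters from the radial
#' profile, summed sphere volumes, and velocity from the centre track.
#'
#' @param frames rows x cols x n array, or a `cyto_run` (in which case
#'   `frame_times` and `config` are taken from the run).
#' @param frame_times Frame timestamps, seconds.
#' @param config [acquisition_config()].
#' @param threshold Absolute intensity threshold; `NULL` (default) selects
#'   median + 5 MAD of each difference image inside the ROI.
#' @param window,min_window Background history (see [compute_background()]).
#' @param min_area_px Minimum component area.
#'
#' @return Tibble of class `cyto_optical_events`: one row per event with
#'   `event_id`, frame span, `time_s`, `n_components`,
#'   `component_diameters_um` (list), `total_volume_um3`, `velocity_um_s`
#'   and `quality_flags`.
#' @export
extract_optical_events <- function(frames, frame_times = NULL, config = NULL,
                                   threshold = NULL, window = 50L,
                                   min_window = 10L, min_area_px = 4L) {
  if (inherits(frames, "cyto_run")) {
    run <- frames
    frames <- run$frames
    frame_times <- frame_times %||% run$frame_times_s
    config <- config %||% run$config
  }
  if (is.null(config)) abort("`config` is required.")
  if (length(dim(frames)) != 3L) abort("`frames` must be a 3-d array.")
  if (!all(dim(frames)[1:2] == config$frame_shape)) {
    abort("frame shape does not match `config$frame_shape`.")
  }
  n_frames <- dim(frames)[3]
  if (is.null(frame_times)) frame_times <- (seq_len(n_frames) - 1L) / config$fps
  if (n_frames < min_window + 1L) abort("need more frames than the background window.")
  roi <- config$roi
  px <- config$pixel_size_um

  # rolling background by running sum over the trailing <= `window` frames
  detections <- vector("list", n_frames)
  bg_sum <- matrix(0, config$frame_shape[1], config$frame_shape[2])
  n_in <- 0L
  for (i in seq_len(n_frames)) {
    if (n_in >= min_window) {
      bg <- bg_sum / n_in
      d <- abs(frames[, , i] - bg)
      thr <- threshold %||% auto_threshold(d, roi)
      segs <- segment_particles(d, thr, roi, min_area_px)
      if (nrow(segs)) {
        segs$frame <- i
        ctr <- t(vapply(segs$pixels, function(p) locate_center(p), c(row = 0, col = 0)))
        segs$row <- ctr[, 1]; segs$col <- ctr[, 2]
        detections[[i]] <- segs
      }
    }
    bg_sum <- bg_sum + frames[, , i]
    n_in <- n_in + 1L
    if (n_in > window) {
      bg_sum <- bg_sum - frames[, , i - window]
      n_in <- window
    }
  }

  det_frames <- which(!vapply(detections, is.null, TRUE))
  if (!length(det_frames)) {
    return(structure(
      tibble(event_id = integer(), frame_start = integer(),
             frame_end = integer(), best_frame = integer(), time_s = numeric(),
             n_components = integer(), component_diameters_um = list(),
             total_volume_um3 = numeric(), velocity_um_s = numeric(),
             quality_flags = character()),
      class = c("cyto_optical_events", class(tibble()))))
  }
  grp <- cumsum(c(1L, diff(det_frames) > 1L))
  events <- vector("list", max(grp))
  for (g in seq_len(max(grp))) {
    fr <- det_frames[grp == g]
    flags <- character()
    segs <- dplyr::bind_rows(detections[fr])
    # best frame: largest single component fully inside the roi
    inside <- segs[!segs$touches_border, ]
    if (nrow(inside)) {
      best <- inside$frame[which.max(inside$area_px)]
    } else {
      best <- segs$frame[which.max(segs$area_px)]
      flags <- c(flags, "border")
    }
    bsegs <- detections[[best]]
    use <- if (any(!bsegs$touches_border)) bsegs[!bsegs$touches_border, ] else bsegs
    bgb <- compute_background(frames, best, window, min_window)
    dbest <- difference_image(frames[, , best], bgb)
    diams <- numeric(nrow(use))
    okc <- logical(nrow(use))
    for (ci in seq_len(nrow(use))) {
      ctr <- c(row = use$row[ci], col = use$col[ci])
      maxr <- max(sqrt((use$pixels[[ci]][, 1] - ctr[1])^2 +
                       (use$pixels[[ci]][, 2] - ctr[2])^2)) + 4
      prof <- radial_profile(dbest, ctr, max_radius_px = maxr)
      diams[ci] <- tryCatch(estimate_diameter(prof, px),
                            error = function(e) NA_real_)
      okc[ci] <- !is.na(diams[ci])
    }
    if (!all(okc)) flags <- c(flags, "component_sizing_failed")
    diams <- diams[okc]
    # centre track: mean centre over all components per frame
    track <- dplyr::summarise(dplyr::group_by(segs, .data$frame),
                              row = mean(.data$row), col = mean(.data$col),
                              .groups = "drop")
    vel <- if (nrow(track) >= 2L) {
      estimate_velocity(track, frame_times[track$frame], px)
    } else {
      flags <- c(flags, "single_frame")
      NA_real_
    }
    events[[g]] <- tibble(
      frame_start = fr[1], frame_end = fr[length(fr)], best_frame = best,
      time_s = frame_times[best],
      n_components = length(diams),
      component_diameters_um = list(diams),
      total_volume_um3 = sum(sphere_volume_um3(diams)),
      velocity_um_s = vel,
      quality_flags = paste(flags, collapse = ";"))
  }
  out <- dplyr::bind_rows(events)
  out <- out[out$n_components > 0L, ]
  out$event_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "event_id")
  structure(out, class = c("cyto_optical_events", class(tibble())))
}
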