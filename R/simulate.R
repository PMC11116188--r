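# Synthetic acquisition generator: co-registered frame stacks, multi-frequency
# impedance traces and ground truth with the statistical structure the
# downstream analysis assumes.

sphere_volume_um3 <- function(diameter_um) (pi / 6) * diameter_um^3

# static illumination field: smooth, deterministic function of the frame shape
background_field <- function(frame_shape, level) {
  rows <- seq_len(frame_shape[1]); cols <- seq_len(frame_shape[2])
  level +
    outer(5 * rows / frame_shape[1], rep(1, frame_shape[2])) +
    outer(rep(1, frame_shape[1]), 3 * sin(2 * pi * cols / frame_shape[2]))
}

# sample per-event ground truth (diameters, times, kinematics) for one run
sample_truth <- function(config, classes, params, duration_s, t0) {
  n_per <- params$n_events_per_class
  class_ids <- rep(classes$class_id, each = n_per)
  n <- length(class_ids)
  if (n == 0) {
    return(tibble(event_id = integer(), class_id = integer(),
                  transit_time_s = numeric(), n_components = integer(),
                  component_diameters_um = list(),
                  true_total_volume_um3 = numeric(),
                  true_velocity_um_s = numeric()))
  }
  class_ids <- sample(class_ids)
  jit <- runif(n, -0.2, 0.2) * params$event_spacing_s
  times <- t0 + (seq_len(n) - 1L) * params$event_spacing_s + jit
  n_comp <- ifelse(runif(n) < params$aggregate_probability,
                   sample(seq(params$aggregate_size_range[1],
                              params$aggregate_size_range[2]),
                          n, replace = TRUE),
                   1L)
  cls <- classes[match(class_ids, classes$class_id), ]
  comps <- purrr::map(seq_len(n), function(i) {
    runif(n_comp[i], cls$diameter_min_um[i], cls$diameter_max_um[i])
  })
  tibble(
    event_id = seq_len(n),
    class_id = class_ids,
    transit_time_s = times,
    n_components = as.integer(n_comp),
    component_diameters_um = comps,
    true_total_volume_um3 = purrr::map_dbl(comps, ~ sum(sphere_volume_um3(.x))),
    true_velocity_um_s = runif(n, params$velocity_range_um_s[1],
                               params$velocity_range_um_s[2])
  )
}

#' Synthesize multi-frequency impedance channels for a set of transits
#'
#' Builds each channel as a unit baseline with slow sinusoidal drift, plus one
#' Gaussian (optionally bipolar) pulse per transit whose amplitude follows
#' `impedance_gain * drift * V^pi_exponent * channel_factor`, corrupted by
#' event-level and per-channel log-normal amplitude noise and additive white
#' noise. With all noise and drift disabled, pulse amplitude is strictly
#' increasing in true volume.
#'
#' @param events Ground-truth tibble with `transit_time_s` and
#'   `true_total_volume_um3` (e.g. the `truth` component of a run).
#' @param config [acquisition_config()].
#' @param params [sim_params()].
#' @param duration_s Trace duration; defaults to the last transit plus 0.5 s.
#' @param seed Seed for this trace's random draws.
#'
#' @return A tibble with `time_s` and one `amp_*` column per frequency (raw,
#'   unnormalized), with the per-event channel amplitudes attached as the
#'   `"amplitudes"` attribute (events x frequencies matrix).
#' @export
synth_trace <- function(events, config, params, duration_s = NULL,
                        seed = params$seed) {
  duration_s <- duration_s %||%
    (if (nrow(events)) max(events$transit_time_s) + 0.5 else 1)
  if (duration_s <= 0) abort("trace duration must be positive.")
  if (nrow(events) && any(events$transit_time_s < 0 |
                          events$transit_time_s > duration_s)) {
    abort("event times must lie within the trace duration.")
  }
  sr <- config$sample_rate_hz
  n <- floor(duration_s * sr)
  t <- (seq_len(n) - 1L) / sr
  freqs <- config$frequencies_hz
  nf <- length(freqs)
  chan_factor <- 1 + 0.04 * (seq_len(nf) - 1L)
  sigma_p <- params$pulse_fwhm_s / (2 * sqrt(2 * log(2)))

  withr::with_seed(seed, {
    run_gain <- params$impedance_gain *
      exp(rnorm(1, 0, params$gain_drift_sd))
    phase <- runif(1, 0, 2 * pi)
    drift <- params$baseline_drift_amp *
      sin(2 * pi * t / params$baseline_drift_period_s + phase)
    ne <- nrow(events)
    shared <- if (ne) exp(rnorm(ne, 0, params$pi_noise_sdlog)) else numeric()
    chan_noise <- if (ne) {
      matrix(exp(rnorm(ne * nf, 0, params$channel_noise_sdlog)), ne, nf)
    } else matrix(numeric(), 0, nf)
    amp <- if (ne) {
      (run_gain * events$true_total_volume_um3^params$pi_exponent * shared) *
        chan_noise * rep(chan_factor, each = max(ne, 1L))
    } else matrix(numeric(), 0, nf)

    channels <- matrix(rep(1 + drift, nf), n, nf)
    if (ne) {
      for (i in seq_len(ne)) {
        ti <- events$transit_time_s[i]
        idx <- which(t >= ti - 4.5 * sigma_p & t <= ti + 4.5 * sigma_p)
        if (!length(idx)) next
        u <- (t[idx] - ti) / sigma_p
        kern <- if (params$bipolar_pulse) -u * exp(0.5) * exp(-u^2 / 2) else exp(-u^2 / 2)
        channels[idx, ] <- channels[idx, ] + outer(kern, amp[i, ])
      }
    }
    if (params$impedance_noise_sd > 0) {
      channels <- channels +
        matrix(rnorm(n * nf, 0, params$impedance_noise_sd), n, nf)
    }
    colnames(channels) <- freq_label(freqs)
    out <- dplyr::bind_cols(tibble(time_s = t), as_tibble(channels))
    attr(out, "units") <- "raw"
    attr(out, "amplitudes") <- amp
    out
  })
}

#' Generate a complete synthetic acquisition run
#'
#' Produces a co-registered frame stack, multi-frequency impedance trace and
#' per-event ground truth for a mixed population of the four particle classes.
#' Each transit appears in the frames as a bright ring of the correct pixel
#' diameter (blurred, noisy, moving at the event's velocity over the frames
#' nearest the transit time) and in every impedance channel as a pulse at the
#' transit time. Aggregates are rendered as adjacent rings and as a single
#' summed-amplitude impedance pulse. Identical inputs and seed give a
#' bit-identical run.
#'
#' @param config [acquisition_config()].
#' @param classes Class table from [class_specs()].
#' @param params [sim_params()].
#' @param run_id Character label carried through to feature provenance.
#'
#' @return An object of class `cyto_run`: a list with `config`, `params`,
#'   `classes`, `frames` (rows x cols x n_frames array), `frame_times_s`,
#'   `trace` (raw tibble), `truth` (tibble, sorted by transit time) and
#'   `run_id`.
#' @examples
#' run <- generate_run(params = sim_params(n_events_per_class = 2, seed = 7))
#' run$truth$class_id
#' @export
generate_run <- function(config = acquisition_config(),
                         classes = class_specs(),
                         params = sim_params(),
                         run_id = "run-1") {
  if (anyDuplicated(classes$class_id)) abort("duplicate `class_id` in classes.")
  n_total <- nrow(classes) * params$n_events_per_class
  t0 <- 0.5
  duration_s <- t0 + max(1L, n_total) * params$event_spacing_s + 0.4
  seeds <- derive_seeds(params$seed, 3L)

  truth <- withr::with_seed(seeds[1], {
    tr <- sample_truth(config, classes, params, duration_s, t0)
    dplyr::arrange(tr, .data$transit_time_s)
  })
  truth$event_id <- seq_len(nrow(truth))

  n_frames <- floor(duration_s * config$fps)
  frame_times <- (seq_len(n_frames) - 1L) / config$fps
  bg <- background_field(config$frame_shape, params$background_level)
  frames <- array(bg, dim = c(config$frame_shape, n_frames))

  px <- config$pixel_size_um
  roi <- config$roi
  row_c <- mean(roi$row)
  col_c <- mean(roi$col)

  truth <- withr::with_seed(seeds[2], {
    traj <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      ev_t <- truth$transit_time_s[i]
      diam_px <- truth$component_diameters_um[[i]] / px
      # apparent (defocused) diameters actually rendered, clamped to +-4 px
      app_px <- diam_px + clamp(rnorm(length(diam_px), 0, params$defocus_sd_px),
                                -4, 4)
      app_px <- pmax(app_px, 2)
      amp <- pmax(20, rnorm(length(diam_px), params$ring_amplitude,
                            params$ring_amplitude_sd))
      v_px <- truth$true_velocity_um_s[i] / px      # px per second, along cols
      rowc <- clamp(row_c + runif(1, -3, 3),
                    1 + max(app_px) / 2 + 1, config$frame_shape[1] - max(app_px) / 2 - 1)
      colc <- col_c + runif(1, -4, 4)
      # component offsets: adjacent, non-overlapping rings along the row axis
      k <- length(diam_px)
      offs <- rep(0, k)
      if (k > 1) {
        gaps <- (app_px[-k] + app_px[-1]) / 2 + 8
        offs <- cumsum(c(0, gaps))
        offs <- offs - mean(offs)
      }
      k0 <- which.min(abs(frame_times - ev_t))
      f_idx <- intersect((k0 - 1L):(k0 + 1L), seq_len(n_frames))
      steps <- purrr::map(f_idx, function(fi) {
        dt <- frame_times[fi] - ev_t
        tibble(frame = fi, time_s = frame_times[fi],
               row = rowc + offs, col = colc + v_px * dt,
               diameter_px = app_px, amplitude = amp,
               ring_width_px = params$ring_width_px)
      })
      traj[[i]] <- dplyr::bind_rows(steps)
    }
    truth$trajectory <- traj
    truth
  })

  # paint all particles, then one noise pass over the whole stack
  for (i in seq_len(nrow(truth))) {
    tr <- truth$trajectory[[i]]
    for (fi in unique(tr$frame)) {
      frames[, , fi] <- add_particles(frames[, , fi], tr[tr$frame == fi, ],
                                      params$psf_sigma_px)
    }
  }
  if (params$optical_noise_sd > 0) {
    withr::with_seed(derive_seeds(seeds[2], 1L), {
      np <- prod(config$frame_shape)
      for (fi in seq_len(n_frames)) {
        frames[, , fi] <- frames[, , fi] + rnorm(np, 0, params$optical_noise_sd)
      }
    })
  }

  trace <- synth_trace(truth, config, params, duration_s = duration_s,
                       seed = seeds[3])

  structure(
    list(config = config, params = params, classes = classes,
         frames = frames, frame_times_s = frame_times,
         trace = trace, truth = truth, run_id = run_id),
    class = "cyto_run"
  )
}

#' @export
print.cyto_run <- function(x, ...) {
  cat(sprintf("<cyto_run '%s'>: %d events, %d frames (%dx%d), %.1f s trace, %d channels\n",
              x$run_id, nrow(x$truth), dim(x$frames)[3],
              dim(x$frames)[1], dim(x$frames)[2],
              max(x$trace$time_s), length(x$config$frequencies_hz)))
  invisible(x)
}
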