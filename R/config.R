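#' Acquisition configuration
#'
#' Bundles the physical and acquisition constants shared by the simulator and
#' the extraction modules: camera frame rate and pixel size, the impedance
#' sampling rate, and the set of carrier frequencies of the multi-frequency
#' lock-in measurement.
#'
#' Defaults mirror a typical bench setup for combined high-speed imaging and
#' impedance cytometry: 125 frames/s with a 63.75 microsecond exposure, 0.2
#' micrometre pixels, 899 impedance samples per second, and eight carrier
#' frequencies from 100 kHz to 1.75 MHz.
#'
#' @param fps Camera frame rate, frames per second.
#' @param exposure_s Camera exposure time in seconds (metadata only; the
#'   simulator does not model motion blur).
#' @param pixel_size_um Physical size of one pixel, micrometres.
#' @param frame_shape Integer vector `c(rows, cols)` of the frame in pixels.
#' @param roi Region of interest as `list(row = c(min, max), col = c(min, max))`
#'   in 1-based pixel coordinates, inclusive. Defaults to the frame inset by a
#'   small margin.
#' @param sample_rate_hz Impedance sampling rate, samples per second.
#' @param frequencies_hz Strictly increasing vector of carrier frequencies, Hz.
#'
#' @return An object of class `cyto_config`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$frequencies_hz
#' @export
acquisition_config <- function(fps = 125,
                               exposure_s = 63.75e-6,
                               pixel_size_um = 0.2,
                               frame_shape = c(128L, 160L),
                               roi = NULL,
                               sample_rate_hz = 899,
                               frequencies_hz = c(100e3, 250e3, 500e3, 750e3,
                                                  1e6, 1.25e6, 1.5e6, 1.75e6)) {
  stop_if_not_scalar_pos(fps, "fps")
  stop_if_not_scalar_pos(sample_rate_hz, "sample_rate_hz")
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 8L)) {
    abort("`frame_shape` must be two integers (rows, cols), each >= 8.")
  }
  if (length(frequencies_hz) < 1L || any(diff(frequencies_hz) <= 0)) {
    abort("`frequencies_hz` must be strictly increasing with length >= 1.")
  }
  roi <- roi %||% list(row = c(6L, frame_shape[1] - 6L),
                       col = c(8L, frame_shape[2] - 8L))
  roi$row <- as.integer(roi$row)
  roi$col <- as.integer(roi$col)
  if (roi$row[1] < 1L || roi$row[2] > frame_shape[1] ||
      roi$col[1] < 1L || roi$col[2] > frame_shape[2] ||
      roi$row[1] >= roi$row[2] || roi$col[1] >= roi$col[2]) {
    abort("`roi` must lie within `frame_shape` with min < max on both axes.")
  }
  structure(
    list(fps = fps, exposure_s = exposure_s, pixel_size_um = pixel_size_um,
         frame_shape = frame_shape, roi = roi,
         sample_rate_hz = sample_rate_hz, frequencies_hz = frequencies_hz),
    class = "cyto_config"
  )
}

#' @export
print.cyto_config <- function(x, ...) {
  cat("<cyto_config>\n")
  cat(sprintf("  camera: %g fps, %g um/px, frame %d x %d px\n",
              x$fps, x$pixel_size_um, x$frame_shape[1], x$frame_shape[2]))
  cat(sprintf("  roi: rows %d..%d, cols %d..%d\n",
              x$roi$row[1], x$roi$row[2], x$roi$col[1], x$roi$col[2]))
  cat(sprintf("  impedance: %g Sa/s, %d frequencies (%s)\n",
              x$sample_rate_hz, length(x$frequencies_hz),
              paste0(x$frequencies_hz / 1e3, "kHz", collapse = ", ")))
  invisible(x)
}

#' Particle class table
#'
#' The four nominal particle classes used throughout the pipeline: three sizes
#' of magnetic polystyrene beads plus one epithelial breast-cancer cell line,
#' each with its nominal diameter range in micrometres.
#'
#' @param class_id Integer class identifiers.
#' @param name Class names.
#' @param diameter_min_um,diameter_max_um Nominal diameter range, micrometres.
#'
#' @return A tibble with one row per class.
#' @export
class_specs <- function(class_id = 1:4,
                        name = c("bead 2.0-2.9 um", "bead 4.0-4.5 um",
                                 "bead 5.0-5.9 um", "MDA-MB-231 cell"),
                        diameter_min_um = c(2.0, 4.0, 5.0, 15.0),
                        diameter_max_um = c(2.9, 4.5, 5.9, 17.0)) {
  cls <- tibble(class_id = as.integer(class_id), name = name,
                diameter_min_um = diameter_min_um,
                diameter_max_um = diameter_max_um)
  if (anyDuplicated(cls$class_id)) abort("duplicate `class_id` in class table.")
  if (any(cls$diameter_min_um <= 0) ||
      any(cls$diameter_max_um < cls$diameter_min_um)) {
    abort("each class needs 0 < diameter_min_um <= diameter_max_um.")
  }
  cls
}

#' Simulation parameters
#'
#' Tunable knobs of the synthetic acquisition generator. The defaults define
#' the reference study conditions used by the tests and the acceptance script;
#' see the methods vignette for the calibration rationale behind the noise
#' levels.
#'
#' @param n_events_per_class Number of particle transits simulated per class.
#' @param event_spacing_s Mean spacing between consecutive transits, seconds.
#' @param aggregate_probability Probability that a transit is an aggregate of
#'   several particles rather than a single one.
#' @param aggregate_size_range Integer `c(min, max)` number of particles in an
#'   aggregate.
#' @param optical_noise_sd Additive camera noise, grey levels (0-255 scale).
#' @param psf_sigma_px Gaussian point-spread blur applied to rendered
#'   particles, pixels.
#' @param ring_width_px Radial width (Gaussian sigma) of the bright ring a
#'   defocused particle produces in the difference image, pixels.
#' @param ring_amplitude,ring_amplitude_sd Mean and spread of the ring's peak
#'   brightness above background, grey levels.
#' @param defocus_sd_px Standard deviation of the apparent rendered diameter
#'   error, pixels; models particle-to-particle focal depth variation in a
#'   deep channel.
#' @param background_level Mean background illumination, grey levels.
#' @param velocity_range_um_s Uniform band of transit velocities, micrometres
#'   per second; independent of particle class.
#' @param impedance_gain Run-level conversion from particle volume (um^3) to
#'   normalized peak intensity (delta Z / Z0 per um^3).
#' @param pi_exponent Exponent `b` of the peak-intensity/volume power law
#'   `PI = gain * V^b`.
#' @param pi_noise_sdlog Event-level log-normal multiplicative noise on peak
#'   amplitude, shared across frequency channels (sdlog, natural log scale).
#' @param channel_noise_sdlog Additional per-channel log-normal amplitude
#'   noise (sdlog, natural log).
#' @param impedance_noise_sd Additive white noise on each normalized impedance
#'   channel.
#' @param gain_drift_sd Run-to-run log-normal gain drift (sdlog); sampled once
#'   per run, models device-to-device and day-to-day variation.
#' @param baseline_drift_amp Relative amplitude of the slow sinusoidal
#'   baseline drift.
#' @param baseline_drift_period_s Period of the baseline drift, seconds.
#' @param pulse_fwhm_s Full width at half maximum of a transit pulse, seconds.
#' @param bipolar_pulse If `TRUE`, transits are rendered as bipolar
#'   (derivative-of-Gaussian) pulses instead of unipolar Gaussians.
#' @param seed Integer seed; identical parameters and seed give a bit-identical
#'   run.
#'
#' @return An object of class `cyto_sim_params`.
#' @export
sim_params <- function(n_events_per_class = 100L,
                       event_spacing_s = 0.1,
                       aggregate_probability = 0.08,
                       aggregate_size_range = c(2L, 3L),
                       optical_noise_sd = 4,
                       psf_sigma_px = 1.0,
                       ring_width_px = 1.2,
                       ring_amplitude = 120,
                       ring_amplitude_sd = 15,
                       defocus_sd_px = 1.5,
                       background_level = 40,
                       velocity_range_um_s = c(200, 500),
                       impedance_gain = 5e-5,
                       pi_exponent = 1.0,
                       pi_noise_sdlog = 0.52,
                       channel_noise_sdlog = 0.37,
                       impedance_noise_sd = 4e-6,
                       gain_drift_sd = 0.3,
                       baseline_drift_amp = 0.01,
                       baseline_drift_period_s = 20,
                       pulse_fwhm_s = 0.02,
                       bipolar_pulse = FALSE,
                       seed = 1L) {
  p <- list(n_events_per_class = as.integer(n_events_per_class),
            event_spacing_s = event_spacing_s,
            aggregate_probability = aggregate_probability,
            aggregate_size_range = as.integer(aggregate_size_range),
            optical_noise_sd = optical_noise_sd,
            psf_sigma_px = psf_sigma_px,
            ring_width_px = ring_width_px,
            ring_amplitude = ring_amplitude,
            ring_amplitude_sd = ring_amplitude_sd,
            defocus_sd_px = defocus_sd_px,
            background_level = background_level,
            velocity_range_um_s = velocity_range_um_s,
            impedance_gain = impedance_gain,
            pi_exponent = pi_exponent,
            pi_noise_sdlog = pi_noise_sdlog,
            channel_noise_sdlog = channel_noise_sdlog,
            impedance_noise_sd = impedance_noise_sd,
            gain_drift_sd = gain_drift_sd,
            baseline_drift_amp = baseline_drift_amp,
            baseline_drift_period_s = baseline_drift_period_s,
            pulse_fwhm_s = pulse_fwhm_s,
            bipolar_pulse = isTRUE(bipolar_pulse),
            seed = as.integer(seed))
  sds <- c("optical_noise_sd", "ring_amplitude_sd", "defocus_sd_px",
           "pi_noise_sdlog", "channel_noise_sdlog", "impedance_noise_sd",
           "gain_drift_sd")
  for (nm in sds) {
    if (!is_scalar_num(p[[nm]]) || p[[nm]] < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", nm))
    }
  }
  if (p$aggregate_probability < 0 || p$aggregate_probability > 1) {
    abort("`aggregate_probability` must be in [0, 1].")
  }
  if (p$n_events_per_class < 0L) abort("`n_events_per_class` must be >= 0.")
  stop_if_not_scalar_pos(p$pi_exponent, "pi_exponent")
  stop_if_not_scalar_pos(p$pulse_fwhm_s, "pulse_fwhm_s")
  stop_if_not_scalar_pos(p$event_spacing_s, "event_spacing_s")
  if (length(p$aggregate_size_range) != 2L || p$aggregate_size_range[1] < 2L ||
      diff(p$aggregate_size_range) < 0L) {
    abort("`aggregate_size_range` must be integers c(min, max) with min >= 2.")
  }
  structure(p, class = "cyto_sim_params")
}

#' @export
print.cyto_sim_params <- function(x, ...) {
  cat("<cyto_sim_params>\n")
  cat(sprintf("  %d events/class, spacing %g s, aggregates p=%g (%d-%d)\n",
              x$n_events_per_class, x$event_spacing_s, x$aggregate_probability,
              x$aggregate_size_range[1], x$aggregate_size_range[2]))
  cat(sprintf("  optics: noise sd %g, psf %g px, defocus sd %g px\n",
              x$optical_noise_sd, x$psf_sigma_px, x$defocus_sd_px))
  cat(sprintf("  impedance: gain %g, b=%g, noise sdlog %g/%g, drift sd %g\n",
              x$impedance_gain, x$pi_exponent, x$pi_noise_sdlog,
              x$channel_noise_sdlog, x$gain_drift_sd))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
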