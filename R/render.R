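# Frame rendering: defocused particles appear in the difference image as a
# bright ring at the particle boundary. The ring is rendered as a Gaussian
# annulus whose centre radius is pulled inward by 1.1774 * w_eff so that,
# after point-spread blurring, the OUTER half-maximum crossing of the radial
# profile sits exactly at the nominal particle radius. This makes the
# rendered "diameter" and the half-maximum read-off rule of
# [estimate_diameter()] consistent by construction.

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a small patch, zero-padded boundary
blur_patch <- function(patch, sigma) {
  if (sigma <= 0) return(patch)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv_mat <- function(n) {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1L & j <= n
      m[i, j[ok]] <- k[ok]
    }
    m
  }
  cr <- conv_mat(nrow(patch))
  cc <- conv_mat(ncol(patch))
  cr %*% patch %*% t(cc)
}

# annulus offset such that the outer half-max of the blurred ring lies at R
ring_mu_offset <- function(ring_width_px, psf_sigma_px) {
  sqrt(2 * log(2)) * sqrt(ring_width_px^2 + psf_sigma_px^2)
}

# render one particle's ring into a zero patch; returns list(patch, row0, col0)
# row0/col0 are the frame coordinates of patch[1,1]
render_ring_patch <- function(row, col, diameter_px, amplitude,
                              ring_width_px, psf_sigma_px) {
  radius <- diameter_px / 2
  mu <- max(0.5, radius - ring_mu_offset(ring_width_px, psf_sigma_px))
  half <- ceiling(radius + 3 * ring_width_px + 3 * psf_sigma_px + 2)
  r0 <- floor(row) - half
  c0 <- floor(col) - half
  n <- 2L * half + 1L
  rr <- (r0:(r0 + n - 1L)) - row
  cc <- (c0:(c0 + n - 1L)) - col
  dist <- sqrt(outer(rr^2, cc^2, "+"))
  patch <- amplitude * exp(-((dist - mu)^2) / (2 * ring_width_px^2))
  patch <- blur_patch(patch, psf_sigma_px)
  list(patch = patch, row0 = r0, col0 = c0)
}

# add particles into a frame (no noise); shared by render_frame and the
# run generator. particles: data frame with row, col, diameter_px and
# optionally amplitude / ring_width_px.
add_particles <- function(frame, particles, psf_sigma_px,
                          default_amplitude = 120, default_ring_width = 1.2) {
  nr <- nrow(frame); nc <- ncol(frame)
  for (i in seq_len(nrow(particles))) {
    p <- particles[i, ]
    amp <- if ("amplitude" %in% names(particles)) p$amplitude else default_amplitude
    w <- if ("ring_width_px" %in% names(particles)) p$ring_width_px else default_ring_width
    rp <- render_ring_patch(p$row, p$col, p$diameter_px, amp, w, psf_sigma_px)
    rows <- rp$row0:(rp$row0 + nrow(rp$patch) - 1L)
    cols <- rp$col0:(rp$col0 + ncol(rp$patch) - 1L)
    rok <- rows >= 1L & rows <= nr
    cok <- cols >= 1L & cols <= nc
    frame[rows[rok], cols[cok]] <- frame[rows[rok], cols[cok]] +
      rp$patch[rok, cok, drop = FALSE]
  }
  frame
}

#' Render particles onto a background frame
#'
#' Draws each particle as a bright ring (Gaussian annulus at the particle
#' boundary) convolved with a Gaussian point-spread function, adds the result
#' to `background`, and optionally adds white camera noise. The input
#' background is never modified.
#'
#' @param background Numeric matrix, the blank-channel image.
#' @param particles Data frame with one row per particle: columns `row`,
#'   `col` (sub-pixel centre, 1-based) and `diameter_px`; optional `amplitude`
#'   and `ring_width_px` columns override the defaults.
#' @param psf_sigma_px Gaussian blur sigma, pixels.
#' @param noise_sd Additive Gaussian noise standard deviation, grey levels.
#' @param seed Optional seed for the noise draw.
#'
#' @return A numeric matrix of the same shape as `background`.
#' @examples
#' bg <- matrix(40, 64, 64)
#' fr <- render_frame(bg, data.frame(row = 32, col = 32, diameter_px = 14))
#' max(fr - bg) > 0
#' @export
render_frame <- function(background, particles, psf_sigma_px = 1,
                         noise_sd = 0, seed = NULL) {
  if (!is.matrix(background)) abort("`background` must be a matrix.")
  particles <- as.data.frame(particles)
  if (nrow(particles) > 0) {
    if (!all(c("row", "col", "diameter_px") %in% names(particles))) {
      abort("`particles` needs columns row, col, diameter_px.")
    }
    if (any(particles$diameter_px <= 0)) abort("diameters must be > 0.")
    nr <- nrow(background); nc <- ncol(background)
    if (any(particles$row < 1 | particles$row > nr |
            particles$col < 1 | particles$col > nc)) {
      abort("particle centres must lie inside the frame.")
    }
    rad <- particles$diameter_px / 2
    if (any(particles$row - rad < 0.5 | particles$row + rad > nr + 0.5 |
            particles$col - rad < 0.5 | particles$col + rad > nc + 0.5)) {
      abort("particle extends outside the frame.")
    }
  }
  out <- add_particles(background, particles, psf_sigma_px)
  if (noise_sd > 0) {
    noise_fun <- function() {
      out + matrix(rnorm(length(out), 0, noise_sd), nrow(out), ncol(out))
    }
    out <- if (is.null(seed)) noise_fun() else withr::with_seed(seed, noise_fun())
  }
  out
}
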