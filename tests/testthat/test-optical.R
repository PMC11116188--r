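test_that("background model averages the preceding window", {
  f <- array(7, dim = c(8, 8, 55))
  bg <- compute_background(f, anchor_index = 55, window = 50)
  expect_equal(bg$image, matrix(7, 8, 8))
  expect_identical(bg$window, 50L)

  # alternating 0/100 frames: mean of any 50 consecutive is exactly 50
  alt <- array(rep(c(0, 100), length.out = 60 * 16), dim = c(4, 4, 60))
  for (i in seq_len(60)) alt[, , i] <- if (i %% 2) 0 else 100
  bga <- compute_background(alt, anchor_index = 55, window = 50)
  expect_equal(bga$image, matrix(50, 4, 4))

  expect_error(compute_background(f, anchor_index = 3, window = 50,
                                  min_window = 10), "insufficient history")
  expect_error(compute_background(f, anchor_index = 20, window = 50,
                                  strict = TRUE), "insufficient history")
  # lenient fallback uses all available history
  expect_identical(compute_background(f, anchor_index = 20, window = 50)$window, 19L)
})

test_that("difference image equals the elementwise absolute-difference oracle", {
  withr::with_seed(11, {
    for (trial in 1:20) {
      a <- matrix(runif(64, 0, 255), 8, 8)
      b <- matrix(runif(64, 0, 255), 8, 8)
      d <- difference_image(a, b)
      oracle <- matrix(0, 8, 8)
      for (i in 1:8) for (j in 1:8) oracle[i, j] <- abs(a[i, j] - b[i, j])
      expect_equal(d, oracle)
      expect_true(all(d >= 0))
    }
  })
  expect_equal(difference_image(matrix(1, 3, 3), matrix(1, 3, 3)),
               matrix(0, 3, 3))
  expect_error(difference_image(matrix(1, 3, 3), matrix(1, 4, 4)), "mismatch")
})

test_that("segmentation matches flood-fill and igraph component oracles", {
  skip_if_not_installed("igraph")
  withr::with_seed(21, {
    for (trial in 1:40) {
      n <- sample(8:32, 1)
      d <- matrix(runif(n * n, 0, 10), n, n)
      thr <- runif(1, 3, 8)
      segs <- segment_particles(d, thr, min_area_px = 1L)
      mask <- d > thr
      oc <- oracle_components8(mask)
      expect_identical(nrow(segs), length(oc))
      # same pixel partition (compare sorted linear indices per component)
      key <- function(p) paste(sort((p[, 2] - 1) * n + p[, 1]), collapse = ",")
      expect_setequal(vapply(segs$pixels, key, ""), vapply(oc, key, ""))
      # independent second oracle: igraph components over the adjacency graph
      fg <- which(mask)
      if (length(fg) > 1) {
        rc <- cbind((fg - 1) %% n + 1, (fg - 1) %/% n + 1)
        adj <- which(outer(rc[, 1], rc[, 1], function(a, b) abs(a - b)) <= 1 &
                     outer(rc[, 2], rc[, 2], function(a, b) abs(a - b)) <= 1,
                     arr.ind = TRUE)
        adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
        g <- igraph::graph_from_edgelist(cbind(adj), directed = FALSE)
        g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
        expect_identical(nrow(segs),
                         as.integer(igraph::components(g)$no))
      }
    }
  })
})

test_that("segmentation respects threshold, area filter, roi and border flags", {
  d <- matrix(0, 20, 30)
  expect_identical(nrow(segment_particles(d + 0.1, 5)), 0L)
  d[5:8, 5:8] <- 10       # blob 1 (16 px)
  d[5:8, 12:15] <- 10     # blob 2, separated by > 1 background pixel
  segs <- segment_particles(d, 5)
  expect_identical(nrow(segs), 2L)
  expect_identical(sort(segs$area_px), c(16L, 16L))
  # raising the threshold never grows any component (mask nesting)
  s_hi <- segment_particles(d, 9.5, min_area_px = 1L)
  pix <- function(s) unlist(lapply(s$pixels, function(p) (p[, 2] - 1) * 20 + p[, 1]))
  expect_true(all(pix(s_hi) %in% pix(segs)))
  # roi masking + border flag: blob 2 is clipped at the roi edge
  roi <- list(row = c(4L, 10L), col = c(3L, 13L))
  s_roi <- segment_particles(d, 5, roi = roi)
  expect_identical(nrow(s_roi), 2L)
  clipped <- which(s_roi$area_px < 16L)
  expect_true(s_roi$touches_border[clipped])
  expect_false(all(s_roi$touches_border))
  expect_error(segment_particles(d, -1), "positive")
})

test_that("centroid equals the coordinate-averaging oracle", {
  m <- matrix(FALSE, 12, 12); m[5, 7] <- TRUE
  expect_equal(locate_center(m), c(row = 5, col = 7))
  # symmetric ring centres on its own centre
  d <- matrix(0, 41, 41)
  ctr <- c(21, 21)
  for (i in 1:41) for (j in 1:41) {
    r <- sqrt((i - 21)^2 + (j - 21)^2)
    if (abs(r - 8) < 1.2) d[i, j] <- 10
  }
  expect_equal(locate_center(d > 5), c(row = 21, col = 21), tolerance = 1e-9)
  withr::with_seed(4, {
    for (trial in 1:25) {
      pix <- unique(cbind(row = sample(1:30, 17, TRUE), col = sample(1:30, 17, TRUE)))
      got <- locate_center(pix)
      expect_equal(got, c(row = sum(pix[, 1]) / nrow(pix),
                          col = sum(pix[, 2]) / nrow(pix)))
    }
  })
  expect_error(locate_center(matrix(FALSE, 3, 3)), "empty")
})

test_that("radial profile equals a per-pixel distance-bucketing oracle", {
  # uniform image: every populated bin equals the constant
  u <- matrix(3.5, 21, 21)
  pr <- radial_profile(u, c(row = 11, col = 11), max_radius_px = 8)
  expect_true(all(pr$mean_intensity[pr$n_px > 0] == 3.5))
  # single bright pixel at distance 4: only bin 4 is nonzero
  s <- matrix(0, 21, 21); s[11, 15] <- 9
  ps <- radial_profile(s, c(row = 11, col = 11), max_radius_px = 8)
  nz <- ps$radius_px[!is.na(ps$mean_intensity) & ps$mean_intensity > 0]
  expect_equal(nz, 4)
  # random images against brute-force bucketing
  withr::with_seed(9, {
    for (trial in 1:25) {
      n <- sample(15:40, 1)
      img <- matrix(runif(n * n), n, n)
      ctr <- c(row = runif(1, 5, n - 4), col = runif(1, 5, n - 4))
      maxr <- runif(1, 3, 10)
      got <- radial_profile(img, ctr, maxr)
      sums <- numeric(round(maxr) + 1); cnts <- integer(round(maxr) + 1)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        b <- round(sqrt((i - ctr[1])^2 + (j - ctr[2])^2))
        if (b <= round(maxr)) {
          sums[b + 1] <- sums[b + 1] + img[i, j]
          cnts[b + 1] <- cnts[b + 1] + 1L
        }
      }
      want <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
      expect_equal(got$mean_intensity, want)
      expect_identical(got$n_px, cnts)
    }
  })
  expect_error(radial_profile(u, c(11, 11), max_radius_px = 0), "> 0")
})

test_that("diameter read-off recovers rendered ring sizes within a pixel", {
  bg <- flat_bg(0, c(128, 160))
  for (R in c(5, 7, 12, 20, 45)) {
    fr <- render_frame(bg, data.frame(row = 64, col = 80, diameter_px = 2 * R),
                       psf_sigma_px = 1, noise_sd = 0)
    prof <- radial_profile(fr, c(row = 64, col = 80), max_radius_px = R + 8)
    est <- estimate_diameter(prof, pixel_size_um = 0.2)
    expect_lt(abs(est - 2 * R * 0.2), 0.2 + 1e-9)  # within 1 px equivalent
  }
  # flat / empty profiles signal "no particle"
  zero <- radial_profile(matrix(0, 31, 31), c(16, 16), 10)
  expect_error(estimate_diameter(zero, 0.2), "no particle")
  flat <- radial_profile(matrix(5, 31, 31), c(16, 16), 10)
  expect_error(estimate_diameter(flat, 0.2), "no particle")
})

test_that("recovered diameters quantize on the pixel grid of the camera", {
  # true diameters on a grid much finer than 0.2 um collapse onto far fewer
  # distinct estimates, set by the 1 px profile binning
  bg <- flat_bg(0, c(96, 96))
  true_d <- seq(4.0, 4.5, by = 0.01)    # um, 51 distinct values
  est <- vapply(true_d, function(d) {
    fr <- render_frame(bg, data.frame(row = 48, col = 48, diameter_px = d / 0.2),
                       psf_sigma_px = 1, noise_sd = 0)
    prof <- radial_profile(fr, c(row = 48, col = 48), max_radius_px = d / 0.4 + 8)
    estimate_diameter(prof, 0.2)
  }, numeric(1))
  n_distinct <- length(unique(round(est, 2)))
  expect_lt(n_distinct, length(unique(true_d)) / 2)
})

test_that("sphere volumes follow the closed form, aggregates sum", {
  expect_identical(compute_volume(0), 0)
  expect_equal(compute_volume(2), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(sum(compute_volume(c(2, 2))), 8 * pi / 3, tolerance = 1e-12)
  expect_error(compute_volume(-1), ">= 0")
})

test_that("velocity equals displacement over time", {
  tr <- data.frame(row = c(0, 0), col = c(0, 10))
  expect_equal(estimate_velocity(tr, c(0, 1 / 125), 0.2), 250)
  expect_equal(estimate_velocity(data.frame(row = c(3, 3, 3), col = c(4, 4, 4)),
                                 c(0, 0.008, 0.016), 0.2), 0)
  withr::with_seed(14, {
    track <- data.frame(row = cumsum(rnorm(5)), col = cumsum(rnorm(5)))
    ts <- seq(0, by = 0.008, length.out = 5)
    steps <- sqrt(diff(track$row)^2 + diff(track$col)^2)
    expect_equal(estimate_velocity(track, ts, 0.2),
                 mean(steps) * 0.2 / 0.008)
  })
  expect_true(is.na(estimate_velocity(data.frame(row = 1, col = 1), 0, 0.2)))
  expect_error(estimate_velocity(tr, c(1, 0.5), 0.2), "increasing")
})

test_that("event extraction finds isolated beads and resolves aggregates", {
  # empty run
  run0 <- generate_run(params = tiny_params(n_per_class = 0L))
  expect_identical(nrow(extract_optical_events(run0)), 0L)

  # one isolated 2.8 um bead
  cls <- class_specs(class_id = 1L, name = "bead", diameter_min_um = 2.8,
                     diameter_max_um = 2.8)
  run1 <- generate_run(classes = cls,
                       params = tiny_params(n_per_class = 1L, seed = 12L,
                                            aggregate_probability = 0,
                                            defocus_sd_px = 0))
  ev1 <- extract_optical_events(run1)
  expect_identical(nrow(ev1), 1L)
  expect_lt(abs(ev1$component_diameters_um[[1]] - 2.8), 0.4)

  # a guaranteed two-bead aggregate
  run2 <- generate_run(classes = cls,
                       params = tiny_params(n_per_class = 1L, seed = 13L,
                                            aggregate_probability = 1,
                                            aggregate_size_range = c(2L, 2L),
                                            defocus_sd_px = 0))
  ev2 <- extract_optical_events(run2)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$n_components[1], 2L)
  expect_equal(ev2$total_volume_um3[1],
               sum((pi / 6) * ev2$component_diameters_um[[1]]^3),
               tolerance = 1e-9)
})
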