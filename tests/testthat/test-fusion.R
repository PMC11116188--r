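ev_tbl <- function(times) tibble::tibble(event_id = seq_along(times), time_s = times)

test_that("identical timestamp lists match perfectly with zero offset", {
  a <- ev_tbl(c(1, 2, 3.5))
  m <- match_events(a, a, tolerance_s = 0.05)
  expect_identical(nrow(m$matched), 3L)
  expect_equal(m$matched$time_offset_s, rep(0, 3))
  expect_identical(nrow(m$unmatched_optical), 0L)
})

test_that("events outside tolerance stay unmatched and are reported", {
  m <- match_events(ev_tbl(1.0), ev_tbl(1.0 + 0.1), tolerance_s = 0.05)
  expect_identical(nrow(m$matched), 0L)
  expect_identical(nrow(m$unmatched_optical), 1L)
  expect_identical(nrow(m$unmatched_electrical), 1L)
})

test_that("greedy pairing equals the exhaustive assignment oracle on jittered lists", {
  withr::with_seed(42, {
    for (trial in 1:25) {
      n <- sample(2:7, 1)
      tol <- 0.05
      # well-separated events with jitter < tolerance/2: pairing unambiguous
      to <- 0.2 * seq_len(n) + runif(n, -0.02, 0.02)
      te <- to + runif(n, -tol / 2.5, tol / 2.5)
      drop <- sample(c(TRUE, FALSE), 1)
      if (drop && n > 2) te <- te[-sample(n, 1)]
      got <- match_events(ev_tbl(to), ev_tbl(sort(te)), tol)
      oracle <- oracle_assignment(to, sort(te), tol)
      expect_identical(nrow(got$matched), nrow(oracle))
      got_pairs <- paste(got$matched$optical_event_id,
                         got$matched$electrical_event_id)
      expect_setequal(got_pairs, paste(oracle[, "i"], oracle[, "j"]))
    }
  })
})

test_that("matching is symmetric in the two modalities", {
  withr::with_seed(8, {
    to <- sort(runif(8, 0, 2)); te <- sort(runif(6, 0, 2))
    m1 <- match_events(ev_tbl(to), ev_tbl(te), 0.08)
    m2 <- match_events(ev_tbl(te), ev_tbl(to), 0.08)
    expect_setequal(paste(m1$matched$optical_event_id, m1$matched$electrical_event_id),
                    paste(m2$matched$electrical_event_id, m2$matched$optical_event_id))
  })
})

fused_fixture <- function(n = 40, seed = 2) {
  withr::with_seed(seed, {
    vol <- 10^runif(n, 0.5, 3.5)
    tibble::tibble(
      event_id = seq_len(n), time_s = seq_len(n) * 0.1,
      vol_um3 = vol, vel_um_s = runif(n, 200, 500),
      pi_100kHz = 1e-4 * vol * exp(rnorm(n, 0, 0.3)),
      pi_500kHz = 1.1e-4 * vol * exp(rnorm(n, 0, 0.3)),
      label = sample(1:4, n, TRUE), run_id = "fx")
  })
}

test_that("feature tables expose exactly the requested modality columns", {
  fx <- fused_fixture()
  t_opt <- build_feature_table(fx, mode = "optical")
  expect_identical(attr(t_opt, "feature_cols"), "vol_um3")
  t_el <- build_feature_table(fx, mode = "electrical", frequencies_hz = 500e3)
  expect_identical(attr(t_el, "feature_cols"), "pi_500kHz")
  t_mm <- build_feature_table(fx, mode = "multimodal")
  expect_identical(length(attr(t_mm, "feature_cols")), 3L)  # 2 PI + VOL here
  expect_error(build_feature_table(fx, mode = "electrical",
                                   frequencies_hz = 750e3), "absent")
  # complete-case rule
  fx$vol_um3[3] <- NA
  expect_identical(nrow(build_feature_table(fx, mode = "multimodal")), 39L)
})

test_that("log-log regression matches the closed-form least-squares oracle", {
  # exact power law: R^2 = 1 and the slope is the exponent
  v <- c(1, 10, 100, 1000)
  tab <- tibble::tibble(vol_um3 = v, pi_500kHz = 2e-4 * v^1.3)
  r <- regress_vol_pi(tab, 500e3)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 1.3, tolerance = 1e-12)
  # two distinct points fit exactly
  r2 <- regress_vol_pi(tibble::tibble(vol_um3 = c(1, 10), pi_500kHz = c(1, 5)), 500e3)
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
  # three hand-listed points against the closed-form OLS solution
  pts_v <- c(1, 10, 100); pts_p <- c(1, 8, 120)
  x <- log10(pts_v); y <- log10(pts_p)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  yhat <- alpha + beta * x
  r2_oracle <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  r3 <- regress_vol_pi(tibble::tibble(vol_um3 = pts_v, pi_500kHz = pts_p), 500e3)
  expect_equal(r3$slope, beta, tolerance = 1e-12)
  expect_equal(r3$intercept, alpha, tolerance = 1e-12)
  expect_equal(r3$r_squared, r2_oracle, tolerance = 1e-12)
  # contract violations
  expect_error(regress_vol_pi(tibble::tibble(vol_um3 = 1, pi_500kHz = 1), 500e3),
               "at least 2")
  expect_error(regress_vol_pi(tibble::tibble(vol_um3 = c(-1, 2),
                                             pi_500kHz = c(1, 2)), 500e3),
               "positive")
  # tidiers
  expect_identical(nrow(tidy(r3)), 2L)
  expect_equal(glance(r3)$r.squared, r2_oracle)
})

test_that("velocity adds nothing when independent, everything when constructed to", {
  fx <- fused_fixture(n = 300, seed = 6)
  vi <- velocity_increment(fx, 500e3)
  expect_lt(vi$increment, 0.01)
  expect_gte(vi$increment, 0)
  # collinear velocity (copy of log volume) adds ~ nothing
  fx2 <- fused_fixture(n = 100, seed = 7)
  fx2$vel_um_s <- log10(fx2$vol_um3)
  expect_lt(velocity_increment(fx2, 500e3)$increment, 1e-6)
  # velocity constructed to explain the residual closes the gap to R^2 = 1
  fx3 <- fused_fixture(n = 100, seed = 8)
  withr::with_seed(9, {
    fx3$pi_500kHz <- 1e-4 * fx3$vol_um3 * exp(rnorm(100, 0, 1.0))
  })
  fx3$vel_um_s <- log10(fx3$pi_500kHz) - log10(fx3$vol_um3)
  vi3 <- velocity_increment(fx3, 500e3)
  expect_gt(vi3$increment, 0.05)
  expect_gt(vi3$r2_with_velocity, 0.999)
  expect_error(velocity_increment(fx3[, -4], 500e3), "vel_um_s")
})
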