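c_ms <- 1500

# ship circling the array: direction coverage over all bearings
ship_circle <- function(n = 60, radius = 400, z = 800) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  data.frame(time = seq_len(n), x = radius * cos(th), y = radius * sin(th),
             z = z)
}

# plane-wave pair TDOAs of ship noise at the array, per 1-s bin
ship_tdoas <- function(ship, offsets, array_pos, noise_sd = 0) {
  H <- pair_matrix(offsets)
  t(vapply(seq_len(nrow(ship)), function(b) {
    s <- array_pos - c(ship$x[b], ship$y[b], ship$z[b])
    s <- s / sqrt(sum(s^2))
    as.numeric(H %*% s) / c_ms + stats::rnorm(6, sd = noise_sd)
  }, numeric(6)))
}

test_that("hydrophone geometry is recovered from circling ship noise", {
  off <- tetrahedron_offsets(1)     # centroid-referenced truth
  array_pos <- c(0, 0, 6)
  ship <- ship_circle()
  td <- ship_tdoas(ship, off, array_pos)
  est <- estimate_hydrophone_geometry(ship, td, array_pos, c_ms)
  expect_lt(max(abs(est - off)), 0.01)
  expect_lt(attr(est, "residual_rms"), 1e-9)
  # all bearings identical: rank-deficient
  ship_line <- ship_circle()
  ship_line$x <- 400
  ship_line$y <- 0
  td_line <- ship_tdoas(ship_line, off, array_pos)
  expect_error(estimate_hydrophone_geometry(ship_line, td_line, array_pos,
                                            c_ms),
               "conditioning")
  expect_error(estimate_hydrophone_geometry(ship[1:5, ], td[1:5, ],
                                            array_pos, c_ms),
               "at least")
})

test_that("geometry error scales roughly linearly with TDOA noise", {
  set.seed(51)
  off <- tetrahedron_offsets(1)
  array_pos <- c(0, 0, 6)
  ship <- ship_circle(n = 120)
  err_at <- function(sg) {
    mean(replicate(5, {
      td <- ship_tdoas(ship, off, array_pos, noise_sd = sg)
      est <- estimate_hydrophone_geometry(ship, td, array_pos, c_ms)
      sqrt(mean((est - off)^2))
    }))
  }
  e1 <- err_at(2e-6)
  e4 <- err_at(8e-6)
  expect_lt(e1, 0.02)
  expect_gt(e4 / e1, 1.5)
  expect_lt(e4 / e1, 10)
})

test_that("trilateration recovers an instrument from two-way travel times", {
  p_true <- c(120, -80, 5)
  ship <- ship_circle(n = 24, radius = 600, z = 900)
  tw <- 2 * sqrt((ship$x - p_true[1])^2 + (ship$y - p_true[2])^2 +
                   (ship$z - p_true[3])^2) / c_ms
  est <- trilaterate_instrument(ship, tw, c_ms)
  expect_lt(sqrt(sum((est - p_true)^2)), 0.1)
  expect_true(attr(est, "converged"))
  # collinear ship track: weak geometry warning
  line <- data.frame(time = 1:24, x = seq(-600, 600, length.out = 24),
                     y = 0, z = 900)
  twl <- 2 * sqrt((line$x - p_true[1])^2 + (line$y - p_true[2])^2 +
                    (line$z - p_true[3])^2) / c_ms
  expect_warning(trilaterate_instrument(line, twl, c_ms), "geometry")
  # 1 ms timing noise: error of order meters, not tens of meters
  set.seed(52)
  errs <- replicate(10, {
    e <- trilaterate_instrument(ship, tw + stats::rnorm(24, sd = 1e-3), c_ms,
                                depth_prior = list(z = 5, sigma = 5))
    sqrt(sum((e - p_true)^2))
  })
  expect_lt(stats::median(errs), 15)
  expect_gt(stats::median(errs), 0.05)
  expect_error(trilaterate_instrument(ship[1:3, ], tw[1:3], c_ms), "4 pings")
})

test_that("aliased pings are detected at the fold-back frequency", {
  fs <- 100000
  dur <- 130
  interval <- 10
  true_times <- seq(2, dur - 2, by = interval) +
    stats::runif(13, -0.01, 0.01)
  # 75 kHz source sampled at 100 kHz lands at 25 kHz; render by direct
  # evaluation, which aliases exactly like an ADC would
  x <- render_clicks(true_times, rep(1, length(true_times)), fs,
                     round(dur * fs), f0 = 75000, dur = 5e-3)
  set.seed(53)
  x <- x + stats::rnorm(length(x), sd = 0.01)
  got <- detect_pings(x, fs, ping_freq = 75000, expected_interval = interval)
  expect_equal(length(got), length(true_times))
  # times consistent with truth up to the fixed envelope-center offset
  offset <- got - true_times
  expect_lt(max(offset) - min(offset), 2e-4)
  expect_lt(abs(stats::median(offset) - 2.5e-3), 5e-4)
  # silence
  expect_warning(none <- detect_pings(stats::rnorm(fs, sd = 0.01), fs, 75000,
                                      interval),
                 "no pings")
  expect_length(none, 0)
})

test_that("200 kHz streams are decimated (deliberately aliasing) before detection", {
  fs <- 200000
  interval <- 10
  dur <- 65
  true_times <- seq(2, dur - 2, by = interval)
  x <- render_clicks(true_times, rep(1, length(true_times)), fs,
                     round(dur * fs), f0 = 75000, dur = 5e-3)
  set.seed(54)
  x <- x + stats::rnorm(length(x), sd = 0.01)
  got <- detect_pings(x, fs, ping_freq = 75000, expected_interval = interval)
  expect_equal(length(got), length(true_times))
  offset <- got - true_times
  expect_lt(max(offset) - min(offset), 2e-4)
  # a spurious burst between pings is rejected by the interval-outlier rule
  x2 <- x + render_clicks(25.4, 1, fs, round(dur * fs), f0 = 75000,
                          dur = 5e-3)
  got2 <- detect_pings(x2, fs, ping_freq = 75000,
                       expected_interval = interval)
  expect_equal(length(got2), length(true_times))
  expect_gt(length(attr(got2, "rejected")), 0)
  expect_lt(min(abs(attr(got2, "rejected") - 25.4)), 0.01)
})

test_that("degree-5 drift polynomial recovers injected clock drift", {
  day <- 86400
  tt <- seq(0, 120 * day, by = 60)
  expected_tdoa <- 0.31
  # zero drift
  m0 <- estimate_clock_drift(tt, tt + expected_tdoa, expected_tdoa)
  expect_lt(max(abs(predict_clock_drift(m0, tt[c(1, 500, 5000)]))), 1e-9)
  # linear drift, 1 ms/day over 120 days
  set.seed(55)
  drift <- 1e-3 / day * tt
  noise <- stats::rnorm(length(tt), sd = 1e-5)
  m1 <- estimate_clock_drift(tt, tt + expected_tdoa + drift + noise,
                             expected_tdoa)
  got <- predict_clock_drift(m1, tt)
  expect_lt(sqrt(mean((got - drift)^2)), 1e-4)
  # smooth cubic drift: fit residual at the measurement-noise level
  drift3 <- 5e-3 * (tt / max(tt))^3 - 2e-3 * (tt / max(tt))^2
  m3 <- estimate_clock_drift(tt, tt + expected_tdoa + drift3 + noise,
                             expected_tdoa)
  expect_lt(m3$residual_rms, 2e-5)
  expect_lt(sqrt(mean((predict_clock_drift(m3, tt) - drift3)^2)), 2e-5)
  expect_error(estimate_clock_drift(tt[1:5], tt[1:5] + 0.3, 0.3),
               "insufficient data")
})

test_that("clock correction restores the drift-free timebase", {
  tt <- seq(0, 1000, by = 60)
  m <- estimate_clock_drift(tt, tt + 0.25 + 0.004, 0.25)  # constant offset
  dets <- detection_set(c(100, 500, 900), 1, "S", 2e5)
  corr <- apply_clock_correction(dets, m)
  expect_equal(corr$time, dets$time - 0.004, tolerance = 1e-9)
  # zero model: identity
  mz <- estimate_clock_drift(tt, tt + 0.25, 0.25)
  expect_equal(apply_clock_correction(dets, mz)$time, dets$time,
               tolerance = 1e-12)
  expect_warning(predict_clock_drift(m, 5000), "extrapolating")
  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_clock_model(m, path)
  back <- read_clock_model(path)
  expect_equal(predict_clock_drift(back, c(100, 900)),
               predict_clock_drift(m, c(100, 900)), tolerance = 1e-12)
})
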