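test_that("track simulation: stationary, transit, dive profile", {
  still <- simulate_track(10, dt = 1, start = c(5, 6, 700), speed = 0,
                          z_forage = 700, descent_time = 1)
  expect_true(all(still$x == 5 & still$y == 6 & still$z == 700))
  wp <- data.frame(time = c(0, 10), x = c(0, 100), y = c(0, 0),
                   z = c(500, 500))
  lin <- simulate_track(10, dt = 0.5, waypoints = wp)
  expect_equal(lin$x, lin$time * 10)
  expect_equal(lin$y, rep(0, nrow(lin)))
  dive <- simulate_track(100, dt = 1, start = c(0, 0, 800), z_forage = 300,
                         descent_time = 40, heading_deg = 0, speed = 2)
  expect_equal(dive$z[dive$time == 40], 300)
  expect_true(all(dive$z[dive$time > 40] == 300))
  expect_equal(dive$x[dive$time == 10], 20)
})

test_that("forward-modelled arrivals obey the exact TDOA and drift", {
  geom <- default_deployment()
  # source equidistant from N and S arrives simultaneously there
  trk <- simulate_track(5, dt = 1, start = c(200, 0, 500), speed = 0,
                        z_forage = 500, descent_time = 1)
  scene <- scene_config(geom, list(list(id = "w1", track = trk, ici = 0.5,
                                        ici_jitter = 0, amplitude = 500)),
                        duration = 5, seed = 9)
  truth <- simulate_arrivals(scene)
  a <- truth$arrivals
  tN <- a$time[a$instrument == "N" & a$channel == 1]
  tS <- a$time[a$instrument == "S" & a$channel == 1]
  expect_equal(tN, tS, tolerance = 1e-12)
  # channel-1 arrival differences equal the distance-based TDOA oracle
  # between the recording hydrophones (channel 1 sits ~0.5 m off-centroid)
  tW <- a$time[a$instrument == "W" & a$channel == 1]
  p <- as.numeric(truth$clicks[1, c("x", "y", "z")])
  oracle <- expected_tdoa_large(p, reference_hydrophone_position(geom, "W"),
                                reference_hydrophone_position(geom, "N"),
                                geom$c)
  # channel delays are rendered with the plane-wave model, so agreement is
  # limited by wavefront curvature across the array (~1e-7 s here)
  expect_lt(abs(tW[1] - tN[1] - oracle), 1e-6)
  # per-channel delays follow the plane-wave model with the true DOA
  w4 <- a[a$instrument == "W" & a$click == 1, ]
  s <- c(w4$doa_x[1], w4$doa_y[1], w4$doa_z[1])
  off <- geom$instruments$W$offsets
  for (ch in 2:4) {
    pred <- expected_tdoa_small(doa(s), off[1, ], off[ch, ], geom$c)
    expect_equal(w4$time[w4$channel == ch] - w4$time[w4$channel == 1],
                 pred, tolerance = 1e-12)
  }
  # injected drift shifts arrivals exactly
  scene_d <- scene_config(geom, scene$sources, 5, seed = 9,
                          drift_coef = list(N = c(0.002, 1e-4)))
  td <- simulate_arrivals(scene_d)
  tNd <- td$arrivals$time[td$arrivals$instrument == "N" &
                            td$arrivals$channel == 1]
  expect_equal(tNd - tN, 0.002 + 1e-4 * tN, tolerance = 1e-12)
})

test_that("waveform rendering: silence, single-click detectability, 1/r law, determinism", {
  geom <- default_deployment()
  empty <- scene_config(geom, list(), duration = 0.5, seed = 3)
  wf0 <- synthesize_waveforms(simulate_arrivals(empty), empty)
  expect_true(all(vapply(wf0, function(w) all(w == 0), logical(1))))
  # one click, no noise: detected within 0.1 ms of the true arrival
  trk <- simulate_track(2, dt = 1, start = c(100, 50, 400), speed = 0,
                        z_forage = 400, descent_time = 1)
  one <- scene_config(geom, list(list(id = "w1", track = trk, ici = 10,
                                      ici_jitter = 0, amplitude = 600,
                                      t_start = 0.5, t_end = 1.4)),
                      duration = 2, seed = 10)
  truth <- simulate_arrivals(one)
  expect_equal(nrow(truth$clicks), 1)
  wf <- synthesize_waveforms(truth, one)
  y <- apply_click_filter(design_click_filter(1e5), wf$W[, 1])
  d <- detect_clicks(y, 1e5, threshold = 0.2)
  expect_equal(nrow(d), 1)
  t_true <- truth$arrivals$time[truth$arrivals$instrument == "W" &
                                  truth$arrivals$channel == 1]
  # the detected peak sits at the click-template center, half a click
  # duration (0.1 ms) after the arrival onset
  expect_lt(abs(d$time - (t_true + 1e-4)), 5e-5)
  # doubling the range halves the peak amplitude
  r1 <- sqrt(sum((c(100, 50, 400) - instrument_position(geom, "N"))^2))
  dir <- (c(100, 50, 400) - instrument_position(geom, "N"))
  p2 <- instrument_position(geom, "N") + dir * 2
  trk2 <- simulate_track(2, dt = 1, start = p2, speed = 0, z_forage = p2[3],
                         descent_time = 1)
  two <- scene_config(geom, list(list(id = "w1", track = trk2, ici = 10,
                                      ici_jitter = 0, amplitude = 600,
                                      t_start = 0.5, t_end = 1.4)),
                      duration = 2, seed = 10)
  truth2 <- simulate_arrivals(two)
  wf2 <- synthesize_waveforms(truth2, two)
  amp_at <- function(tr) tr$arrivals$amplitude[tr$arrivals$instrument == "N"]
  expect_equal(amp_at(truth2) / amp_at(truth), 0.5, tolerance = 1e-9)
  # rendered energy scales as amplitude^2 (sampled peak values are
  # carrier-phase sensitive, energy is not)
  expect_equal(sum(wf2$N^2) / sum(wf$N^2), 0.25, tolerance = 0.02)
  # identical seed: bit-identical waveforms, including noise and clutter
  noisy <- scene_config(geom, one$sources, duration = 2, clutter_rate = 2,
                        noise_floor = 0.01, seed = 77)
  wa <- synthesize_waveforms(simulate_arrivals(noisy), noisy)
  wb <- synthesize_waveforms(simulate_arrivals(noisy), noisy)
  expect_identical(wa$W, wb$W)
  expect_identical(wa$S, wb$S)
})

test_that("WAV files round-trip in all supported encodings", {
  set.seed(12)
  x <- matrix(stats::runif(4000, -0.9, 0.9), ncol = 4)
  for (bits in c(16L, 24L, 32L)) {
    path <- tempfile(fileext = ".wav")
    write_wav(x, 100000, path, bits = bits)
    back <- read_wav(path)
    expect_equal(back$fs, 100000)
    expect_equal(ncol(back$data), 4)
    tol <- c(`16` = 2^-15, `24` = 2^-23, `32` = 1e-7)[[as.character(bits)]]
    expect_lt(max(abs(back$data - x)), tol * 1.01)
  }
  mono <- stats::runif(1000, -1, 1)
  path <- tempfile(fileext = ".wav")
  write_wav(mono, 200000, path, bits = 24L)
  back <- read_wav(path)
  expect_equal(dim(back$data), c(1000L, 1L))
  expect_equal(back$fs, 200000)
})
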