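test_that("click trains rasterize detections with the floor convention", {
  d <- detection_set(c(0.1004, 0.25, 0.31), 1, "W", 1e5,
                     label = c("a", "a", "b"))
  tr <- build_click_train(d, 0, 1)
  expect_equal(sum(tr$values), 3)
  expect_true(all(tr$values %in% c(0, 1)))
  # label filter
  tra <- build_click_train(d, 0, 1, label_filter = "a")
  expect_equal(sum(tra$values), 2)
  trc <- build_click_train(d, 0, 1, label_filter = "zzz")
  expect_equal(sum(trc$values), 0)
  # a detection exactly on a cell boundary lands in the cell starting there
  db <- detection_set(0.005, 1, "W", 1e5)
  trb <- build_click_train(db, 0, 1, resolution = 1e-3)
  expect_equal(which(trb$values == 1), 6L)   # cell [0.005, 0.006)
  expect_error(build_click_train(d, 0, 1, resolution = 5e-3), "1 ms")
})

test_that("Hann smoothing spreads impulses and matches direct summation", {
  d <- detection_set(0.2, 1, "W", 1e5)
  tr <- smooth_click_train(build_click_train(d, 0, 1), hann_ms = 20)
  pk <- which.max(tr$values)
  expect_equal(pk, 201L)
  expect_equal(tr$values[pk - 1:8], tr$values[pk + 1:8], tolerance = 1e-12)
  # two impulses 40 ms apart produce non-overlapping bumps
  d2 <- detection_set(c(0.2, 0.24), 1, "W", 1e5)
  tr2 <- smooth_click_train(build_click_train(d2, 0, 1), hann_ms = 20)
  expect_equal(min(tr2$values[215:225]), 0)
  # oracle: convolution equals a sum of shifted Hann windows
  set.seed(31)
  times <- sort(stats::runif(12, 0.05, 0.95))
  d3 <- detection_set(times, 1, "W", 1e5)
  raw <- build_click_train(d3, 0, 1)
  sm <- smooth_click_train(raw, hann_ms = 20)
  w <- signal::hanning(21)
  naive <- numeric(length(raw$values))
  for (cell in which(raw$values == 1)) {
    for (j in -10:10) {
      idx <- cell + j
      if (idx >= 1 && idx <= length(naive)) {
        naive[idx] <- naive[idx] + w[j + 11]
      }
    }
  }
  expect_equal(sm$values, naive, tolerance = 1e-9)
})

test_that("click-train correlation finds the lag and rejects ambiguity", {
  set.seed(32)
  times <- sort(stats::runif(40, 0, 25))
  dl <- detection_set(times, 1, "W", 1e5, label = "a")
  du <- detection_set(times + 0.35, 1, "N", 2e5)
  tl <- smooth_click_train(build_click_train(dl, 0, 30, label_filter = "a"))
  tu <- smooth_click_train(build_click_train(du, 0, 30))
  res <- ctc_tdoa(tl, tu, max_lag = 1)
  expect_true(res$accepted)
  expect_equal(res$tau, 0.35, tolerance = 2e-3)
  # reverse direction gives the opposite lag (within one grid cell)
  rev <- ctc_tdoa(tu, tl, max_lag = 1)
  expect_equal(rev$tau, -res$tau, tolerance = 1e-3 + 1e-9)
  # strictly periodic train: every alignment looks alike -> rejected
  per <- detection_set(seq(0.2, 25, by = 0.4), 1, "W", 1e5, label = "a")
  peru <- detection_set(seq(0.2, 25, by = 0.4) + 0.13, 1, "N", 2e5)
  resp <- ctc_tdoa(smooth_click_train(build_click_train(per, 0, 30,
                                                        label_filter = "a")),
                   smooth_click_train(build_click_train(peru, 0, 30)),
                   max_lag = 1)
  expect_false(resp$accepted)
  expect_gt(resp$peak_ratio, 0.8)
  # all-zero train: flagged, undefined tau
  z <- smooth_click_train(build_click_train(
    detection_set(numeric(0), numeric(0), "N", 2e5), 0, 30))
  resz <- ctc_tdoa(tl, z, max_lag = 1)
  expect_false(resz$accepted)
  expect_true(is.na(resz$tau))
})

test_that("CTC recovers the delay of a jittered subset among clutter", {
  set.seed(33)
  src <- cumsum(0.4 * (1 + stats::runif(70, -0.1, 0.1)))
  src <- src[src < 25]
  tau_true <- 0.42
  keep <- stats::runif(length(src)) < 0.8
  clutter <- stats::runif(round(0.3 * sum(keep)), 0, 25)
  dl <- detection_set(src, 1, "W", 1e5, label = "a")
  du <- detection_set(sort(c(src[keep] + tau_true, clutter)), 1, "N", 2e5)
  res <- ctc_tdoa(smooth_click_train(build_click_train(dl, 0, 30,
                                                       label_filter = "a")),
                  smooth_click_train(build_click_train(du, 0, 30)),
                  max_lag = 1)
  expect_true(res$accepted)
  expect_lt(abs(res$tau - tau_true), 0.01)
})

test_that("label propagation assigns nearest matches within tolerance", {
  lab <- detection_set(c(1, 2, 3), 1, "W", 1e5, label = c("a", "a", "b"))
  unl <- detection_set(c(1.502, 2.497, 3.6), 1, "N", 2e5)
  out <- propagate_labels(unl, lab, tau = 0.5, tol = 0.01)
  expect_equal(out$label, c("a", "a", NA))
  # nothing within tolerance: unchanged
  out2 <- propagate_labels(unl, lab, tau = 0.9, tol = 0.01)
  expect_true(all(is.na(out2$label)))
  # tie resolved to the nearest labelled click
  lab3 <- detection_set(c(1.0, 1.02), 1, "W", 1e5, label = c("a", "b"))
  unl3 <- detection_set(1.512, 1, "N", 2e5)
  out3 <- propagate_labels(unl3, lab3, tau = 0.5, tol = 0.02)
  expect_equal(out3$label, "b")
})

test_that("sliding CTC yields consistent delays and rejects silent windows", {
  set.seed(34)
  sc <- assoc_scene(1, seed = 341, duration = 60, clutter_frac = 0)
  res <- sliding_ctc(sc$dets_ref, sc$dets_unl, max_lag = sc$max_lag,
                     step = 10)
  acc <- res$windows[res$windows$accepted, ]
  expect_gt(nrow(acc), 3)
  expect_lt(max(acc$tau) - min(acc$tau), 0.05)  # smooth tau track
  expect_gt(mean(res$detections$label == "w1", na.rm = TRUE), 0.99)
  # a label with no clicks on the partner instrument in the window is
  # rejected by the peak-ratio rule: make the source silent after t = 30 s
  dr <- sc$dets_ref
  keep_u <- sc$dets_unl$time < 30.3
  du <- detection_set(sc$dets_unl$time[keep_u], 1, "N", 2e5)
  # add unrelated clutter afterwards so trains are not all-zero
  set.seed(35)
  du <- detection_set(c(du$time, stats::runif(80, 31, 60)), 1, "N", 2e5)
  res2 <- sliding_ctc(dr, du, max_lag = sc$max_lag, step = 10)
  late <- res2$windows[res2$windows$t0 > 32, ]
  expect_true(all(!late$accepted))
})

test_that("fine TDOA refinement handles rate mismatch and flags junk", {
  fs1 <- 100000
  # equal rates, known integer offset
  a <- render_clicks(5e-3, 1, fs1, 2001)
  b <- render_clicks(5e-3 + 17 / fs1, 1, fs1, 2001)
  ft <- fine_tdoa(a, fs1, b, fs1, coarse_tau = 0, search_halfwidth = 1e-3)
  expect_true(ft$reliable)
  expect_equal(ft$tau, 17 / fs1, tolerance = 1e-9)
  # 200 kHz vs 100 kHz with a fractional-sample true delay
  true_d <- 23.37 / fs1
  a2 <- render_clicks(5e-3, 1, fs1, 2001)
  b2 <- render_clicks(5e-3 + true_d, 1, 200000, 4001)
  ft2 <- fine_tdoa(a2, fs1, b2, 200000, coarse_tau = 0,
                   search_halfwidth = 1e-3)
  expect_true(ft2$reliable)
  expect_lt(abs(ft2$tau - true_d) * fs1, 0.5)
  # uncorrelated noise: unreliable (low peak or boundary)
  set.seed(36)
  n1 <- stats::rnorm(2001)
  n2 <- stats::rnorm(2001)
  ft3 <- fine_tdoa(n1, fs1, n2, fs1, coarse_tau = 0,
                   search_halfwidth = 5e-3)
  expect_false(ft3$reliable)
})
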