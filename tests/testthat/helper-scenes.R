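# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# n random unit vectors (rows)
rand_unit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# continuous Hann-windowed tone burst (same shape as the simulator's click)
tone_click <- function(t, f0 = 35000, dur = 2e-4) {
  inside <- t >= 0 & t <= dur
  w <- numeric(length(t))
  w[inside] <- sin(pi * t[inside] / dur)^2 *
    cos(2 * pi * f0 * (t[inside] - dur / 2))
  w
}

# waveform with clicks at the given (fractional-sample) times
render_clicks <- function(times, amps, fs, n, f0 = 35000, dur = 2e-4) {
  x <- numeric(n)
  for (k in seq_along(times)) {
    i0 <- max(1L, floor(times[k] * fs))
    i1 <- min(n, ceiling((times[k] + dur) * fs) + 1L)
    if (i0 > n || i1 < 1L) next
    idx <- i0:i1
    x[idx] <- x[idx] + amps[k] * tone_click((idx - 1L) / fs - times[k],
                                            f0, dur)
  }
  x
}

# 4-channel plane-wave snippet for a propagation direction s
plane_wave_snippet <- function(s, offsets, fs, c_ms = 1500, n_half = 150L,
                               f0 = 35000, dur = 2e-4) {
  n <- 2L * n_half + 1L
  t0 <- (n_half - 20L) / fs
  sapply(1:4, function(ch) {
    delay <- sum(s * offsets[ch, ]) / c_ms
    render_clicks(t0 + delay, 1, fs, n, f0 = f0, dur = dur)
  })
}

# label detections from simulated ground truth (the "analyst" step)
labels_from_truth <- function(dets, truth, instrument, tol = 1e-3) {
  ta <- truth$arrivals[truth$arrivals$instrument == instrument &
                         truth$arrivals$channel == 1L, , drop = FALSE]
  labs <- rep(NA_character_, nrow(dets))
  for (k in seq_len(nrow(dets))) {
    i <- which.min(abs(ta$time - dets$time[k]))
    if (length(i) && abs(ta$time[i] - dets$time[k]) <= tol) {
      labs[k] <- ta$source[i]
    }
  }
  labs
}

# true emission position of the click behind a reference-array detection
truth_position_at <- function(truth, instrument, det_time) {
  ta <- truth$arrivals[truth$arrivals$instrument == instrument &
                         truth$arrivals$channel == 1L, , drop = FALSE]
  i <- which.min(abs(ta$time - det_time))
  cl <- truth$clicks[truth$clicks$source == ta$source[i], , drop = FALSE]
  as.numeric(cl[ta$click[i], c("x", "y", "z")])
}

# detection-time-level multi-source scene for association tests: labelled
# reference detections + unlabeled partner detections with Poisson clutter
assoc_scene <- function(n_sources, seed, duration = 120,
                        clutter_frac = 0.3) {
  set.seed(seed)
  geom <- default_deployment()
  sources <- lapply(seq_len(n_sources), function(k) {
    list(id = paste0("w", k),
         track = simulate_track(duration,
                                start = c(-600 + 350 * k, -500 + 240 * k,
                                          400 + 50 * k),
                                heading_deg = 30 + 67 * k, speed = 1.5),
         ici = 0.3 + 0.05 * (k - 1), ici_jitter = 0.1, amplitude = 600)
  })
  scene <- scene_config(geom, sources, duration, seed = seed)
  truth <- simulate_arrivals(scene)
  ta <- truth$arrivals
  W <- ta[ta$instrument == "W" & ta$channel == 1L, , drop = FALSE]
  P <- ta[ta$instrument == "N" & ta$channel == 1L, , drop = FALSE]
  dets_ref <- detection_set(W$time, 1, "W", 1e5, label = W$source)
  n_clut <- stats::rpois(1, clutter_frac * nrow(P))
  clut_t <- stats::runif(n_clut, 0, duration)
  dets_unl <- detection_set(c(P$time, clut_t), 1, "N", 2e5)
  true_lab <- c(P$source, rep(NA, n_clut))[order(c(P$time, clut_t))]
  max_lag <- sqrt(sum((instrument_position(geom, "W") -
                         instrument_position(geom, "N"))^2)) / geom$c + 0.05
  list(geom = geom, truth = truth, dets_ref = dets_ref,
       dets_unl = dets_unl, true_lab = true_lab, max_lag = max_lag)
}

# uncertainty parameters used in noise-propagation tests: plausible values
# for ~1 m arrays, surveyed seafloor instruments and cross-correlation
# timing at 100 kHz
test_uncertainty <- function() {
  uncertainty_params(sigma_H = 0.05, sigma_hi = 1, sigma_ray = 1e-5,
                     sigma_c = 1, sigma_xcorr = 1e-5,
                     sigma_traveltime = 1e-5, sigma_drift = 1e-4)
}

# TDOA-level measurement of one detection: plane-wave small TDOAs for both
# arrays and exact large TDOAs between reference hydrophones, with optional
# Gaussian noise at the model sigmas
make_bundle <- function(p, geom, params = NULL, noisy = FALSE) {
  c_ms <- geom$c
  small <- list()
  for (a in c("W", "E")) {
    ctr <- instrument_position(geom, a)
    s <- ctr - p
    s <- s / sqrt(sum(s^2))
    H <- pair_matrix(geom$instruments[[a]]$offsets)
    tau <- as.numeric(H %*% s) / c_ms
    if (noisy) {
      tau <- tau + stats::rnorm(6) *
        sigma_small(params, tau, c_ms, pair_norm = sqrt(rowSums(H^2)))
    }
    small[[a]] <- tau
  }
  lg <- do.call(rbind, lapply(list(c("W", "N"), c("W", "S"), c("W", "E")),
                              function(pr) {
    fi <- reference_hydrophone_position(geom, pr[1])
    fj <- reference_hydrophone_position(geom, pr[2])
    td <- (sqrt(sum((p - fi)^2)) - sqrt(sum((p - fj)^2))) / c_ms
    if (noisy) td <- td + stats::rnorm(1) * sigma_large(params, td, c_ms)
    data.frame(inst_i = pr[1], inst_j = pr[2], tdoa = td,
               stringsAsFactors = FALSE)
  }))
  tdoa_bundle(small, lg)
}
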