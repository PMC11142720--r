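#' Relative hydrophone geometry from ship noise
#'
#' Recovers the relative positions of the four hydrophones of a volumetric
#' array from broadband ship noise: with the ship's GPS position known in
#' each one-second bin, the direction of propagation to the array is known,
#' and every binned pair TDOA contributes one plane-wave equation
#' `s_b . (h_j - h_i) = c * tau`. Stacking all bins and pairs gives a linear
#' system in the hydrophone positions, solved in least squares with the
#' minimum-norm (Moore-Penrose) solution, which fixes the translational
#' gauge freedom by centering the array at the origin.
#'
#' @param ship_track Data frame with columns `time, x, y, z`: ship positions
#'   (m, same frame as the array) per 1-s bin.
#' @param binned_tdoas n_bins x 6 matrix of measured pair TDOAs (s,
#'   [pair_index()] order), rows matching `ship_track` rows.
#' @param array_pos The array reference position (m).
#' @param c_ms Sound speed (m/s).
#' @param min_bins Minimum usable bins (default 12).
#' @param cond_tol Maximum acceptable ratio of largest to smallest informative
#'   singular value; beyond it the bearing coverage is too narrow.
#' @return 4 x 3 matrix of centroid-referenced hydrophone offsets (m), with
#'   attributes `residual_rms` (s) and `condition`.
#' @export
estimate_hydrophone_geometry <- function(ship_track, binned_tdoas, array_pos,
                                         c_ms, min_bins = 12L,
                                         cond_tol = 1e4) {
  binned_tdoas <- as.matrix(binned_tdoas)
  nb <- nrow(binned_tdoas)
  if (nb != nrow(ship_track)) stop("ship track and TDOA bins differ in length")
  if (nb < min_bins) stop("need at least ", min_bins, " one-second bins")
  array_pos <- check_position(array_pos, "array_pos")
  p <- pair_index()
  # design: unknown theta = (h1, h2, h3, h4) stacked, 12 unknowns
  rows <- matrix(0, nb * 6L, 12L)
  rhs <- numeric(nb * 6L)
  r <- 0L
  for (b in seq_len(nb)) {
    ship <- c(ship_track$x[b], ship_track$y[b], ship_track$z[b])
    s <- array_pos - ship              # propagation: ship (source) -> array
    s <- s / sqrt(sum(s^2))
    for (k in seq_len(6L)) {
      if (!is.finite(binned_tdoas[b, k])) next
      r <- r + 1L
      i <- p[k, 1L]
      j <- p[k, 2L]
      rows[r, (3L * (j - 1L) + 1L):(3L * j)] <- s
      rows[r, (3L * (i - 1L) + 1L):(3L * i)] <-
        rows[r, (3L * (i - 1L) + 1L):(3L * i)] - s
      rhs[r] <- c_ms * binned_tdoas[b, k]
    }
  }
  rows <- rows[seq_len(r), , drop = FALSE]
  rhs <- rhs[seq_len(r)]
  sv <- svd(rows)$d
  # translation of the whole array is unobservable: 3 null directions
  informative <- sv[seq_len(9L)]
  if (informative[9L] <= 0 || informative[1L] / informative[9L] > cond_tol) {
    stop("conditioning error: ship bearings do not span enough directions ",
         "(condition ", format(informative[1L] / max(informative[9L],
                                                     .Machine$double.eps),
                               digits = 3), ")")
  }
  theta <- as.numeric(MASS::ginv(rows) %*% rhs)
  offsets <- matrix(theta, nrow = 4L, byrow = TRUE)
  resid <- (as.numeric(rows %*% theta) - rhs) / c_ms
  structure(offsets, residual_rms = sqrt(mean(resid^2)),
            condition = informative[1L] / informative[9L])
}

#' Trilaterate an instrument from two-way travel times
#'
#' Estimates a seafloor instrument's position from the two-way travel times
#' of acoustic-release transponder pings exchanged with a ship at known
#' positions, by nonlinear least squares on
#' `sum_k (2 ||ship_k - p|| / c - t_k)^2`, optionally with a soft depth
#' prior.
#'
#' @param ship_track Data frame `time, x, y, z` of ship positions (m) at each
#'   ping.
#' @param two_way_times Measured two-way travel times (s), one per row of
#'   `ship_track`.
#' @param c_ms Sound speed (m/s).
#' @param depth_prior Optional list `list(z =, sigma =)`: soft constraint on
#'   the instrument's z (m).
#' @param start Optional starting position; defaults to below the mean ship
#'   position.
#' @return Length-3 position (m) with attributes `residual_rms` (s),
#'   `converged`, and `condition` (of the Gauss-Newton normal matrix at the
#'   solution; large values indicate weak geometry, e.g. a collinear ship
#'   track).
#' @export
trilaterate_instrument <- function(ship_track, two_way_times, c_ms,
                                   depth_prior = NULL, start = NULL) {
  n <- length(two_way_times)
  if (n < 4L) stop("need at least 4 pings")
  if (n != nrow(ship_track)) stop("ship track and times differ in length")
  S <- cbind(ship_track$x, ship_track$y, ship_track$z)
  if (is.null(start)) {
    start <- c(mean(S[, 1]), mean(S[, 2]),
               if (!is.null(depth_prior)) depth_prior$z
               else mean(S[, 3]) - c_ms * mean(two_way_times) / 2)
  }
  objective <- function(par) {
    d <- sqrt((S[, 1] - par[1])^2 + (S[, 2] - par[2])^2 +
                (S[, 3] - par[3])^2)
    val <- sum((2 * d / c_ms - two_way_times)^2)
    if (!is.null(depth_prior)) {
      val <- val + ((par[3] - depth_prior$z) / depth_prior$sigma)^2
    }
    val
  }
  fit <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  p <- fit$par
  d <- sqrt(rowSums((S - matrix(p, n, 3L, TRUE))^2))
  resid <- 2 * d / c_ms - two_way_times
  # geometry conditioning from the Jacobian of the travel-time model
  J <- -2 * (S - matrix(p, n, 3L, TRUE)) / (c_ms * d)
  sv <- svd(J)$d
  cond <- sv[1L] / max(sv[3L], .Machine$double.eps)
  if (cond > 1e4) {
    warning("weak trilateration geometry (condition ",
            format(cond, digits = 3),
            "); cross-track position poorly constrained")
  }
  structure(stats::setNames(p, c("x", "y", "z")),
            residual_rms = sqrt(mean(resid^2)),
            converged = fit$convergence == 0L, condition = cond)
}

#' Detect periodic synchronization pings
#'
#' Detects narrowband calibration pings (acoustic-release or ADCP) in a
#' single-channel recording. Pings whose source frequency exceeds Nyquist are
#' recorded at their aliased frequency and detected there; 200-kHz streams
#' are first decimated to 100 kHz *without* an anti-alias filter, so a 75-kHz
#' ping deliberately folds to 25 kHz. Detection is a band-pass around the
#' effective frequency, envelope thresholding, pruning within a ping
#' duration, and interval-based outlier rejection (median absolute deviation
#' of the offset from the nominal ping grid).
#'
#' @param x Waveform.
#' @param fs Sampling rate (Hz).
#' @param ping_freq Source ping frequency (Hz), e.g. 75000.
#' @param expected_interval Nominal ping interval (s), e.g. 60.
#' @param threshold Linear envelope threshold; default 5 x the median
#'   envelope.
#' @param target_fs Rate to decimate to before detection when `fs >
#'   target_fs` (default 100 kHz).
#' @param bandwidth Half-width (Hz) of the detection band (default 2000).
#' @param mad_mult Outlier rejection multiplier (default 5).
#' @return Numeric vector of ping times (s) with attribute `rejected` (times
#'   removed as interval outliers). Empty (with a warning) when nothing is
#'   found.
#' @export
detect_pings <- function(x, fs, ping_freq, expected_interval,
                         threshold = NULL, target_fs = 100000,
                         bandwidth = 2000, mad_mult = 5) {
  if (fs > target_fs) {
    dec <- round(fs / target_fs)
    x <- x[seq(1L, length(x), by = dec)]   # deliberate aliasing: no filter
    fs <- fs / dec
  }
  f_eff <- abs(ping_freq - fs * round(ping_freq / fs))
  if (f_eff <= 0 || f_eff >= fs / 2) {
    stop("effective ping frequency out of band: ", f_eff, " Hz at fs ", fs)
  }
  lo <- max(f_eff - bandwidth, 100) / (fs / 2)
  hi <- min(f_eff + bandwidth, fs / 2 - 100) / (fs / 2)
  bp <- signal::butter(4, c(lo, hi), type = "pass")
  y <- signal::filtfilt(bp, x)
  env <- abs(y)
  # smooth the envelope over ~1 ms
  k <- max(3L, round(1e-3 * fs))
  env <- stats::filter(env, rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  if (is.null(threshold)) threshold <- 5 * stats::median(env[env > 0])
  dets <- detect_clicks(env, fs, threshold,
                        prune_ms = min(1000, expected_interval / 4 * 1000))
  times <- dets$time
  if (length(times) == 0L) {
    warning("no pings found")
    return(structure(numeric(0), rejected = numeric(0)))
  }
  # interval outlier rejection: offset from the nominal ping grid
  phase <- ((times - times[1]) + expected_interval / 2) %% expected_interval -
    expected_interval / 2
  dev <- abs(phase - stats::median(phase))
  scale <- max(stats::mad(phase), 1e-4)
  keep <- dev <= mad_mult * scale
  structure(times[keep], rejected = times[!keep])
}

#' Estimate relative clock drift between two instruments
#'
#' Pairs synchronization pings detected on two instruments (nearest in time,
#' within half the nominal interval), takes the measured inter-instrument
#' TDOA of each pair, subtracts the expected (drift-free) TDOA, and fits a
#' fifth-order polynomial to the resulting drift samples over the
#' deployment. Times are centered and scaled before fitting for numerical
#' stability.
#'
#' @param ping_times_i,ping_times_j Ping times (s, each instrument's own
#'   clock).
#' @param expected_tdoa Expected drift-free TDOA (s) of the ping at j
#'   relative to i (e.g. from the survey-epoch measurement).
#' @param expected_interval Nominal ping interval (s) used for pairing
#'   (default 60).
#' @param degree Polynomial degree (default 5, the model's fixed choice).
#' @return An object of class `"clock_model"`: list with `coef`, `t_center`,
#'   `t_scale`, `validity` (time range), `residual_rms` (s), `n_pairs`,
#'   `drift` samples (`time`, `offset`).
#' @export
estimate_clock_drift <- function(ping_times_i, ping_times_j, expected_tdoa,
                                 expected_interval = 60, degree = 5L) {
  if (length(ping_times_i) == 0L || length(ping_times_j) == 0L) {
    stop("insufficient data: no pings on one instrument")
  }
  ti <- sort(ping_times_i)
  tj <- sort(ping_times_j)
  idx <- findInterval(ti, tj)
  cand_lo <- pmax(1L, idx)
  cand_hi <- pmin(length(tj), idx + 1L)
  d_lo <- abs(tj[cand_lo] - ti)
  d_hi <- abs(tj[cand_hi] - ti)
  j_near <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
  dist <- pmin(d_lo, d_hi)
  ok <- dist <= expected_interval / 2
  if (sum(ok) < degree + 2L) {
    stop("insufficient data: need at least ", degree + 2L,
         " matched ping pairs for a degree-", degree, " fit")
  }
  t_pair <- ti[ok]
  offset <- tj[j_near[ok]] - ti[ok] - expected_tdoa
  t_center <- mean(range(t_pair))
  t_scale <- max((diff(range(t_pair)) / 2), 1)
  u <- (t_pair - t_center) / t_scale
  X <- outer(u, 0:degree, `^`)
  fit <- stats::lm.fit(X, offset)
  resid <- fit$residuals
  structure(list(coef = fit$coefficients, t_center = t_center,
                 t_scale = t_scale, validity = range(t_pair),
                 residual_rms = sqrt(mean(resid^2)), n_pairs = sum(ok),
                 drift = data.frame(time = t_pair, offset = offset)),
            class = "clock_model")
}

#' Evaluate a clock-drift model
#'
#' @param model A `"clock_model"`.
#' @param time Times (s) at which to evaluate the drift.
#' @param warn_extrapolate Warn when `time` is outside the fitted validity
#'   interval.
#' @return Drift (s) of instrument j's clock relative to instrument i at
#'   `time`.
#' @export
predict_clock_drift <- function(model, time, warn_extrapolate = TRUE) {
  stopifnot(inherits(model, "clock_model"))
  if (warn_extrapolate &&
      (any(time < model$validity[1]) || any(time > model$validity[2]))) {
    warning("times outside clock model validity interval; extrapolating")
  }
  u <- (time - model$t_center) / model$t_scale
  drop(outer(u, seq_along(model$coef) - 1L, `^`) %*% model$coef)
}

#' Apply a clock-drift correction to a detection set
#'
#' Shifts detection times by minus the modelled drift, moving instrument j's
#' clock onto instrument i's timebase. Correction is not idempotent: the
#' model maps *uncorrected* times, so apply it once.
#'
#' @param dets A [detection_set()] recorded on the drifting instrument.
#' @param model A `"clock_model"` for (reference, this instrument).
#' @return The corrected [detection_set()].
#' @export
apply_clock_correction <- function(dets, model) {
  dets$time <- dets$time - predict_clock_drift(model, dets$time)
  dets[order(dets$time), , drop = FALSE]
}

#' Write / read a clock model as JSON
#'
#' @param model A `"clock_model"`.
#' @param path File path.
#' @return `path` (write) or the `"clock_model"` (read).
#' @export
write_clock_model <- function(model, path) {
  out <- list(coef = as.numeric(model$coef), t_center = model$t_center,
              t_scale = model$t_scale, validity = model$validity,
              residual_rms = model$residual_rms, n_pairs = model$n_pairs)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coef = raw$coef, t_center = raw$t_center,
                 t_scale = raw$t_scale, validity = raw$validity,
                 residual_rms = raw$residual_rms, n_pairs = raw$n_pairs,
                 drift = NULL),
            class = "clock_model")
}
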