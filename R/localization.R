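#' TDOA uncertainty parameters
#'
#' The per-measurement standard deviations entering the small- and
#' large-aperture TDOA error budgets ([sigma_small()], [sigma_large()]).
#' All values are standard deviations, >= 0.
#'
#' @param sigma_H Hydrophone-pair vector uncertainty (m).
#' @param pair_norm Hydrophone pair-vector length `||H||` (m); may be
#'   overridden per pair.
#' @param sigma_hi Instrument position uncertainty (m).
#' @param sigma_ray Plane-wave / ray-bending timing error (s).
#' @param sigma_c Sound-speed uncertainty (m/s).
#' @param sigma_xcorr Cross-correlation timing uncertainty (s).
#' @param sigma_traveltime Travel-time model uncertainty (s).
#' @param sigma_drift Residual clock-drift uncertainty (s).
#' @return An object of class `"uncertainty_params"`.
#' @export
uncertainty_params <- function(sigma_H = 0, pair_norm = 1, sigma_hi = 0,
                               sigma_ray = 0, sigma_c = 0, sigma_xcorr = 0,
                               sigma_traveltime = 0, sigma_drift = 0) {
  p <- list(sigma_H = sigma_H, pair_norm = pair_norm, sigma_hi = sigma_hi,
            sigma_ray = sigma_ray, sigma_c = sigma_c,
            sigma_xcorr = sigma_xcorr, sigma_traveltime = sigma_traveltime,
            sigma_drift = sigma_drift)
  bad <- vapply(p, function(v) any(!is.finite(v)) || any(v < 0), logical(1))
  if (any(bad)) {
    stop("uncertainty parameters must be finite and >= 0: ",
         paste(names(p)[bad], collapse = ", "))
  }
  structure(p, class = "uncertainty_params")
}

#' Small-aperture TDOA standard deviation
#'
#' Propagated error budget of a small-aperture (within-array) TDOA:
#' \deqn{\sigma_{sml} = \sqrt{(\sigma_H/c)^2
#'   + (\|H\|/c)^2 (\sigma_{hi}^2/100^2 + \sigma_{ray}^2)
#'   + (TDOA_{calc}/c)^2 \sigma_c^2 + \sigma_{xcorr}^2}.}
#' The 1/100^2 factor on the instrument-position term is part of the budget
#' definition (it arises from a unit conversion in the budget's derivation)
#' and is applied exactly as written.
#'
#' @param params An [uncertainty_params()].
#' @param tdoa_calc The modelled/measured TDOA (s); may be a vector.
#' @param c_ms Sound speed (m/s).
#' @param pair_norm Pair-vector length (m); defaults to `params$pair_norm`.
#' @return Standard deviation(s) in seconds.
#' @export
sigma_small <- function(params, tdoa_calc, c_ms, pair_norm = NULL) {
  stopifnot(inherits(params, "uncertainty_params"))
  H <- pair_norm %||% params$pair_norm
  sqrt((params$sigma_H / c_ms)^2 +
         (H / c_ms)^2 * (params$sigma_hi^2 / 100^2 + params$sigma_ray^2) +
         (tdoa_calc / c_ms)^2 * params$sigma_c^2 +
         params$sigma_xcorr^2)
}

#' Large-aperture TDOA standard deviation
#'
#' Propagated error budget of an inter-instrument TDOA:
#' \deqn{\sigma_{lrg} = \sqrt{(\sigma_{hi}^2 + \sigma_{hj}^2)/c^2
#'   + TDOA_{calc}^2 \sigma_c^2 / c^2
#'   + \sigma_{traveltime}^2 + \sigma_{drift}^2 + \sigma_{xcorr}^2}.}
#'
#' @param params An [uncertainty_params()].
#' @param tdoa_calc The modelled/measured TDOA (s); may be a vector.
#' @param c_ms Sound speed (m/s).
#' @param sigma_hj Position uncertainty of the second instrument (m);
#'   defaults to `params$sigma_hi`.
#' @return Standard deviation(s) in seconds.
#' @export
sigma_large <- function(params, tdoa_calc, c_ms, sigma_hj = NULL) {
  stopifnot(inherits(params, "uncertainty_params"))
  shj <- sigma_hj %||% params$sigma_hi
  sqrt((params$sigma_hi^2 + shj^2) / c_ms^2 +
         tdoa_calc^2 * params$sigma_c^2 / c_ms^2 +
         params$sigma_traveltime^2 + params$sigma_drift^2 +
         params$sigma_xcorr^2)
}

#' Localize from one DOA ray and one large-aperture TDOA
#'
#' The source lies along the DOA ray of the 4-channel array (receiver-to-
#' source direction, i.e. `array_pos - s * r`). The measured large-aperture
#' TDOA between the array and a partner instrument constrains the source to
#' one hyperboloid sheet; the estimate is the ray point where the modelled
#' TDOA ([expected_tdoa_large()], array as receiver i, partner as receiver j)
#' best matches the measurement. The discrete range grid is refined by a
#' local parabolic fit of the squared TDOA error.
#'
#' @param doa A [doa()] from the 4-channel array.
#' @param array_pos,partner_pos Instrument positions (m). `array_pos` is the
#'   ray origin (array reference point).
#' @param tdoa Measured TDOA (s), sign convention `(d_array - d_partner)/c`.
#' @param c_ms Sound speed (m/s).
#' @param range_grid Candidate ranges (m); default `seq(1, 8000, by = 1)`.
#' @param focus_i,focus_j Hyperboloid foci: the positions of the hydrophones
#'   the TDOA was actually measured between (default the instrument
#'   positions). For a 4-channel array whose TDOA was measured on the
#'   reference channel, pass that hydrophone's position — the ~0.5 m offset
#'   from the array centroid is worth hundreds of microseconds.
#' @return Length-3 position with attributes `range` (m), `tdoa_error` (s)
#'   and `at_boundary` (TRUE when the minimum sits at a grid end, e.g. when
#'   the TDOA is inconsistent with every ray point).
#' @export
localize_doa_plus_tdoa <- function(doa, array_pos, partner_pos, tdoa, c_ms,
                                   range_grid = NULL, focus_i = array_pos,
                                   focus_j = partner_pos) {
  s <- unclass(doa)
  if (is.null(range_grid)) range_grid <- seq(1, 8000, by = 1)
  array_pos <- check_position(array_pos, "array_pos")
  focus_i <- check_position(focus_i, "focus_i")
  focus_j <- check_position(focus_j, "focus_j")
  # points along the ray, vectorized over the grid
  px <- array_pos[1] - s[1] * range_grid
  py <- array_pos[2] - s[2] * range_grid
  pz <- array_pos[3] - s[3] * range_grid
  di <- sqrt((px - focus_i[1])^2 + (py - focus_i[2])^2 +
               (pz - focus_i[3])^2)
  dj <- sqrt((px - focus_j[1])^2 + (py - focus_j[2])^2 +
               (pz - focus_j[3])^2)
  err <- (di - dj) / c_ms - tdoa
  e2 <- err^2
  m <- which.min(e2)
  at_boundary <- m == 1L || m == length(range_grid)
  r_hat <- range_grid[m]
  if (!at_boundary) {
    yl <- e2[m - 1L]
    ym <- e2[m]
    yr <- e2[m + 1L]
    den <- yl - 2 * ym + yr
    if (is.finite(den) && den > 0) {
      step <- range_grid[m + 1L] - range_grid[m]
      r_hat <- r_hat + 0.5 * (yl - yr) / den * step
    }
  }
  pos <- array_pos - s * r_hat
  structure(pos, range = r_hat, tdoa_error = sqrt(min(e2)),
            at_boundary = at_boundary)
}

#' Localize from two DOA rays (closest point of intersection)
#'
#' Solves the two-unknown least-squares system for the ranges `r1`, `r2`
#' minimizing the distance between points on the two DOA lines
#' `g_n = u_n r_n + h_n` (with `u_n` the receiver-to-source directions), and
#' returns the midpoint of the closest points `g1`, `g2`.
#'
#' @param doa1,doa2 [doa()] objects from the two arrays.
#' @param h1,h2 Array positions (m).
#' @param min_angle_deg Minimum angle between the lines (default 0.1
#'   degrees); below this the system is ill-conditioned and an error is
#'   raised.
#' @return Length-3 position with attributes `r1`, `r2` (ranges, m) and
#'   `miss_distance` (`||g1 - g2||`, m; 0 iff the lines truly intersect).
#' @export
localize_two_doa <- function(doa1, h1, doa2, h2, min_angle_deg = 0.1) {
  u1 <- -unclass(doa1)
  u2 <- -unclass(doa2)
  h1 <- check_position(h1, "h1")
  h2 <- check_position(h2, "h2")
  cosang <- abs(sum(u1 * u2))
  if (cosang > cos(min_angle_deg * pi / 180)) {
    stop("ill-conditioned: DOA lines are within ", min_angle_deg,
         " degrees of parallel")
  }
  A <- cbind(u1, -u2)             # 3 x 2
  R <- qr.solve(A, h2 - h1)       # least squares for (r1, r2)
  g1 <- h1 + u1 * R[1]
  g2 <- h2 + u2 * R[2]
  structure((g1 + g2) / 2, r1 = R[1], r2 = R[2],
            miss_distance = sqrt(sum((g1 - g2)^2)))
}

#' Bundle the TDOA measurements of one detection
#'
#' Collects everything needed to localize one click: the six small-aperture
#' TDOAs of each available 4-channel array, and the measured large-aperture
#' TDOAs between instrument pairs (sign convention `(d_i - d_j)/c`).
#'
#' @param small Named list: array id -> numeric length-6 small-aperture TDOAs
#'   (s, [pair_index()] order). May be empty for no 4-channel data.
#' @param large `NULL` or data frame with columns `inst_i`, `inst_j`, `tdoa`
#'   (s).
#' @return An object of class `"tdoa_bundle"`.
#' @export
tdoa_bundle <- function(small = list(), large = NULL) {
  if (is.null(large)) {
    large <- data.frame(inst_i = character(0), inst_j = character(0),
                        tdoa = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(small = small, large = large), class = "tdoa_bundle")
}

# All localizable instrument combinations in a bundle:
#  - for each array with a DOA and each large TDOA involving that array:
#    DOA ray + hyperboloid;
#  - for each pair of arrays with DOAs: two-DOA intersect.
bundle_combinations <- function(bundle) {
  arrays <- names(bundle$small)
  combos <- list()
  lg <- bundle$large
  for (a in arrays) {
    if (nrow(lg)) {
      for (r in seq_len(nrow(lg))) {
        if (lg$inst_i[r] == a || lg$inst_j[r] == a) {
          partner <- if (lg$inst_i[r] == a) lg$inst_j[r] else lg$inst_i[r]
          combos[[length(combos) + 1L]] <-
            list(type = "doa_tdoa", array = a, partner = partner,
                 large_row = r,
                 tag = paste0(a, "+", partner))
        }
      }
    }
  }
  if (length(arrays) >= 2L) {
    pr <- utils::combn(arrays, 2L)
    for (k in seq_len(ncol(pr))) {
      combos[[length(combos) + 1L]] <-
        list(type = "two_doa", array = pr[1L, k], array2 = pr[2L, k],
             tag = paste0(pr[1L, k], "x", pr[2L, k]))
    }
  }
  combos
}

#' Monte-Carlo localization of one detection
#'
#' Approximates the distribution of source locations consistent with one
#' detection's TDOAs: in each of `n_perturb` passes, Gaussian noise with
#' standard deviation [sigma_small()] / [sigma_large()] is added to the
#' small- / large-aperture TDOAs, the DOAs are re-solved from the perturbed
#' small-aperture TDOAs, and every available instrument combination (DOA ray
#' + hyperboloid, and two-DOA intersect) is localized. All samples are kept
#' with their combination tags.
#'
#' @param bundle A [tdoa_bundle()].
#' @param geometry A [deployment_geometry()].
#' @param params An [uncertainty_params()] (defaults to
#'   `geometry$uncertainty`).
#' @param n_perturb Number of random perturbations (default 50).
#' @param range_grid Range grid for the DOA+TDOA path.
#' @param seed Optional RNG seed for reproducible perturbations; recorded on
#'   the output.
#' @return Data frame of class `"mc_samples"`: `x, y, z, combination,
#'   perturbation, at_boundary`; attribute `seed`. Zero rows when no valid
#'   combination exists.
#' @export
monte_carlo_localize <- function(bundle, geometry, params = NULL,
                                 n_perturb = 50, range_grid = NULL,
                                 seed = NULL) {
  stopifnot(inherits(bundle, "tdoa_bundle"))
  if (is.null(params)) params <- geometry$uncertainty
  if (!is.null(seed)) set.seed(seed)
  combos <- bundle_combinations(bundle)
  if (length(combos) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      combination = character(0), perturbation = integer(0),
                      at_boundary = logical(0), stringsAsFactors = FALSE)
    return(structure(out, seed = seed, class = c("mc_samples", "data.frame")))
  }
  c_ms <- geometry$c
  arrays <- names(bundle$small)
  pair_norms <- lapply(arrays, function(a) {
    sqrt(rowSums(pair_matrix(geometry$instruments[[a]]$offsets)^2))
  })
  names(pair_norms) <- arrays
  sig_small <- lapply(arrays, function(a) {
    sigma_small(params, bundle$small[[a]], c_ms,
                pair_norm = pair_norms[[a]])
  })
  names(sig_small) <- arrays
  sig_large <- if (nrow(bundle$large)) {
    sigma_large(params, bundle$large$tdoa, c_ms)
  } else numeric(0)
  rows <- vector("list", n_perturb * length(combos))
  ri <- 0L
  for (p in seq_len(n_perturb)) {
    doas <- lapply(arrays, function(a) {
      tau <- bundle$small[[a]] + stats::rnorm(6L) * sig_small[[a]]
      solve_doa(tau, geometry$instruments[[a]]$offsets, c_ms)
    })
    names(doas) <- arrays
    lg_tdoa <- if (nrow(bundle$large)) {
      bundle$large$tdoa + stats::rnorm(nrow(bundle$large)) * sig_large
    } else numeric(0)
    for (cb in combos) {
      ri <- ri + 1L
      if (cb$type == "doa_tdoa") {
        a <- cb$array
        r <- cb$large_row
        tdoa_ap <- lg_tdoa[r]
        # orient the measurement as (d_array - d_partner)/c
        if (bundle$large$inst_i[r] != a) tdoa_ap <- -tdoa_ap
        est <- localize_doa_plus_tdoa(
          doas[[a]],
          instrument_position(geometry, a),
          instrument_position(geometry, cb$partner),
          tdoa_ap, c_ms, range_grid,
          focus_i = reference_hydrophone_position(geometry, a),
          focus_j = reference_hydrophone_position(geometry, cb$partner))
        rows[[ri]] <- data.frame(x = est[1], y = est[2], z = est[3],
                                 combination = cb$tag, perturbation = p,
                                 at_boundary = attr(est, "at_boundary"),
                                 stringsAsFactors = FALSE)
      } else {
        est <- tryCatch(
          localize_two_doa(doas[[cb$array]],
                           instrument_position(geometry, cb$array),
                           doas[[cb$array2]],
                           instrument_position(geometry, cb$array2)),
          error = function(e) NULL)
        if (is.null(est)) next
        rows[[ri]] <- data.frame(x = est[1], y = est[2], z = est[3],
                                 combination = cb$tag, perturbation = p,
                                 at_boundary = FALSE,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  structure(out, seed = seed, class = c("mc_samples", "data.frame"))
}

# Per-combination inverse-variance weights, one weight per sample.
# Zero-variance combinations are capped at 1/(0.1 m)^2.
sample_weights <- function(samples, var_floor = 0.01) {
  w <- numeric(nrow(samples))
  for (tag in unique(samples$combination)) {
    idx <- samples$combination == tag
    v <- mean(c(var_or_zero(samples$x[idx]), var_or_zero(samples$y[idx]),
                var_or_zero(samples$z[idx])))
    w[idx] <- 1 / max(v, var_floor)
  }
  w
}

var_or_zero <- function(x) if (length(x) < 2L) 0 else stats::var(x)

weighted_mean3 <- function(samples, w) {
  c(x = sum(w * samples$x), y = sum(w * samples$y),
    z = sum(w * samples$z)) / sum(w)
}

weighted_sd3 <- function(samples, w, center) {
  sw <- sum(w)
  c(x = sum(w * (samples$x - center[1])^2),
    y = sum(w * (samples$y - center[2])^2),
    z = sum(w * (samples$z - center[3])^2)) / sw
}

#' Bootstrap location estimate with Studentized confidence intervals
#'
#' Combines a Monte-Carlo sample cloud into a single location estimate.
#' Samples are weighted by the inverse variance of their instrument
#' combination (zero-variance combinations capped at 1/(0.1 m)^2). The cloud
#' is resampled with replacement `n_boot` times; each resample yields a
#' weighted-average location, and the final position is the mean of those
#' resampled averages.
#'
#' The 95% intervals are Studentized against the spread of *per-perturbation
#' replicate estimates*: the weighted combination of all instrument
#' combinations within one perturbation is one complete localization under
#' one fresh draw of TDOA noise at the assumed sigmas, so the per-axis
#' standard deviation of these replicates estimates the final estimator's
#' error under measurement noise — the quantity a confidence interval must
#' scale with. (Neither the pooled cloud spread, which ignores the
#' inverse-variance combination of instrument pairs, nor the standard error
#' of the cloud mean, which treats perturbations as independent data, has
#' that property.) The replicate estimates are Studentized about the final
#' position, their alpha/2 quantiles are bootstrap-averaged over the
#' resamples, and the interval is the final position plus those pivot
#' quantiles times the replicate standard deviation.
#'
#' @param samples An `"mc_samples"` data frame from [monte_carlo_localize()].
#' @param n_boot Number of bootstrap resamples (default 50).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @param drop_boundary Drop samples flagged `at_boundary` first (default
#'   TRUE; they revert to all samples if everything is flagged).
#' @return An object of class `"location_estimate"`: list with `position`
#'   (x, y, z), `ci_lower`, `ci_upper` (per axis), `combinations`,
#'   `n_samples`, `seed`.
#' @export
bootstrap_location <- function(samples, n_boot = 50, conf = 0.95,
                               seed = NULL, drop_boundary = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (drop_boundary && any(!samples$at_boundary)) {
    samples <- samples[!samples$at_boundary, , drop = FALSE]
  }
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 Monte-Carlo samples")
  w <- sample_weights(samples)
  # replicate estimates: one weighted combination per perturbation
  perturb <- samples$perturbation %||% seq_len(n)
  reps <- t(vapply(unique(perturb), function(p) {
    idx <- perturb == p
    weighted_mean3(samples[idx, , drop = FALSE], w[idx])
  }, numeric(3)))
  n_rep <- nrow(reps)
  boot_means <- matrix(NA_real_, n_boot, 3L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_means[b, ] <- weighted_mean3(samples[idx, , drop = FALSE], w[idx])
  }
  position <- colMeans(boot_means)
  names(position) <- c("x", "y", "z")
  sd_rep <- apply(reps, 2L, stats::sd)
  if (n_rep < 2L) sd_rep <- rep(0, 3L)
  alpha <- (1 - conf) / 2
  qlo <- matrix(0, n_boot, 3L)
  qhi <- matrix(0, n_boot, 3L)
  for (b in seq_len(n_boot)) {
    ridx <- sample.int(n_rep, n_rep, replace = TRUE)
    for (ax in 1:3) {
      if (sd_rep[ax] > 0) {
        t_pivot <- (reps[ridx, ax] - position[ax]) / sd_rep[ax]
        qs <- stats::quantile(t_pivot, c(alpha, 1 - alpha), names = FALSE)
        qlo[b, ax] <- qs[1]
        qhi[b, ax] <- qs[2]
      }
    }
  }
  # Small-sample floor on the pivot quantiles: empirical quantiles of ~50
  # replicates are biased toward zero; under Gaussian replicates the exact
  # predictive quantile is qt(., n_rep - 1) * sqrt(1 + 1/n_rep).
  q_floor <- stats::qt(1 - alpha, df = max(n_rep - 1L, 1L)) *
    sqrt(1 + 1 / n_rep)
  ci_lower <- position + pmin(colMeans(qlo), -q_floor) * sd_rep
  ci_upper <- position + pmax(colMeans(qhi), q_floor) * sd_rep
  structure(list(position = position,
                 ci_lower = pmin(ci_lower, position),
                 ci_upper = pmax(ci_upper, position),
                 combinations = unique(samples$combination),
                 n_samples = n, seed = seed),
            class = "location_estimate")
}

#' @export
print.location_estimate <- function(x, ...) {
  cat(sprintf(paste0("<location_estimate> (%.1f, %.1f, %.1f) m, ",
                     "CI x [%.1f, %.1f] y [%.1f, %.1f] z [%.1f, %.1f], ",
                     "%d samples (%s)\n"),
              x$position[1], x$position[2], x$position[3],
              x$ci_lower[1], x$ci_upper[1], x$ci_lower[2], x$ci_upper[2],
              x$ci_lower[3], x$ci_upper[3], x$n_samples,
              paste(x$combinations, collapse = ", ")))
  invisible(x)
}

#' Two-DOA localization with jackknife confidence intervals
#'
#' Fast linearized localization for deployments with two volumetric arrays:
#' the full estimate intersects the two 6-TDOA DOAs ([localize_two_doa()]).
#' Uncertainty comes from 12 leave-one-TDOA-out re-estimates: each of the six
#' TDOAs on each array is dropped in turn, that array's DOA re-solved from
#' the remaining five, and the intersection recomputed with the other
#' array's full DOA. The jackknife variance of the 12 positions enters a
#' Student-t quantile for the 95% per-axis intervals.
#'
#' @param small_tdoas_1,small_tdoas_2 Numeric length-6 small-aperture TDOA
#'   vectors (s) for the two arrays (or `"small_tdoa"` objects).
#' @param geometry A [deployment_geometry()] containing both arrays.
#' @param array_ids Character vector of the two array ids; defaults to the
#'   first two 4-channel instruments in `geometry`.
#' @param conf Confidence level (default 0.95).
#' @return A `"location_estimate"` (position, per-axis CI bounds,
#'   `combinations`, `n_samples = 12`), plus attribute `jackknife`
#'   (12 x 3 matrix of leave-one-out positions).
#' @export
jackknife_two_doa <- function(small_tdoas_1, small_tdoas_2, geometry,
                              array_ids = NULL, conf = 0.95) {
  tau1 <- if (inherits(small_tdoas_1, "small_tdoa")) small_tdoas_1$tdoa
          else as.numeric(small_tdoas_1)
  tau2 <- if (inherits(small_tdoas_2, "small_tdoa")) small_tdoas_2$tdoa
          else as.numeric(small_tdoas_2)
  if (length(tau1) != 6L || length(tau2) != 6L ||
      !all(is.finite(c(tau1, tau2)))) {
    stop("insufficient data: both arrays need all 6 TDOAs")
  }
  if (is.null(array_ids)) {
    is4 <- vapply(geometry$instruments, function(i) i$n_channels == 4L,
                  logical(1))
    array_ids <- names(geometry$instruments)[is4][1:2]
  }
  if (length(array_ids) != 2L || any(is.na(array_ids))) {
    stop("need two 4-channel arrays")
  }
  off1 <- geometry$instruments[[array_ids[1]]]$offsets
  off2 <- geometry$instruments[[array_ids[2]]]$offsets
  h1 <- instrument_position(geometry, array_ids[1])
  h2 <- instrument_position(geometry, array_ids[2])
  c_ms <- geometry$c
  doa1 <- solve_doa(tau1, off1, c_ms)
  doa2 <- solve_doa(tau2, off2, c_ms)
  full <- localize_two_doa(doa1, h1, doa2, h2)
  jk <- matrix(NA_real_, 12L, 3L)
  for (k in seq_len(6L)) {
    d1k <- solve_doa_subset(tau1, off1, c_ms, drop = k)
    jk[k, ] <- as.numeric(localize_two_doa(d1k, h1, doa2, h2))
    d2k <- solve_doa_subset(tau2, off2, c_ms, drop = k)
    jk[6L + k, ] <- as.numeric(localize_two_doa(doa1, h1, d2k, h2))
  }
  nj <- nrow(jk)
  jbar <- colMeans(jk)
  jvar <- (nj - 1) / nj * colSums((jk - matrix(jbar, nj, 3L, TRUE))^2)
  tq <- stats::qt(1 - (1 - conf) / 2, df = nj - 1L)
  half <- tq * sqrt(jvar)
  position <- stats::setNames(as.numeric(full), c("x", "y", "z"))
  structure(list(position = position,
                 ci_lower = position - half,
                 ci_upper = position + half,
                 combinations = paste0(array_ids[1], "x", array_ids[2]),
                 n_samples = nj, seed = NULL),
            class = "location_estimate",
            jackknife = jk, miss_distance = attr(full, "miss_distance"))
}

# DOA from 5 of the 6 pair equations (leave-one-out).
solve_doa_subset <- function(tau, offsets, c_ms, drop) {
  H <- pair_matrix(offsets)[-drop, , drop = FALSE]
  s_raw <- qr.solve(H, c_ms * tau[-drop])
  nrm <- sqrt(sum(s_raw^2))
  if (nrm < 1e-9) stop("indeterminate DOA in jackknife subset")
  doa(s_raw / nrm)
}

#' Fill short gaps in a per-pair TDOA series
#'
#' Linearly interpolates missing TDOA values between bracketing measurements
#' when the bracketing detections are no more than `max_gap` apart (default
#' 5 minutes); longer gaps are left missing. Interpolated entries are
#' flagged.
#'
#' @param time Numeric, strictly increasing times (s) of the full detection
#'   sequence.
#' @param tdoa Numeric TDOAs (s) with `NA` where the pair has no measurement.
#' @param max_gap Maximum bracketing-measurement separation to fill (s).
#' @return Data frame `time, tdoa, interpolated`.
#' @export
interpolate_tdoa_gaps <- function(time, tdoa, max_gap = 300) {
  stopifnot(length(time) == length(tdoa))
  if (is.unsorted(time, strictly = FALSE)) stop("time must be sorted")
  out <- data.frame(time = time, tdoa = tdoa, interpolated = FALSE)
  obs <- which(is.finite(tdoa))
  if (length(obs) < 2L) return(out)
  for (k in seq_len(length(obs) - 1L)) {
    i <- obs[k]
    j <- obs[k + 1L]
    if (j - i <= 1L) next
    if (time[j] - time[i] > max_gap) next
    mid <- (i + 1L):(j - 1L)
    out$tdoa[mid] <- tdoa[i] + (tdoa[j] - tdoa[i]) *
      (time[mid] - time[i]) / (time[j] - time[i])
    out$interpolated[mid] <- TRUE
  }
  out
}
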