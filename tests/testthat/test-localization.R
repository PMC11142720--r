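test_that("TDOA error budgets reduce to single terms and match hand evaluation", {
  p0 <- uncertainty_params()
  expect_equal(sigma_small(p0, 1e-4, 1500), 0)
  expect_equal(sigma_large(p0, 1e-4, 1500), 0)
  expect_equal(sigma_small(uncertainty_params(sigma_xcorr = 1e-5), 0, 1500),
               1e-5)
  expect_equal(sigma_large(uncertainty_params(sigma_drift = 3e-4), 0, 1500),
               3e-4)
  set.seed(41)
  for (k in 1:200) {
    v <- stats::runif(8, 0, 1)
    p <- uncertainty_params(sigma_H = v[1], pair_norm = 1 + v[2],
                            sigma_hi = 5 * v[3], sigma_ray = 1e-5 * v[4],
                            sigma_c = 3 * v[5], sigma_xcorr = 1e-5 * v[6],
                            sigma_traveltime = 1e-5 * v[7],
                            sigma_drift = 1e-4 * v[8])
    td <- stats::runif(1, -0.5, 0.5)
    cc <- stats::runif(1, 1400, 1550)
    # independent term-by-term evaluation of the printed budgets
    ref_s <- sqrt((v[1] / cc)^2 +
                    ((1 + v[2]) / cc)^2 *
                      ((5 * v[3])^2 / 100^2 + (1e-5 * v[4])^2) +
                    (td / cc)^2 * (3 * v[5])^2 + (1e-5 * v[6])^2)
    ref_l <- sqrt(((5 * v[3])^2 + (5 * v[3])^2) / cc^2 +
                    td^2 * (3 * v[5])^2 / cc^2 + (1e-5 * v[7])^2 +
                    (1e-4 * v[8])^2 + (1e-5 * v[6])^2)
    expect_equal(sigma_small(p, td, cc), ref_s, tolerance = 1e-12)
    expect_equal(sigma_large(p, td, cc), ref_l, tolerance = 1e-12)
  }
  expect_error(uncertainty_params(sigma_H = -1), ">= 0")
})

test_that("DOA-ray + hyperboloid localization inverts the forward model", {
  set.seed(42)
  h1 <- c(0, 0, 6)
  h2 <- c(700, 100, 10)
  for (k in 1:20) {
    r_true <- stats::runif(1, 200, 3000)
    dir <- as.numeric(rand_unit(1))
    p <- h1 - dir * r_true       # dir = propagation direction source->array
    td <- expected_tdoa_large(p, h1, h2, 1500)
    est <- localize_doa_plus_tdoa(doa(dir), h1, h2, td, 1500,
                                  range_grid = seq(1, 4000, by = 1))
    expect_false(attr(est, "at_boundary"))
    expect_lt(sqrt(sum((as.numeric(est) - p)^2)), 0.5)
  }
  # TDOA larger than the baseline travel time fits no ray point
  est2 <- localize_doa_plus_tdoa(doa(c(0, 0, -1)), h1, h2,
                                 sqrt(sum((h1 - h2)^2)) / 1500 * 1.5, 1500,
                                 range_grid = seq(1, 4000, by = 1))
  expect_true(attr(est2, "at_boundary"))
})

test_that("ray localization matches a dense brute-force range search", {
  set.seed(43)
  for (k in 1:100) {
    h1 <- c(stats::runif(2, -200, 200), stats::runif(1, 0, 20))
    h2 <- h1 + c(stats::runif(2, 300, 900), stats::runif(1, -5, 5))
    dir <- as.numeric(rand_unit(1))
    r_true <- stats::runif(1, 100, 2500)
    td <- expected_tdoa_large(h1 - dir * r_true, h1, h2, 1500) +
      stats::rnorm(1, sd = 2e-5)   # slight inconsistency, as in real data
    coarse <- localize_doa_plus_tdoa(doa(dir), h1, h2, td, 1500,
                                     range_grid = seq(1, 3000, by = 1))
    fine_grid <- seq(1, 3000, by = 0.1)
    brute <- localize_doa_plus_tdoa(doa(dir), h1, h2, td, 1500,
                                    range_grid = fine_grid)
    if (!attr(coarse, "at_boundary") && !attr(brute, "at_boundary")) {
      expect_lt(abs(attr(coarse, "range") - attr(brute, "range")), 0.5)
    }
  }
})

test_that("two-DOA intersection: exact, skew-line least squares, parallel error", {
  # lines through a common point recover it to machine precision
  p <- c(250, -120, 480)
  h1 <- c(0, 0, 0)
  h2 <- c(600, 50, 10)
  s1 <- (h1 - p) / sqrt(sum((h1 - p)^2))
  s2 <- (h2 - p) / sqrt(sum((h2 - p)^2))
  g <- localize_two_doa(doa(s1), h1, doa(s2), h2)
  expect_equal(as.numeric(g), p, tolerance = 1e-9)
  expect_lt(attr(g, "miss_distance"), 1e-9)
  # skew lines: midpoint of the common perpendicular, against a numeric oracle
  u1 <- c(1, 0, 0)
  h2b <- c(0, 1, 1)
  u2 <- c(0, 1, 0)
  g2 <- localize_two_doa(doa(-u1), h1, doa(-u2), h2b)
  fr <- function(r) sqrt(sum((u1 * r[1] + h1 - (u2 * r[2] + h2b))^2))
  op <- stats::optim(c(0, 0), fr)
  oracle_mid <- (u1 * op$par[1] + h1 + u2 * op$par[2] + h2b) / 2
  expect_equal(as.numeric(g2), oracle_mid, tolerance = 1e-4)
  expect_equal(attr(g2, "miss_distance"), 1, tolerance = 1e-9)
  expect_error(localize_two_doa(doa(c(0, 0, -1)), h1, doa(c(0, 0, -1)), h2),
               "parallel")
})

test_that("Monte-Carlo cloud: deterministic seed, zero-noise degeneracy, spread scaling", {
  geom <- default_deployment(uncertainty = uncertainty_params())
  p <- c(150, -250, 500)
  bundle <- make_bundle(p, geom)
  # all sigmas zero: every sample equals the noiseless solution
  samp0 <- monte_carlo_localize(bundle, geom, n_perturb = 8, seed = 5)
  for (tag in unique(samp0$combination)) {
    sub <- samp0[samp0$combination == tag, ]
    expect_lt(max(stats::sd(sub$x), stats::sd(sub$y), stats::sd(sub$z)), 1e-9)
  }
  # noiseless solutions all agree with the true position
  expect_lt(max(abs(samp0$x - p[1])), 0.2)
  expect_lt(max(abs(samp0$z - p[3])), 0.6)
  # fixed seed: bit-identical repetition
  params <- test_uncertainty()
  s1 <- monte_carlo_localize(bundle, geom, params, n_perturb = 10, seed = 7)
  s2 <- monte_carlo_localize(bundle, geom, params, n_perturb = 10, seed = 7)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$z, s2$z)
  # doubling the sigmas grows the per-combination spread
  params2 <- uncertainty_params(sigma_H = 0.1, sigma_hi = 2, sigma_ray = 2e-5,
                                sigma_c = 2, sigma_xcorr = 2e-5,
                                sigma_traveltime = 2e-5, sigma_drift = 2e-4)
  s3 <- monte_carlo_localize(bundle, geom, params2, n_perturb = 40, seed = 8)
  s1b <- monte_carlo_localize(bundle, geom, params, n_perturb = 40, seed = 8)
  spread <- function(s) mean(tapply(s$x, s$combination, stats::sd) +
                               tapply(s$z, s$combination, stats::sd))
  expect_gt(spread(s3), spread(s1b))
})

test_that("bootstrap combination: point degeneracy and inverse-variance weighting", {
  # identical samples collapse to a zero-width interval
  samp <- data.frame(x = rep(10, 20), y = rep(-5, 20), z = rep(300, 20),
                     combination = rep(c("a", "b"), 10),
                     perturbation = rep(1:10, each = 2),
                     at_boundary = FALSE)
  est <- bootstrap_location(samp, n_boot = 20, seed = 1)
  expect_equal(as.numeric(est$position), c(10, -5, 300))
  expect_equal(as.numeric(est$ci_upper - est$ci_lower), c(0, 0, 0))
  # two combinations, one with far larger variance: the final estimate
  # follows the low-variance combination
  set.seed(44)
  n <- 50
  good <- data.frame(x = stats::rnorm(n, 0, 1), y = stats::rnorm(n, 0, 1),
                     z = stats::rnorm(n, 100, 1), combination = "good",
                     perturbation = 1:n, at_boundary = FALSE)
  bad <- data.frame(x = stats::rnorm(n, 40, 10), y = stats::rnorm(n, 40, 10),
                    z = stats::rnorm(n, 140, 10), combination = "bad",
                    perturbation = 1:n, at_boundary = FALSE)
  est2 <- bootstrap_location(rbind(good, bad), n_boot = 50, seed = 2)
  w_expect <- c(1, 1 / 100)
  mu_expect <- (0 * w_expect[1] + 40 * w_expect[2]) / sum(w_expect)
  expect_lt(abs(est2$position[["x"]] - mu_expect), 2 * 1 / sqrt(n))
  expect_lt(abs(est2$position[["x"]]), 2)
})

test_that("jackknife two-DOA intervals: degeneracy, targeted corruption, monotone width", {
  geom <- default_deployment()
  p <- c(120, 260, 520)
  mk_tau <- function(a) {
    ctr <- instrument_position(geom, a)
    s <- (ctr - p) / sqrt(sum((ctr - p)^2))
    as.numeric(pair_matrix(geom$instruments[[a]]$offsets) %*% s) / geom$c
  }
  tau1 <- mk_tau("W")
  tau2 <- mk_tau("E")
  est <- jackknife_two_doa(tau1, tau2, geom, array_ids = c("W", "E"))
  expect_lt(sqrt(sum((est$position - p)^2)), 0.01)
  expect_lt(max(est$ci_upper - est$ci_lower), 1e-4)
  jk <- attr(est, "jackknife")
  expect_equal(nrow(jk), 12)
  expect_lt(max(apply(jk, 2, stats::sd)), 1e-6)
  # corrupt one TDOA: exactly one leave-one-out estimate recovers the clean
  # solution (the one dropping the corrupted pair)
  tau1c <- tau1
  tau1c[3] <- tau1c[3] + 5e-5
  estc <- jackknife_two_doa(tau1c, tau2, geom, array_ids = c("W", "E"))
  jkc <- attr(estc, "jackknife")
  d_clean <- sqrt(rowSums((jkc - matrix(p, 12, 3, TRUE))^2))
  expect_equal(sum(d_clean < 0.01), 1)
  expect_equal(which(d_clean < 0.01), 3L)
  # interval width grows with injected noise (in expectation)
  set.seed(45)
  width_at <- function(sg) {
    mean(replicate(30, {
      e <- jackknife_two_doa(tau1 + stats::rnorm(6, sd = sg),
                             tau2 + stats::rnorm(6, sd = sg), geom,
                             array_ids = c("W", "E"))
      mean(e$ci_upper - e$ci_lower)
    }))
  }
  ws <- vapply(c(1e-7, 1e-6, 1e-5), width_at, numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_error(jackknife_two_doa(tau1[1:5], tau2, geom,
                                 array_ids = c("W", "E")),
               "6 TDOAs")
})

test_that("short TDOA gaps are chord-interpolated, long gaps left missing", {
  time <- c(0, 60, 160, 460, 560, 580)
  tdoa <- c(0.1, NA, 0.2, NA, 0.3, NA)
  out <- interpolate_tdoa_gaps(time, tdoa, max_gap = 300)
  # 160 s gap (0 -> 160): filled on the chord
  expect_true(out$interpolated[2])
  expect_equal(out$tdoa[2], 0.1 + (0.2 - 0.1) * 60 / 160)
  # 400 s gap (160 -> 560): left missing
  expect_false(out$interpolated[4])
  expect_true(is.na(out$tdoa[4]))
  # trailing point has no bracketing measurement
  expect_true(is.na(out$tdoa[6]))
})
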