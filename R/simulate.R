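#' Tetrahedral hydrophone offsets
#'
#' Regular-tetrahedron hydrophone positions (m) centered on the instrument
#' reference point, with the given edge length (hydrophone spacing).
#'
#' @param edge Hydrophone spacing (m), default 1.
#' @return 4 x 3 numeric matrix.
#' @export
tetrahedron_offsets <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v * edge / (2 * sqrt(2))
}

#' Default two-array + two-single deployment
#'
#' A deployment emulating the kind of seafloor layout the toolkit targets:
#' two 4-channel tetrahedral arrays (~1 m aperture, 100 kHz) on an East-West
#' baseline 1070 m apart, and two single-channel instruments (200 kHz) to the
#' North and South, inter-instrument spacing within 470-1075 m. Coordinates
#' are local ENU meters with z positive up and the seafloor near z = 0.
#'
#' @param c_ms Sound speed (m/s).
#' @param uncertainty An [uncertainty_params()].
#' @return A [deployment_geometry()] with instruments `W`, `E` (4-channel)
#'   and `N`, `S` (single-channel).
#' @export
default_deployment <- function(c_ms = 1500,
                               uncertainty = uncertainty_params()) {
  deployment_geometry(list(
    list(id = "W", position = c(-535, 0, 6), n_channels = 4L, fs = 100000,
         offsets = tetrahedron_offsets(1)),
    list(id = "E", position = c(535, 0, 6), n_channels = 4L, fs = 100000,
         offsets = tetrahedron_offsets(1)),
    list(id = "N", position = c(0, 500, 10), n_channels = 1L, fs = 200000),
    list(id = "S", position = c(0, -500, 10), n_channels = 1L, fs = 200000)
  ), c_ms = c_ms, uncertainty = uncertainty)
}

#' Simulate a source track
#'
#' Either resamples piecewise-linear waypoints onto a regular grid, or builds
#' a parametric dive: a straight-line transit at constant speed with a linear
#' descent from `z_start` to the foraging depth `z_forage` over
#' `descent_time`, then level.
#'
#' @param duration Track duration (s).
#' @param dt Output time step (s).
#' @param waypoints Optional data frame `time, x, y, z`; interpolated
#'   linearly (constant beyond the ends).
#' @param start Start position (m) for the parametric dive.
#' @param heading_deg Horizontal heading (degrees counter-clockwise from
#'   East).
#' @param speed Horizontal speed (m/s).
#' @param z_forage Foraging height (m, same up-positive frame as the
#'   geometry).
#' @param descent_time Time (s) to reach `z_forage` from `start[3]`.
#' @return Data frame `time, x, y, z`.
#' @export
simulate_track <- function(duration, dt = 1, waypoints = NULL,
                           start = c(0, 0, 800), heading_deg = 90,
                           speed = 1.5, z_forage = 300,
                           descent_time = duration / 2) {
  if (dt <= 0) stop("dt must be > 0")
  tt <- seq(0, duration, by = dt)
  if (!is.null(waypoints)) {
    f <- function(col) stats::approx(waypoints$time, waypoints[[col]], tt,
                                     rule = 2)$y
    return(data.frame(time = tt, x = f("x"), y = f("y"), z = f("z")))
  }
  hr <- heading_deg * pi / 180
  z <- ifelse(tt < descent_time,
              start[3] + (z_forage - start[3]) * tt / descent_time,
              z_forage)
  data.frame(time = tt,
             x = start[1] + speed * cos(hr) * tt,
             y = start[2] + speed * sin(hr) * tt,
             z = z)
}

interp_track <- function(track, t) {
  cbind(stats::approx(track$time, track$x, t, rule = 2)$y,
        stats::approx(track$time, track$y, t, rule = 2)$y,
        stats::approx(track$time, track$z, t, rule = 2)$y)
}

#' Regular click schedule with jitter
#'
#' Emission times with a regular inter-click interval plus uniform jitter
#' (a fraction of the ICI), emulating odontocete search-click regularity.
#'
#' @param t_start,t_end Schedule window (s).
#' @param ici Mean inter-click interval (s).
#' @param jitter Fractional ICI jitter (default 0.1): each interval is
#'   `ici * (1 + U(-jitter, jitter))`.
#' @return Numeric emission times (uses the current RNG state).
#' @export
click_schedule <- function(t_start, t_end, ici = 0.4, jitter = 0.1) {
  n_max <- ceiling((t_end - t_start) / (ici * (1 - jitter))) + 2L
  gaps <- ici * (1 + stats::runif(n_max, -jitter, jitter))
  times <- t_start + cumsum(gaps) - gaps[1]
  times[times <= t_end]
}

#' Scene configuration for the simulator
#'
#' Describes a synthetic acoustic scene: deployment geometry, echolocating
#' sources (each a track plus click schedule parameters), Poisson clutter,
#' noise floor, per-instrument clock-drift polynomials, optional
#' synchronization pings, and the master seed from which all randomness
#' flows.
#'
#' @param geometry A [deployment_geometry()].
#' @param sources List of source descriptions: each a list with `id`,
#'   `track` (from [simulate_track()]), `ici` (s), `ici_jitter` (fraction),
#'   `amplitude` (source level in recorded units at 1 m), optional
#'   `beam_exponent` (cosine-power directivity about the heading; 0 = omni)
#'   and `t_start`/`t_end`.
#' @param duration Scene duration (s).
#' @param clutter_rate Poisson rate (clicks/s) of unassociated clutter per
#'   instrument.
#' @param noise_floor Gaussian noise standard deviation (recorded units).
#' @param drift_coef Named list instrument id -> polynomial coefficients
#'   (drift seconds as a function of time in s, constant term first); `NULL`
#'   for no drift.
#' @param pings Optional list `list(freq =, interval =, amplitude =,
#'   position =)` injecting periodic synchronization pings from a fixed
#'   position.
#' @param click_f0 Click carrier frequency (Hz), default 35 kHz (inside the
#'   detection band at both 100 and 200 kHz rates).
#' @param click_dur Click duration (s), default 0.2 ms.
#' @param seed Master RNG seed; recorded in all outputs.
#' @return An object of class `"scene_config"`.
#' @export
scene_config <- function(geometry, sources, duration, clutter_rate = 0,
                         noise_floor = 0, drift_coef = NULL, pings = NULL,
                         click_f0 = 35000, click_dur = 2e-4, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (clutter_rate < 0 || noise_floor < 0) stop("rates must be >= 0")
  structure(list(geometry = geometry, sources = sources,
                 duration = duration, clutter_rate = clutter_rate,
                 noise_floor = noise_floor, drift_coef = drift_coef,
                 pings = pings, click_f0 = click_f0, click_dur = click_dur,
                 seed = as.integer(seed)),
            class = "scene_config")
}

eval_drift <- function(drift_coef, id, t) {
  cf <- drift_coef[[id]]
  if (is.null(cf)) return(rep(0, length(t)))
  drop(outer(t, seq_along(cf) - 1L, `^`) %*% cf)
}

#' Forward-model the arrival times of a scene
#'
#' For every source click, computes the exact (spherical, constant-c)
#' arrival time at each instrument's reference point, plus per-channel
#' plane-wave delays from the true instantaneous DOA for 4-channel arrays,
#' plus the instrument's clock drift evaluated at the arrival. Emission
#' times come from [click_schedule()] under the scene seed.
#'
#' @param scene A [scene_config()].
#' @return A list of class `"ground_truth"`: `clicks` (data frame `source,
#'   time, x, y, z`), `arrivals` (data frame `source, click, instrument,
#'   channel, time, amplitude, doa_x, doa_y, doa_z`), `seed`.
#' @export
simulate_arrivals <- function(scene) {
  stopifnot(inherits(scene, "scene_config"))
  set.seed(scene$seed)
  geometry <- scene$geometry
  c_ms <- geometry$c
  clicks <- list()
  arrivals <- list()
  for (src in scene$sources) {
    t0 <- src$t_start %||% 0
    t1 <- src$t_end %||% scene$duration
    et <- click_schedule(t0, t1, src$ici %||% 0.4, src$ici_jitter %||% 0.1)
    if (length(et) == 0L) next
    pos <- interp_track(src$track, et)
    clicks[[length(clicks) + 1L]] <-
      data.frame(source = src$id, time = et, x = pos[, 1], y = pos[, 2],
                 z = pos[, 3], stringsAsFactors = FALSE)
    # heading for directivity
    posn <- interp_track(src$track, et + 1)
    head_vec <- posn - pos
    hn <- sqrt(rowSums(head_vec^2))
    hn[hn == 0] <- 1
    head_vec <- head_vec / hn
    for (inst in geometry$instruments) {
      dvec <- matrix(inst$position, length(et), 3L, TRUE) - pos
      r <- sqrt(rowSums(dvec^2))
      s <- dvec / r                       # propagation source -> receiver
      arr_ref <- et + r / c_ms
      drift <- eval_drift(scene$drift_coef, inst$id, arr_ref)
      amp <- (src$amplitude %||% 500) / r
      m <- src$beam_exponent %||% 0
      if (m > 0) {
        cosang <- rowSums(head_vec * s)
        amp <- amp * ((1 + cosang) / 2)^m
      }
      nch <- inst$n_channels
      for (ch in seq_len(nch)) {
        dt_ch <- if (nch == 4L) {
          as.numeric(s %*% inst$offsets[ch, ]) / c_ms
        } else 0
        arrivals[[length(arrivals) + 1L]] <-
          data.frame(source = src$id, click = seq_along(et),
                     instrument = inst$id, channel = ch,
                     time = arr_ref + dt_ch + drift, amplitude = amp,
                     doa_x = s[, 1], doa_y = s[, 2], doa_z = s[, 3],
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(clicks = if (length(clicks)) do.call(rbind, clicks) else
                   data.frame(),
                 arrivals = if (length(arrivals)) do.call(rbind, arrivals)
                   else data.frame(),
                 seed = scene$seed),
            class = "ground_truth")
}

# Continuous click template: Hann-windowed tone burst, evaluated at
# arbitrary (fractional-sample) times, so arrivals land exactly where the
# forward model puts them.
click_waveform <- function(t, f0, dur) {
  inside <- t >= 0 & t <= dur
  w <- numeric(length(t))
  ti <- t[inside]
  w[inside] <- sin(pi * ti / dur)^2 * cos(2 * pi * f0 * (ti - dur / 2))
  w
}

add_transient <- function(x, fs, t_arr, amp, f0, dur) {
  i0 <- floor(t_arr * fs) + 1L
  i1 <- ceiling((t_arr + dur) * fs) + 1L
  if (i1 < 1L || i0 > length(x)) return(x)
  i0 <- max(1L, i0)
  i1 <- min(length(x), i1)
  idx <- i0:i1
  x[idx] <- x[idx] + amp * click_waveform((idx - 1L) / fs - t_arr, f0, dur)
  x
}

#' Render the multichannel waveforms of a scene
#'
#' Turns a [simulate_arrivals()] ground truth into per-instrument waveforms:
#' each click is a short Hann-windowed tone burst placed at its exact
#' fractional-sample arrival time, scaled by spherical spreading (1/r) and
#' optional directivity; Gaussian noise at the configured floor; independent
#' Poisson clutter clicks per instrument (rendered with a random DOA so
#' 4-channel clutter still has physically consistent channel delays);
#' optional periodic narrowband pings, which alias naturally when the ping
#' frequency exceeds Nyquist.
#'
#' @param truth A `"ground_truth"` from [simulate_arrivals()].
#' @param scene The same [scene_config()].
#' @return Named list (by instrument id) of waveform matrices (n x channels),
#'   each with attribute `fs`; attribute `clipped` counts samples beyond
#'   |1e3| (a warning is raised if any).
#' @export
synthesize_waveforms <- function(truth, scene) {
  stopifnot(inherits(truth, "ground_truth"), inherits(scene, "scene_config"))
  set.seed(scene$seed + 1L)
  geometry <- scene$geometry
  c_ms <- geometry$c
  out <- list()
  for (inst in geometry$instruments) {
    fs <- inst$fs
    n <- ceiling(scene$duration * fs)
    nch <- inst$n_channels
    wf <- matrix(0, n, nch)
    if (nrow(truth$arrivals)) {
      rows <- truth$arrivals[truth$arrivals$instrument == inst$id, ,
                             drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        ch <- rows$channel[r]
        wf[, ch] <- add_transient(wf[, ch], fs, rows$time[r],
                                  rows$amplitude[r], scene$click_f0,
                                  scene$click_dur)
      }
    }
    n_clut <- stats::rpois(1L, scene$clutter_rate * scene$duration)
    if (n_clut > 0L) {
      tc <- stats::runif(n_clut, 0, scene$duration)
      ac <- stats::runif(n_clut, 0.3, 1.5)
      for (k in seq_len(n_clut)) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        for (ch in seq_len(nch)) {
          dt_ch <- if (nch == 4L) sum(u * inst$offsets[ch, ]) / c_ms else 0
          wf[, ch] <- add_transient(wf[, ch], fs, tc[k] + dt_ch, ac[k],
                                    scene$click_f0, scene$click_dur)
        }
      }
    }
    if (!is.null(scene$pings)) {
      pg <- scene$pings
      dist <- sqrt(sum((pg$position - inst$position)^2))
      tp <- seq(0, scene$duration, by = pg$interval) + dist / c_ms
      drift <- eval_drift(scene$drift_coef, inst$id, tp)
      tp <- tp + drift
      for (t_arr in tp[tp < scene$duration]) {
        for (ch in seq_len(nch)) {
          wf[, ch] <- add_transient(wf[, ch], fs, t_arr, pg$amplitude,
                                    pg$freq, pg$dur %||% 5e-3)
        }
      }
    }
    if (scene$noise_floor > 0) {
      wf <- wf + matrix(stats::rnorm(n * nch, sd = scene$noise_floor),
                        n, nch)
    }
    clipped <- sum(abs(wf) > 1e3)
    if (clipped > 0) {
      warning("instrument ", inst$id, ": ", clipped, " clipped samples")
    }
    attr(wf, "fs") <- fs
    attr(wf, "clipped") <- clipped
    out[[inst$id]] <- wf
  }
  attr(out, "seed") <- scene$seed
  out
}
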