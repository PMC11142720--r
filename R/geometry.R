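#' Hydrophone pair index for a 4-channel array
#'
#' The fixed ordering of the six hydrophone pairs of a tetrahedral 4-channel
#' array: (1,2), (1,3), (1,4), (2,3), (2,4), (3,4). All small-aperture TDOA
#' vectors in the package follow this ordering so files are comparable across
#' runs.
#'
#' @return A 6 x 2 integer matrix; each row is one (i, j) channel pair.
#' @export
pair_index <- function() {
  matrix(c(1L, 2L, 1L, 3L, 1L, 4L, 2L, 3L, 2L, 4L, 3L, 4L),
         ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("i", "j")))
}

#' Pair-vector matrix of a hydrophone array
#'
#' Stacks the six pair vectors \eqn{h_j - h_i} (rows, in [pair_index()] order)
#' of a 4-hydrophone array into the design matrix of the plane-wave TDOA
#' system.
#'
#' @param offsets 4 x 3 numeric matrix of hydrophone positions (m), relative
#'   to the instrument reference point, in an East-North-Up frame.
#' @return 6 x 3 numeric matrix.
#' @export
pair_matrix <- function(offsets) {
  offsets <- as.matrix(offsets)
  if (!all(dim(offsets) == c(4L, 3L))) {
    stop("offsets must be a 4 x 3 matrix of hydrophone positions")
  }
  p <- pair_index()
  offsets[p[, 2L], , drop = FALSE] - offsets[p[, 1L], , drop = FALSE]
}

check_position <- function(p, what = "position") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop("invalid geometry: ", what, " must be 3 finite coordinates (m, ENU)")
  }
  p
}

#' Exact (large-aperture) time difference of arrival
#'
#' TDOA of a signal from `source` between receivers `rec_i` and `rec_j` under
#' straight-ray constant-sound-speed propagation:
#' \deqn{TDOA_{i,j} = (\|source - rec_i\| - \|source - rec_j\|) / c.}
#' Positive when the signal reaches receiver j first. A single TDOA constrains
#' the source to one sheet of a hyperboloid with foci at the receivers.
#'
#' @param source,rec_i,rec_j Numeric length-3 positions (m, local East-North-Up
#'   frame, z positive up).
#' @param c_ms Sound speed (m/s).
#' @return TDOA in seconds.
#' @export
expected_tdoa_large <- function(source, rec_i, rec_j, c_ms) {
  source <- check_position(source, "source")
  rec_i <- check_position(rec_i, "rec_i")
  rec_j <- check_position(rec_j, "rec_j")
  if (!is.finite(c_ms) || c_ms <= 0) stop("invalid geometry: c must be > 0")
  di <- sqrt(sum((source - rec_i)^2))
  dj <- sqrt(sum((source - rec_j)^2))
  if (di == 0 || dj == 0) {
    stop("invalid geometry: source coincides with a receiver")
  }
  (di - dj) / c_ms
}

#' Plane-wave (small-aperture) time difference of arrival
#'
#' For receivers much closer together than the source range, the wavefront is
#' effectively planar across the array and the TDOA reduces to
#' \deqn{TDOA_{i,j} = s \cdot (h_j - h_i) / c,}
#' where `s` is the unit vector along the direction of propagation (pointing
#' from source toward receiver).
#'
#' @param doa A [doa()] object (or unit length-3 vector) pointing
#'   source-to-receiver.
#' @param offset_i,offset_j Hydrophone positions (m) relative to the
#'   instrument reference point.
#' @param c_ms Sound speed (m/s).
#' @return TDOA in seconds.
#' @export
expected_tdoa_small <- function(doa, offset_i, offset_j, c_ms) {
  s <- unclass(doa)
  s <- check_position(s, "doa vector")
  offset_i <- check_position(offset_i, "offset_i")
  offset_j <- check_position(offset_j, "offset_j")
  if (!is.finite(c_ms) || c_ms <= 0) stop("invalid geometry: c must be > 0")
  h <- offset_j - offset_i
  if (sum(h^2) == 0) stop("degenerate pair: hydrophone offsets coincide")
  sum(s * h) / c_ms
}

#' Direction-of-arrival unit vector
#'
#' Constructs a DOA object from a 3-vector pointing from the source toward the
#' receiver (the wavefront normal, i.e. the direction of propagation). Vectors
#' within 1e-6 of unit length are renormalized silently; larger deviations are
#' an error.
#'
#' @param s Numeric length-3 vector.
#' @return An object of class `"doa"`: the unit vector, with azimuth/elevation
#'   available via [doa_to_azel()].
#' @export
doa <- function(s) {
  s <- check_position(s, "doa vector")
  n <- sqrt(sum(s^2))
  if (n == 0) stop("indeterminate DOA: zero vector")
  if (abs(n - 1) > 1e-6) {
    stop("DOA vector is not unit length (|s| = ", format(n), ")")
  }
  structure(s / n, class = "doa")
}

#' @export
print.doa <- function(x, ...) {
  ae <- doa_to_azel(x)
  cat(sprintf("<doa> s = (%.6f, %.6f, %.6f)  az = %.3f deg  el = %.3f deg\n",
              x[1], x[2], x[3], ae[["az"]], ae[["el"]]))
  invisible(x)
}

#' Convert a DOA unit vector to azimuth and elevation
#'
#' Angles describe the direction from the receiver toward the source (hence
#' the sign flips on the propagation vector `s`):
#' \deqn{az = atan2(-s_y, -s_x), \quad el = 180 - acos(-s_z)}
#' in degrees. Azimuth is counter-clockwise from East (East 0, North 90),
#' elevation is 0 straight down, 90 horizontal, 180 straight up toward the sea
#' surface.
#'
#' @param s A [doa()] object or unit length-3 vector (source-to-receiver).
#' @return Named numeric vector `c(az =, el =)` in degrees, az in (-180, 180].
#' @export
doa_to_azel <- function(s) {
  s <- unclass(s)
  s <- check_position(s, "doa vector")
  n <- sqrt(sum(s^2))
  if (abs(n - 1) > 1e-6) stop("DOA vector is not unit length")
  s <- s / n
  az <- atan2(-s[2], -s[1]) * 180 / pi
  if (az <= -180) az <- az + 360
  el <- 180 - acos(max(-1, min(1, -s[3]))) * 180 / pi
  c(az = az, el = el)
}

#' Convert azimuth/elevation to a DOA unit vector
#'
#' Inverse of [doa_to_azel()]: builds the source-to-receiver propagation
#' vector from display angles (receiver-to-source convention).
#'
#' @param az Azimuth in degrees, counter-clockwise from East.
#' @param el Elevation in degrees in `[0, 180]` (0 down, 90 horizontal,
#'   180 up).
#' @return A [doa()] object.
#' @export
azel_to_doa <- function(az, el) {
  if (!is.finite(az) || !is.finite(el)) stop("az/el must be finite")
  if (el < 0 || el > 180) stop("elevation out of range [0, 180] degrees")
  azr <- az * pi / 180
  elr <- el * pi / 180
  # receiver->source vector u = -s; el measured from straight down
  sz <- cos(elr)            # -(-cos(pi - el)) worked through the sign flips
  h <- sin(elr)
  doa(c(-h * cos(azr), -h * sin(azr), sz))
}

#' Deployment geometry
#'
#' Describes one deployment: instrument positions in a common local
#' East-North-Up frame (m, z positive up), per-instrument channel counts and
#' sampling rates, hydrophone offsets for 4-channel volumetric arrays, the
#' (constant) sound speed, and TDOA uncertainty parameters.
#'
#' @param instruments A list; each element a list with fields `id` (character),
#'   `position` (length-3 numeric, m), `n_channels` (1 or 4), `fs` (Hz), and,
#'   for 4-channel instruments, `offsets` (4 x 3 matrix, m, relative to
#'   `position`).
#' @param c_ms Sound speed in m/s. The localization model assumes a constant
#'   sound speed; the default 1500 m/s is a nominal deep-water value and should
#'   be replaced by a site estimate, with its uncertainty in
#'   `uncertainty$sigma_c`.
#' @param uncertainty An [uncertainty_params()] object (may be all-zero).
#' @return An object of class `"deployment_geometry"`.
#' @export
deployment_geometry <- function(instruments, c_ms = 1500,
                                uncertainty = uncertainty_params()) {
  if (!is.list(instruments) || length(instruments) < 1L) {
    stop("invalid geometry: need at least one instrument")
  }
  if (!is.finite(c_ms) || c_ms <= 0) stop("invalid geometry: c must be > 0")
  ids <- character(length(instruments))
  for (k in seq_along(instruments)) {
    inst <- instruments[[k]]
    if (is.null(inst$id)) stop("instrument ", k, " has no id")
    ids[k] <- as.character(inst$id)
    inst$position <- check_position(inst$position,
                                    paste0("instrument ", inst$id))
    inst$n_channels <- as.integer(inst$n_channels %||% 1L)
    if (!inst$n_channels %in% c(1L, 4L)) {
      stop("instrument ", inst$id, ": n_channels must be 1 or 4")
    }
    if (is.null(inst$fs) || !is.finite(inst$fs) || inst$fs <= 0) {
      stop("instrument ", inst$id, ": invalid sampling rate")
    }
    if (inst$n_channels == 4L) {
      if (is.null(inst$offsets)) {
        stop("instrument ", inst$id, ": 4-channel instrument needs offsets")
      }
      inst$offsets <- as.matrix(inst$offsets)
      if (!all(dim(inst$offsets) == c(4L, 3L)) ||
          !all(is.finite(inst$offsets))) {
        stop("instrument ", inst$id, ": offsets must be a finite 4 x 3 matrix")
      }
      seps <- sqrt(rowSums(pair_matrix(inst$offsets)^2))
      if (any(seps <= 0)) {
        stop("instrument ", inst$id, ": coincident hydrophones in array")
      }
    } else {
      inst$offsets <- NULL
    }
    instruments[[k]] <- inst
  }
  if (anyDuplicated(ids)) stop("duplicate instrument ids")
  names(instruments) <- ids
  structure(list(instruments = instruments, c = c_ms,
                 uncertainty = uncertainty),
            class = "deployment_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.deployment_geometry <- function(x, ...) {
  cat("<deployment_geometry> ", length(x$instruments), " instruments, c = ",
      x$c, " m/s\n", sep = "")
  for (inst in x$instruments) {
    cat(sprintf("  %-8s %d ch @ %g kHz at (%.1f, %.1f, %.1f) m\n",
                inst$id, inst$n_channels, inst$fs / 1000,
                inst$position[1], inst$position[2], inst$position[3]))
  }
  invisible(x)
}

#' Position of an instrument in a deployment
#'
#' @param geometry A [deployment_geometry()].
#' @param id Instrument id.
#' @return Length-3 numeric position (m).
#' @export
instrument_position <- function(geometry, id) {
  inst <- geometry$instruments[[as.character(id)]]
  if (is.null(inst)) stop("unknown instrument id: ", id)
  inst$position
}

#' Position of the reference (channel-1) hydrophone
#'
#' The position at which an instrument's reference-channel waveform is
#' recorded: the instrument position plus, for 4-channel arrays, the first
#' hydrophone's offset. Large-aperture TDOAs measured on reference channels
#' constrain hyperboloids whose foci are these points; the ~0.5 m offset
#' between a tetrahedral array's centroid and its first hydrophone is worth
#' hundreds of microseconds of TDOA.
#'
#' @param geometry A [deployment_geometry()].
#' @param id Instrument id.
#' @return Length-3 numeric position (m).
#' @export
reference_hydrophone_position <- function(geometry, id) {
  inst <- geometry$instruments[[as.character(id)]]
  if (is.null(inst)) stop("unknown instrument id: ", id)
  if (inst$n_channels == 4L) inst$position + inst$offsets[1L, ]
  else inst$position
}

#' Read a deployment geometry configuration file
#'
#' The configuration is YAML with top-level fields `c` (sound speed, m/s),
#' `uncertainty` (named sigma fields, see [uncertainty_params()]), and
#' `instruments`: a list of records with `id`, `position` (3 numbers, m, ENU),
#' `n_channels`, `fs` (Hz) and, for 4-channel arrays, `offsets` (4 rows of 3
#' numbers, m). The loader validates the same invariants as
#' [deployment_geometry()].
#'
#' @param path Path to the YAML config.
#' @return A [deployment_geometry()].
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) stop("geometry config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$instruments)) stop("geometry config has no instruments")
  instruments <- lapply(cfg$instruments, function(inst) {
    if (!is.null(inst$offsets)) {
      inst$offsets <- do.call(rbind, lapply(inst$offsets, as.numeric))
    }
    inst$position <- as.numeric(inst$position)
    inst
  })
  unc <- do.call(uncertainty_params, as.list(cfg$uncertainty %||% list()))
  deployment_geometry(instruments, c_ms = cfg$c %||% 1500, uncertainty = unc)
}

#' Write a deployment geometry configuration file
#'
#' @param geometry A [deployment_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry_config <- function(geometry, path) {
  insts <- lapply(unname(geometry$instruments), function(inst) {
    out <- list(id = inst$id, position = as.numeric(inst$position),
                n_channels = inst$n_channels, fs = inst$fs)
    if (!is.null(inst$offsets)) {
      out$offsets <- lapply(seq_len(4L), function(r) {
        as.numeric(inst$offsets[r, ])
      })
    }
    out
  })
  cfg <- list(c = geometry$c,
              uncertainty = unclass(geometry$uncertainty),
              instruments = insts)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}
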