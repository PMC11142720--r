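#' Design the click-band high-pass filter
#'
#' Beaked-whale echolocation clicks concentrate energy above ~20 kHz while most
#' ambient and flow noise sits lower; a 4th-order elliptic high-pass at 20 kHz
#' (0.1 dB passband ripple, 40 dB stopband attenuation) applied zero-phase
#' (forward-backward, so the effective attenuation doubles and the phase delay
#' cancels) isolates the click band without shifting peak times.
#'
#' @param fs Sampling rate (Hz).
#' @param cutoff High-pass cutoff (Hz), default 20 kHz.
#' @param ripple_db Passband ripple (dB).
#' @param atten_db Minimum stopband attenuation (dB).
#' @param order Filter order.
#' @return An object of class `"click_filter"` wrapping the filter
#'   coefficients; apply with [apply_click_filter()].
#' @export
design_click_filter <- function(fs, cutoff = 20000, ripple_db = 0.1,
                                atten_db = 40, order = 4) {
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate")
  if (cutoff >= fs / 2) {
    stop("filter config error: cutoff (", cutoff,
         " Hz) must be below Nyquist (", fs / 2, " Hz)")
  }
  flt <- signal::ellip(order, ripple_db, atten_db, cutoff / (fs / 2),
                       type = "high")
  structure(list(b = flt$b, a = flt$a, fs = fs, cutoff = cutoff,
                 ripple_db = ripple_db, atten_db = atten_db, order = order),
            class = "click_filter")
}

#' Apply the click filter zero-phase
#'
#' Forward-backward (zero-phase) application of a [design_click_filter()]
#' filter. Works on a vector or column-wise on a multichannel matrix.
#'
#' @param filt A `"click_filter"`.
#' @param x Numeric vector or n x channels matrix.
#' @return Filtered data, same shape as `x`.
#' @export
apply_click_filter <- function(filt, x) {
  stopifnot(inherits(filt, "click_filter"))
  ff <- function(v) signal::filtfilt(signal::Arma(b = filt$b, a = filt$a), v)
  if (is.matrix(x)) apply(x, 2L, ff) else ff(x)
}

#' Convert a dB re 1 uPa threshold to linear recorded amplitude
#'
#' Maps a sound-pressure-level threshold (dB re 1 uPa) to the linear amplitude
#' in recorded units using a flat hydrophone + recorder sensitivity
#' (recorded units per uPa): `10^(db/20) * calibration`.
#'
#' @param db_re_1uPa Threshold in dB re 1 uPa (peak pressure).
#' @param calibration Recorded units per uPa (> 0).
#' @return Linear amplitude threshold in recorded units.
#' @seealso [db_from_amplitude()]
#' @export
amplitude_threshold_from_db <- function(db_re_1uPa, calibration = 1) {
  if (!is.finite(calibration) || calibration <= 0) {
    stop("calibration must be > 0")
  }
  10^(db_re_1uPa / 20) * calibration
}

#' Inverse of [amplitude_threshold_from_db()]
#'
#' @param amplitude Linear amplitude in recorded units (> 0).
#' @param calibration Recorded units per uPa (> 0).
#' @return Level in dB re 1 uPa.
#' @export
db_from_amplitude <- function(amplitude, calibration = 1) {
  if (!is.finite(calibration) || calibration <= 0) {
    stop("calibration must be > 0")
  }
  20 * log10(amplitude / calibration)
}

#' Construct a detection set
#'
#' A detection set is a data frame of click detections for one instrument:
#' columns `time` (s since recording start, instrument clock), `amplitude`
#' (linear peak value of the filtered waveform) and `instrument_id`, ordered
#' by time, with attributes `fs` and `instrument_id`.
#'
#' @param time,amplitude Numeric vectors.
#' @param instrument_id Instrument identifier.
#' @param fs Sampling rate (Hz).
#' @param label Optional character vector of source labels (default
#'   `NA`, i.e. unlabeled); the reserved label `"false"` marks rejected
#'   detections.
#' @return A `data.frame` of class `"detection_set"`.
#' @export
detection_set <- function(time, amplitude, instrument_id, fs,
                          label = NA_character_) {
  o <- order(time)
  d <- data.frame(time = as.numeric(time)[o],
                  amplitude = as.numeric(amplitude)[o],
                  instrument_id = rep_len(as.character(instrument_id),
                                          length(time)),
                  label = rep_len(as.character(label), length(time))[o],
                  stringsAsFactors = FALSE)
  structure(d, fs = fs, class = c("detection_set", "data.frame"))
}

#' Detect echolocation clicks in a filtered waveform
#'
#' Finds local maxima of the absolute filtered waveform above a linear
#' amplitude threshold, then prunes: within any `+/- prune_ms` window around a
#' larger peak, smaller peaks are removed (greedy, descending amplitude), so a
#' multi-cycle click yields a single detection.
#'
#' @param x Numeric waveform (already filtered with [apply_click_filter()];
#'   for 4-channel data pass the reference channel).
#' @param fs Sampling rate (Hz).
#' @param threshold Linear amplitude threshold (see
#'   [amplitude_threshold_from_db()]).
#' @param prune_ms Pruning half-window in milliseconds (default 5).
#' @param instrument_id Instrument identifier stored with the detections.
#' @return A [detection_set()]; empty if nothing exceeds the threshold.
#' @export
detect_clicks <- function(x, fs, threshold, prune_ms = 5,
                          instrument_id = "inst") {
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")
  a <- abs(as.numeric(x))
  n <- length(a)
  if (n < 3L) {
    return(detection_set(numeric(0), numeric(0), instrument_id, fs))
  }
  core <- a[2:(n - 1L)]
  is_peak <- core >= a[1:(n - 2L)] & core > a[3:n] & core > threshold
  idx <- which(is_peak) + 1L
  if (length(idx) == 0L) {
    return(detection_set(numeric(0), numeric(0), instrument_id, fs))
  }
  keep <- prune_peaks(idx, a[idx], prune_samples = prune_ms * 1e-3 * fs)
  detection_set((keep - 1L) / fs, a[keep], instrument_id, fs)
}

# Greedy pruning: visit peaks in descending amplitude; keep a peak only if no
# already-kept peak lies within the prune window. Returns kept indices sorted.
prune_peaks <- function(idx, amp, prune_samples) {
  o <- order(amp, decreasing = TRUE)
  idx_sorted <- idx[o]
  kept <- integer(0)
  for (i in idx_sorted) {
    if (length(kept) == 0L || min(abs(kept - i)) > prune_samples) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Re-prune a detection set
#'
#' Applies the same `+/- prune_ms` larger-peak rule to an existing detection
#' set (e.g. after merging). [detect_clicks()] output is idempotent under
#' re-pruning.
#'
#' @param dets A [detection_set()].
#' @param prune_ms Pruning half-window (ms).
#' @return A pruned [detection_set()].
#' @export
prune_detections <- function(dets, prune_ms = 5) {
  if (nrow(dets) == 0L) return(dets)
  o <- order(dets$amplitude, decreasing = TRUE)
  kept_t <- numeric(0)
  keep_row <- logical(nrow(dets))
  for (r in o) {
    t <- dets$time[r]
    if (length(kept_t) == 0L || min(abs(kept_t - t)) > prune_ms * 1e-3) {
      kept_t <- c(kept_t, t)
      keep_row[r] <- TRUE
    }
  }
  out <- dets[keep_row, , drop = FALSE]
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, fs = attr(dets, "fs"),
            class = c("detection_set", "data.frame"))
}
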