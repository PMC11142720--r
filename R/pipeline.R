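# High-level orchestration: from labelled detections on a reference array to
# per-detection TDOA bundles ready for the localizers.

#' Detect clicks and measure DOAs on every instrument of a scene
#'
#' Convenience driver for multi-instrument recordings: applies the click
#' filter, detects clicks on each instrument's reference channel, and builds
#' the DOA series of each 4-channel array.
#'
#' @param waveforms Named list (instrument id -> n x channels matrix with an
#'   `fs` attribute), e.g. from [synthesize_waveforms()] or [read_wav()].
#' @param geometry A [deployment_geometry()].
#' @param threshold Linear detection threshold.
#' @param prune_ms Detection pruning half-window (ms).
#' @return List with `filtered` (filtered waveforms), `detections` (named
#'   list of [detection_set()]s) and `series` (named list of DOA series for
#'   the 4-channel arrays).
#' @export
detect_scene <- function(waveforms, geometry, threshold, prune_ms = 5) {
  filtered <- list()
  detections <- list()
  series <- list()
  for (id in names(waveforms)) {
    inst <- geometry$instruments[[id]]
    fs <- attr(waveforms[[id]], "fs") %||% inst$fs
    filt <- design_click_filter(fs)
    x <- apply_click_filter(filt, waveforms[[id]])
    filtered[[id]] <- structure(x, fs = fs)
    ref <- if (is.matrix(x)) x[, 1L] else x
    detections[[id]] <- detect_clicks(ref, fs, threshold,
                                      prune_ms = prune_ms,
                                      instrument_id = id)
    if (inst$n_channels == 4L) {
      series[[id]] <- doa_series_from_waveform(x, fs, detections[[id]],
                                               inst$offsets,
                                               c_ms = geometry$c,
                                               array_id = id)
    }
  }
  list(filtered = filtered, detections = detections, series = series)
}

#' Associate and measure an encounter from labelled reference detections
#'
#' The automated half of the association workflow, once an analyst (or a
#' ground-truth labelling step) has labelled the reference array's
#' detections: click-train correlation against every other instrument,
#' fine-scale large-aperture TDOA measurement, label propagation to the
#' second array, and assembly of per-detection [tdoa_bundle()]s.
#'
#' @param scene_data Output of [detect_scene()].
#' @param geometry The [deployment_geometry()].
#' @param labels Character vector of source labels (or `NA`) for the
#'   reference array's detections, in detection order.
#' @param ref_id Reference (labelled) 4-channel array id.
#' @param step CTC window step in detections (default 10).
#' @param window_len CTC window length (s).
#' @param drift_allowance Extra slack (s) on the physical inter-instrument
#'   TDOA bound (default 0.05).
#' @param ... Passed to [measure_large_tdoas()].
#' @return List: `bundles` (for [localize_encounter()]), `ser_ref`,
#'   `ser_partner` (labelled DOA series), `large` (fine TDOA table),
#'   `ctc` (per-partner [sliding_ctc()] window tables).
#' @export
associate_encounter <- function(scene_data, geometry, labels, ref_id,
                                step = 10L, window_len = 30,
                                drift_allowance = 0.05, ...) {
  dets <- scene_data$detections
  stopifnot(length(labels) == nrow(dets[[ref_id]]))
  dets_ref <- dets[[ref_id]]
  dets_ref$label <- labels
  ser_ref <- scene_data$series[[ref_id]]
  ser_ref$label <- labels
  ids4 <- names(scene_data$series)
  array2 <- setdiff(ids4, ref_id)
  array2 <- if (length(array2)) array2[1] else NULL
  partners <- setdiff(names(dets), ref_id)
  large <- list()
  ctc <- list()
  ser2 <- NULL
  for (id in partners) {
    baseline <- sqrt(sum((instrument_position(geometry, ref_id) -
                            instrument_position(geometry, id))^2))
    ml <- baseline / geometry$c + drift_allowance
    res <- sliding_ctc(dets_ref, dets[[id]], max_lag = ml,
                       window_len = window_len, step = step)
    ctc[[id]] <- res$windows
    xr <- scene_data$filtered[[ref_id]]
    xp <- scene_data$filtered[[id]]
    large[[id]] <- measure_large_tdoas(
      if (is.matrix(xr)) xr[, 1L] else xr, attr(xr, "fs"),
      if (is.matrix(xp)) xp[, 1L] else xp, attr(xp, "fs"),
      dets_ref, res$windows, ref_id, id, ...)
    if (identical(id, array2)) {
      ser2 <- scene_data$series[[id]]
      ser2$label <- res$detections$label
    }
  }
  large <- do.call(rbind, large)
  bundles <- assemble_bundles(ser_ref, ser2, large,
                              ids = c(ref_id, array2))
  list(bundles = bundles, ser_ref = ser_ref, ser_partner = ser2,
       large = large, ctc = ctc)
}

#' Extract a waveform snippet around a time
#'
#' @param x Numeric waveform (one channel).
#' @param fs Sampling rate (Hz).
#' @param t_center Snippet center (s).
#' @param half_s Half-width (s).
#' @return The snippet with attribute `t_start` (the exact time of its
#'   first sample, s), or `NULL` when the window is not fully inside the
#'   recording. The requested center is rounded to the sample grid, so
#'   `t_start` — not `t_center - half_s` — must be used when converting
#'   cross-instrument correlation lags to TDOAs.
#' @export
extract_snippet <- function(x, fs, t_center, half_s) {
  i0 <- round(t_center * fs) + 1L
  h <- round(half_s * fs)
  lo <- i0 - h
  hi <- i0 + h
  if (lo < 1L || hi > length(x)) return(NULL)
  structure(x[lo:hi], t_start = (lo - 1L) / fs)
}

#' Coarse click-train delay for a label at arbitrary times
#'
#' Interpolates the accepted per-window [sliding_ctc()] delays of one source
#' label onto the requested times (constant beyond the first/last accepted
#' window).
#'
#' @param windows The `windows` data frame from [sliding_ctc()].
#' @param label Source label.
#' @param time Times (s).
#' @return Numeric delays (s); `NA` where the label has no accepted window.
#' @export
ctc_tau_at <- function(windows, label, time) {
  w <- windows[windows$accepted & is.finite(windows$tau) &
                 windows$label == label, , drop = FALSE]
  if (nrow(w) == 0L) return(rep(NA_real_, length(time)))
  if (nrow(w) == 1L) return(rep(w$tau, length(time)))
  stats::approx(w$t0, w$tau, time, rule = 2)$y
}

#' Fine large-aperture TDOAs for every labelled detection
#'
#' For each labelled detection on the reference instrument, predicts the
#' arrival time on a partner instrument from the accepted click-train delays,
#' extracts waveform snippets around both arrivals, and refines the delay by
#' sub-sample cross-correlation ([fine_tdoa()]). The returned TDOA follows
#' the hyperboloid convention `(d_ref - d_partner)/c`
#' ([expected_tdoa_large()] with the reference as receiver i), i.e. minus
#' the measured delay of the partner relative to the reference.
#'
#' @param x_ref,x_partner Filtered single-channel waveforms (reference
#'   channel for 4-channel data).
#' @param fs_ref,fs_partner Sampling rates (Hz).
#' @param dets_ref Labelled [detection_set()] on the reference instrument.
#' @param windows Accepted-window table from [sliding_ctc()] run against the
#'   partner instrument.
#' @param inst_ref,inst_partner Instrument ids for the output rows.
#' @param snippet_halfwidth Snippet half-width (s), default 8 ms: wide
#'   enough that the true arrival stays inside the window even when the
#'   coarse click-train delay lags a moving source by a few milliseconds.
#' @param search_halfwidth Residual delay search half-width (s), default
#'   5 ms.
#' @return Data frame `det_row, time, label, inst_i, inst_j, tdoa,
#'   peak_norm` with one row per labelled detection that could be measured
#'   reliably.
#' @export
measure_large_tdoas <- function(x_ref, fs_ref, x_partner, fs_partner,
                                dets_ref, windows, inst_ref, inst_partner,
                                snippet_halfwidth = 8e-3,
                                search_halfwidth = 5e-3) {
  rows <- list()
  for (k in seq_len(nrow(dets_ref))) {
    lab <- dets_ref$label[k]
    if (is.na(lab) || lab == "false") next
    tau_c <- ctc_tau_at(windows, lab, dets_ref$time[k])
    if (!is.finite(tau_c)) next
    si <- extract_snippet(x_ref, fs_ref, dets_ref$time[k],
                          snippet_halfwidth)
    sj <- extract_snippet(x_partner, fs_partner, dets_ref$time[k] + tau_c,
                          snippet_halfwidth)
    if (is.null(si) || is.null(sj)) next
    # delay between the snippet grids, exact on each instrument's clock
    grid_offset <- attr(sj, "t_start") - attr(si, "t_start")
    ft <- fine_tdoa(si, fs_ref, sj, fs_partner, grid_offset,
                    search_halfwidth)
    if (!ft$reliable) next
    rows[[length(rows) + 1L]] <-
      data.frame(det_row = k, time = dets_ref$time[k], label = lab,
                 inst_i = inst_ref, inst_j = inst_partner,
                 tdoa = -ft$tau, peak_norm = ft$peak_norm,
                 stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(det_row = integer(0), time = numeric(0),
               label = character(0), inst_i = character(0),
               inst_j = character(0), tdoa = numeric(0),
               peak_norm = numeric(0), stringsAsFactors = FALSE)
}

#' Assemble per-detection TDOA bundles for localization
#'
#' Joins a labelled reference-array DOA series with an optional second-array
#' series (matched by label and by the predicted arrival time from the
#' measured ref-partner TDOA, falling back to nearest-in-time within
#' `tol`) and with measured large-aperture TDOA rows, producing the
#' per-detection input of [localize_encounter()].
#'
#' @param ser_ref Labelled `"doa_series"` of the reference array (with
#'   `tdoa1..tdoa6` columns).
#' @param ser_partner Optional second-array `"doa_series"`.
#' @param large Optional [measure_large_tdoas()] table (may include several
#'   partner instruments).
#' @param ids Character vector: id of the reference array and, if
#'   `ser_partner` is given, of the second array.
#' @param tol Time-matching tolerance (s) for the second array.
#' @return List of bundle entries (`time`, `label`, `bundle`, and
#'   `small_1`/`small_2` where available).
#' @export
assemble_bundles <- function(ser_ref, ser_partner = NULL, large = NULL,
                             ids, tol = 20e-3) {
  tdoa_cols <- paste0("tdoa", 1:6)
  bundles <- list()
  for (k in seq_len(nrow(ser_ref))) {
    lab <- ser_ref$label[k]
    if (is.na(lab) || lab == "false") next
    b <- list(time = ser_ref$time[k], label = lab)
    b$small_1 <- as.numeric(ser_ref[k, tdoa_cols])
    small <- stats::setNames(list(b$small_1), ids[1])
    lg <- NULL
    if (!is.null(large) && nrow(large)) {
      lr <- large[large$label == lab &
                    abs(large$time - b$time) < 1e-9, , drop = FALSE]
      if (nrow(lr)) {
        lg <- data.frame(inst_i = lr$inst_i, inst_j = lr$inst_j,
                         tdoa = lr$tdoa, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(ser_partner) && length(ids) >= 2L) {
      cand <- which(!is.na(ser_partner$label) & ser_partner$label == lab)
      if (length(cand)) {
        t_exp <- b$time
        if (!is.null(lg) && any(lg$inst_j == ids[2])) {
          t_exp <- b$time - lg$tdoa[lg$inst_j == ids[2]][1]
        }
        m <- cand[which.min(abs(ser_partner$time[cand] - t_exp))]
        if (abs(ser_partner$time[m] - t_exp) <= tol) {
          b$small_2 <- as.numeric(ser_partner[m, tdoa_cols])
          small[[ids[2]]] <- b$small_2
        }
      }
    }
    b$bundle <- tdoa_bundle(small, lg)
    bundles[[length(bundles) + 1L]] <- b
  }
  bundles
}
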