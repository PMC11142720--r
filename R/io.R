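# CSV schemas are versioned with a header comment ("# clicktrackr <kind> v1")
# so downstream loaders can reject files they do not understand.

csv_header <- function(kind) sprintf("# clicktrackr %s v1", kind)

write_versioned_csv <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header(kind), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_versioned_csv <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!identical(first, csv_header(kind))) {
    stop("unrecognized ", kind, " file version: ", first)
  }
  utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
}

#' Read and write detection sets as CSV
#'
#' Columns: `instrument_id, time, amplitude, label`; the file carries a
#' schema-version header comment and the sampling rate as a second comment.
#'
#' @param dets A [detection_set()].
#' @param path File path.
#' @return `path` (write) or a [detection_set()] (read).
#' @export
write_detections_csv <- function(dets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header("detections"), con)
  writeLines(sprintf("# fs=%s", format(attr(dets, "fs") %||% NA)), con)
  utils::write.csv(as.data.frame(dets), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 2L)
  if (!identical(hdr[1], csv_header("detections"))) {
    stop("unrecognized detections file version: ", hdr[1])
  }
  fs <- suppressWarnings(as.numeric(sub("# fs=", "", hdr[2])))
  df <- utils::read.csv(path, skip = 2L, stringsAsFactors = FALSE)
  detection_set(df$time, df$amplitude, df$instrument_id, fs,
                label = df$label)
}

#' Read and write DOA series as CSV
#'
#' Columns: `array_id, time, sx, sy, sz, az, el, label, residual`.
#'
#' @param series A `"doa_series"` data frame
#'   ([doa_series_from_waveform()]).
#' @param path File path.
#' @return `path` (write) or the series (read).
#' @export
write_doa_csv <- function(series, path) {
  write_versioned_csv(as.data.frame(series), path, "doa")
}

#' @rdname write_doa_csv
#' @export
read_doa_csv <- function(path) {
  df <- read_versioned_csv(path, "doa")
  structure(df, class = c("doa_series", "data.frame"))
}

#' Write a track estimate as CSV
#'
#' One row per localized detection: `label, time, x, y, z, ci lower/upper
#' per axis, combination, interpolated, seed`.
#'
#' @param track Data frame with those columns (see
#'   [localize_encounter()]).
#' @param path File path.
#' @return `path` (write) or the track data frame (read).
#' @export
write_track_csv <- function(track, path) {
  write_versioned_csv(as.data.frame(track), path, "track")
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  read_versioned_csv(path, "track")
}

#' Localize a labelled encounter
#'
#' Batch localization driver: for each labelled detection on the reference
#' array, assembles the available TDOA measurements into a [tdoa_bundle()]
#' and runs either the Monte-Carlo bootstrap path
#' ([monte_carlo_localize()] + [bootstrap_location()]) or the two-DOA
#' jackknife path ([jackknife_two_doa()]).
#'
#' @param bundles Named or unnamed list of per-detection entries: each a
#'   list with `time`, `label`, and either a [tdoa_bundle()] (`bundle`) for
#'   the Monte-Carlo path or `small_1`/`small_2` length-6 TDOA vectors for
#'   the two-DOA path.
#' @param geometry A [deployment_geometry()].
#' @param method `"montecarlo"` or `"doaintersect"`.
#' @param n_perturb,n_boot Monte-Carlo / bootstrap sizes.
#' @param seed RNG seed (recorded per row).
#' @param array_ids The two 4-channel ids for the two-DOA path.
#' @param range_grid Range grid for the DOA+TDOA path.
#' @return A track data frame: `label, time, x, y, z, ci_*, combination,
#'   interpolated, seed`, time-ordered, of class `"track_estimate"`.
#' @export
localize_encounter <- function(bundles, geometry, method = c("montecarlo",
                                                             "doaintersect"),
                               n_perturb = 50, n_boot = 50, seed = 1L,
                               array_ids = NULL, range_grid = NULL) {
  method <- match.arg(method)
  rows <- vector("list", length(bundles))
  for (k in seq_along(bundles)) {
    b <- bundles[[k]]
    est <- tryCatch({
      if (method == "montecarlo") {
        samples <- monte_carlo_localize(b$bundle, geometry,
                                        n_perturb = n_perturb,
                                        range_grid = range_grid,
                                        seed = seed + k)
        if (nrow(samples) < 2L) NULL else
          bootstrap_location(samples, n_boot = n_boot, seed = seed + k)
      } else {
        jackknife_two_doa(b$small_1, b$small_2, geometry,
                          array_ids = array_ids)
      }
    }, error = function(e) NULL)
    if (is.null(est)) next
    rows[[k]] <- data.frame(
      label = b$label %||% NA_character_, time = b$time,
      x = est$position[1], y = est$position[2], z = est$position[3],
      ci_x_lo = est$ci_lower[1], ci_x_hi = est$ci_upper[1],
      ci_y_lo = est$ci_lower[2], ci_y_hi = est$ci_upper[2],
      ci_z_lo = est$ci_lower[3], ci_z_hi = est$ci_upper[3],
      combination = paste(est$combinations, collapse = "|"),
      interpolated = isTRUE(b$interpolated), seed = seed,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), time = numeric(0), x = numeric(0),
               y = numeric(0), z = numeric(0))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("track_estimate", "data.frame"))
}
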