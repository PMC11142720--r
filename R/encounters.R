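#' Group detections into encounters
#'
#' An encounter is a contiguous period of detections separated from its
#' neighbours by at least `gap_s` of silence (default 30 minutes), pooled
#' over the given detection sets.
#'
#' @param det_sets List of [detection_set()]s (one per instrument).
#' @param gap_s Silence gap starting a new encounter (s).
#' @return A list of `"encounter"` objects: each a list with `id`,
#'   `t_start`, `t_end`, `instruments`, `detections` (the pooled rows),
#'   `labels`.
#' @export
group_encounters <- function(det_sets, gap_s = 1800) {
  all <- do.call(rbind, lapply(det_sets, as.data.frame))
  if (is.null(all) || nrow(all) == 0L) return(list())
  all <- all[order(all$time), , drop = FALSE]
  brk <- c(0, cumsum(diff(all$time) >= gap_s))
  lapply(unique(brk), function(g) {
    d <- all[brk == g, , drop = FALSE]
    labs <- unique(d$label[!is.na(d$label) & d$label != "false"])
    structure(list(id = paste0("enc", g + 1), t_start = min(d$time),
                   t_end = max(d$time),
                   instruments = unique(d$instrument_id),
                   detections = d, labels = labs),
              class = "encounter")
  })
}

#' Filter encounters for localization usability
#'
#' An encounter is usable when it lasts at least `min_duration` *and* at
#' least one source label carries at least `min_clicks` detections (counted
#' after label cleaning, per label; short encounters and sparsely clicking
#' individuals cannot be localized reliably).
#'
#' @param encounters List of encounters from [group_encounters()].
#' @param min_duration Minimum duration (s), default 300 (5 minutes).
#' @param min_clicks Minimum labelled clicks per label, default 300.
#' @return The usable encounters, each with `usable = TRUE` and a
#'   `usable_labels` field listing the labels meeting the click rule.
#' @export
filter_encounters <- function(encounters, min_duration = 300,
                              min_clicks = 300) {
  keep <- list()
  for (e in encounters) {
    dur <- e$t_end - e$t_start
    lab <- e$detections$label
    lab <- lab[!is.na(lab) & lab != "false"]
    counts <- table(lab)
    good_labs <- names(counts)[counts >= min_clicks]
    if (dur >= min_duration && length(good_labs) > 0L) {
      e$usable <- TRUE
      e$usable_labels <- good_labs
      keep[[length(keep) + 1L]] <- e
    }
  }
  keep
}

#' Programmatic label editing
#'
#' Deterministic replacement for interactive brushing of DOA plots: applies
#' an edit script to a DOA series (or labelled detection table) in order,
#' keeping a full audit log. Supported operations (one row each):
#' \describe{
#'   \item{`label_time`}{assign `label` to rows with `t_min <= time < t_max`}
#'   \item{`remove_time`}{mark rows in the time range as `"false"`}
#'   \item{`label_rows` / `remove_rows`}{by row id (comma-separated `rows`)}
#'   \item{`label_polygon` / `remove_polygon`}{rows whose (az, el) falls
#'     inside the polygon given by comma-separated `az` / `el` vertex lists
#'     (e.g. to strip a high-elevation dolphin cluster)}
#' }
#'
#' @param series A data frame with at least `time` and `label` columns;
#'   polygon operations also need `az` and `el`.
#' @param script Data frame with columns `op`, `label`, `t_min`, `t_max`,
#'   `rows`, `az`, `el` (unused fields may be `NA`).
#' @return The edited series, with attribute `audit` (one row per operation:
#'   op, rows affected).
#' @export
edit_labels <- function(series, script) {
  if (is.null(script) || nrow(script) == 0L) {
    attr(series, "audit") <- data.frame(op = character(0),
                                        n_affected = integer(0))
    return(series)
  }
  audit <- vector("list", nrow(script))
  for (k in seq_len(nrow(script))) {
    op <- script$op[k]
    idx <- switch(
      op,
      label_time = ,
      remove_time = which(series$time >= script$t_min[k] &
                            series$time < script$t_max[k]),
      label_rows = ,
      remove_rows = {
        rows <- as.integer(strsplit(as.character(script$rows[k]),
                                    ",")[[1]])
        bad <- rows[rows < 1L | rows > nrow(series)]
        if (length(bad)) {
          stop("edit script references missing rows: ",
               paste(bad, collapse = ", "))
        }
        rows
      },
      label_polygon = ,
      remove_polygon = {
        px <- as.numeric(strsplit(as.character(script$az[k]), ",")[[1]])
        py <- as.numeric(strsplit(as.character(script$el[k]), ",")[[1]])
        which(pracma::inpolygon(series$az, series$el, px, py))
      },
      stop("unknown edit operation: ", op)
    )
    new_label <- if (startsWith(op, "remove")) "false" else
      as.character(script$label[k])
    series$label[idx] <- new_label
    audit[[k]] <- data.frame(op = op, n_affected = length(idx))
  }
  attr(series, "audit") <- do.call(rbind, audit)
  series
}
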