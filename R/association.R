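#' Build a binary click train from a detection set
#'
#' Rasterizes detection times onto a uniform grid: the train has value 1 in
#' every grid cell that contains a (label-filtered) detection and 0 elsewhere.
#' Cell assignment uses the floor convention, so a detection exactly on a cell
#' boundary belongs to the cell starting there. The temporal pattern of this
#' train is the fingerprint used to associate detections across instruments.
#'
#' @param dets A [detection_set()].
#' @param window_start Window start time (s).
#' @param window_len Window length (s).
#' @param label_filter `NULL` (all detections regardless of label), or a label
#'   string: only detections with that label are included. Detections labelled
#'   `"false"` are always excluded.
#' @param resolution Grid cell width (s), at most 1 ms.
#' @return An object of class `"click_train"`: list with `values`, `t0`,
#'   `dt`, `label`, `smoothed`.
#' @export
build_click_train <- function(dets, window_start, window_len,
                              label_filter = NULL, resolution = 1e-3) {
  if (resolution > 1e-3 + 1e-12) {
    stop("click-train grid resolution must be <= 1 ms")
  }
  n <- max(1L, ceiling(window_len / resolution))
  v <- numeric(n)
  t <- dets$time
  lab <- dets$label
  keep <- t >= window_start & t < window_start + window_len
  keep <- keep & (is.na(lab) | lab != "false")
  if (!is.null(label_filter)) {
    keep <- keep & !is.na(lab) & lab == label_filter
  }
  cells <- floor((t[keep] - window_start) / resolution) + 1L
  cells <- cells[cells >= 1L & cells <= n]
  v[unique(cells)] <- 1
  structure(list(values = v, t0 = window_start, dt = resolution,
                 label = if (is.null(label_filter)) "all" else label_filter,
                 smoothed = FALSE),
            class = "click_train")
}

#' Smooth a click train with a Hann window
#'
#' Convolves the binary train with a Hann window of the given width, so each
#' detection impulse becomes a smooth bump. This tolerates small arrival-time
#' differences and inter-click-interval changes from a moving source when two
#' trains are cross-correlated. The window is normalized to unit peak, so an
#' isolated detection keeps amplitude 1; total mass is the window sum per
#' impulse.
#'
#' @param train A [build_click_train()] result.
#' @param hann_ms Full width of the Hann window in milliseconds (default 20).
#' @return A smoothed `"click_train"`.
#' @export
smooth_click_train <- function(train, hann_ms = 20) {
  stopifnot(inherits(train, "click_train"))
  ncells <- round(hann_ms * 1e-3 / train$dt)
  if (ncells < 2L) stop("Hann width must span at least 2 grid cells")
  if (ncells %% 2L == 0L) ncells <- ncells + 1L  # symmetric, odd length
  w <- signal::hanning(ncells)
  half <- (ncells - 1L) %/% 2L
  v <- stats::convolve(train$values, rev(w), type = "open")
  train$values <- v[(half + 1L):(half + length(train$values))]
  train$smoothed <- TRUE
  train$hann_ms <- hann_ms
  train
}

#' Click-train correlation between two instruments
#'
#' Cross-correlates a labelled (smoothed) click train with an unlabeled one
#' and returns the lag of the global correlation maximum as the coarse
#' large-aperture delay `tau` of the unlabeled instrument relative to the
#' labelled one (positive: the source's clicks arrive later at the unlabeled
#' instrument). The match is accepted only when the correlation peak is
#' unambiguous: among local maxima separated by at least one Hann width, the
#' second-highest must be below `ratio_threshold` times the highest,
#' otherwise too few shared clicks (or a periodic pattern) make the alignment
#' ambiguous and no labels may be propagated from this window.
#'
#' @param train_labeled,train_unlabeled Smoothed [smooth_click_train()]s on
#'   the same grid resolution.
#' @param max_lag Maximum |tau| searched (s); must cover the physical
#'   inter-instrument TDOA range plus clock-drift allowance.
#' @param ratio_threshold Acceptance threshold on second-highest/highest peak
#'   (default 0.8).
#' @return An object of class `"ctc_result"`: list with `tau` (s, `NA` when
#'   undefined), `peak`, `peak_ratio`, `accepted`.
#' @export
ctc_tdoa <- function(train_labeled, train_unlabeled, max_lag,
                     ratio_threshold = 0.8) {
  stopifnot(inherits(train_labeled, "click_train"),
            inherits(train_unlabeled, "click_train"))
  if (abs(train_labeled$dt - train_unlabeled$dt) > 1e-12) {
    stop("click trains must share a grid resolution")
  }
  dt <- train_labeled$dt
  a <- train_labeled$values
  b <- train_unlabeled$values
  if (all(a == 0) || all(b == 0)) {
    return(structure(list(tau = NA_real_, peak = 0, peak_ratio = NA_real_,
                          accepted = FALSE),
                     class = "ctc_result"))
  }
  offset <- train_unlabeled$t0 - train_labeled$t0
  # lag grid in cells; lag L means b delayed by L cells relative to a
  L <- stats::nextn(length(a) + length(b), 2)
  A <- stats::fft(c(a, rep(0, L - length(a))))
  B <- stats::fft(c(b, rep(0, L - length(b))))
  r <- Re(stats::fft(B * Conj(A), inverse = TRUE)) / L
  max_cells <- min(L %/% 2L - 1L, ceiling((max_lag + abs(offset)) / dt))
  lags <- c(0:max_cells, -(max_cells:1))
  rw <- r[c(1:(max_cells + 1L), (L - max_cells + 1L):L)]
  tau_all <- lags * dt + offset
  inside <- abs(tau_all) <= max_lag + dt / 2
  if (!any(inside)) {
    return(structure(list(tau = NA_real_, peak = 0, peak_ratio = NA_real_,
                          accepted = FALSE),
                     class = "ctc_result"))
  }
  ord <- order(tau_all[inside])
  tau_grid <- tau_all[inside][ord]
  rr <- rw[inside][ord]
  best <- which.max(rr)
  tau <- tau_grid[best]
  peak <- rr[best]
  # local maxima, then greedy separation by >= one Hann width
  m <- length(rr)
  sep_cells <- max(1L, round((train_labeled$hann_ms %||% 20) * 1e-3 / dt))
  is_max <- rep(FALSE, m)
  if (m >= 3L) {
    core <- rr[2:(m - 1L)]
    is_max[2:(m - 1L)] <- core >= rr[1:(m - 2L)] & core > rr[3:m] & core > 0
  }
  is_max[best] <- TRUE
  cand <- which(is_max)
  cand <- cand[order(rr[cand], decreasing = TRUE)]
  selected <- integer(0)
  for (i in cand) {
    if (length(selected) == 0L || min(abs(selected - i)) >= sep_cells) {
      selected <- c(selected, i)
    }
  }
  ratio <- if (length(selected) >= 2L) rr[selected[2L]] / rr[selected[1L]]
           else 0
  structure(list(tau = tau, peak = peak, peak_ratio = ratio,
                 accepted = is.finite(ratio) && ratio < ratio_threshold),
            class = "ctc_result")
}

#' Propagate source labels across instruments after CTC
#'
#' Given an accepted click-train-correlation delay `tau`, every unlabeled
#' detection that falls within `tol` of a labelled detection time + `tau` is
#' assumed to originate from the same source and receives that label; ties go
#' to the nearest labelled click. Other detections are untouched.
#'
#' @param unlabeled A [detection_set()] to receive labels.
#' @param labeled A [detection_set()] whose `label` column carries source ids.
#' @param tau Delay (s) of the unlabeled instrument relative to the labelled
#'   one, from [ctc_tdoa()].
#' @param tol Matching tolerance (s), default 10 ms (half the default Hann
#'   width).
#' @return The unlabeled [detection_set()] with labels filled in where
#'   matched.
#' @export
propagate_labels <- function(unlabeled, labeled, tau, tol = 10e-3) {
  lab_rows <- !is.na(labeled$label) & labeled$label != "false"
  lt <- labeled$time[lab_rows] + tau
  ll <- labeled$label[lab_rows]
  if (length(lt) == 0L || nrow(unlabeled) == 0L) return(unlabeled)
  o <- order(lt)
  lt <- lt[o]
  ll <- ll[o]
  for (k in seq_len(nrow(unlabeled))) {
    i <- findInterval(unlabeled$time[k], lt)
    cand <- unique(pmax(1L, pmin(length(lt), c(i, i + 1L))))
    dists <- abs(lt[cand] - unlabeled$time[k])
    j <- cand[which.min(dists)]
    if (min(dists) <= tol) unlabeled$label[k] <- ll[j]
  }
  unlabeled
}

#' Sliding-window click-train correlation
#'
#' Steps a CTC window forward detection-by-detection through the labelled
#' detection set. In each window, every source label present is correlated
#' against the unlabeled instrument's train; accepted windows cast label
#' votes on the unlabeled detections they align with. Conflicts across
#' overlapping windows are resolved by majority vote (ties left unlabeled).
#'
#' @param labeled_set A labelled [detection_set()] (e.g. one 4-channel array).
#' @param unlabeled_set The [detection_set()] to label.
#' @param max_lag Physical TDOA bound between the two instruments (s).
#' @param window_len CTC window length (s), default 30.
#' @param step Advance in labelled detections per window (default 1).
#' @param hann_ms Hann smoothing width (ms).
#' @param ratio_threshold Peak-ratio acceptance threshold.
#' @param tol Label-propagation tolerance (s).
#' @param resolution Click-train grid (s).
#' @return A list: `detections` (the unlabeled set with labels), `windows`
#'   (data frame of per-window, per-label CTC results: `t0, label, tau,
#'   peak_ratio, accepted`).
#' @export
sliding_ctc <- function(labeled_set, unlabeled_set, max_lag,
                        window_len = 30, step = 1L, hann_ms = 20,
                        ratio_threshold = 0.8, tol = 10e-3,
                        resolution = 1e-3) {
  labs <- unique(labeled_set$label)
  labs <- labs[!is.na(labs) & labs != "false"]
  nu <- nrow(unlabeled_set)
  votes <- list()
  rows <- list()
  lab_times <- labeled_set$time
  starts <- lab_times[seq(1L, length(lab_times), by = max(1L, step))]
  starts <- starts[!duplicated(round(starts / resolution))]
  for (t0 in starts) {
    in_l <- labeled_set$time >= t0 & labeled_set$time < t0 + window_len
    win_l <- labeled_set[in_l, , drop = FALSE]
    tu <- build_click_train(unlabeled_set, t0 - max_lag,
                            window_len + 2 * max_lag,
                            resolution = resolution)
    tu <- smooth_click_train(tu, hann_ms)
    for (w in labs) {
      if (!any(!is.na(win_l$label) & win_l$label == w)) next
      tl <- build_click_train(win_l, t0, window_len, label_filter = w,
                              resolution = resolution)
      tl <- smooth_click_train(tl, hann_ms)
      res <- ctc_tdoa(tl, tu, max_lag, ratio_threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(t0 = t0, label = w,
                   tau = if (is.null(res$tau)) NA_real_ else res$tau,
                   peak_ratio = res$peak_ratio, accepted = res$accepted)
      if (!res$accepted || !is.finite(res$tau)) next
      lw <- win_l[!is.na(win_l$label) & win_l$label == w, , drop = FALSE]
      shifted <- lw$time + res$tau
      for (k in seq_len(nu)) {
        if (nu == 0L) break
        tk <- unlabeled_set$time[k]
        if (tk < t0 - max_lag || tk > t0 + window_len + max_lag) next
        if (length(shifted) && min(abs(shifted - tk)) <= tol) {
          votes[[length(votes) + 1L]] <- c(k, w)
        }
      }
    }
  }
  out <- unlabeled_set
  if (length(votes)) {
    vdf <- as.data.frame(do.call(rbind, votes), stringsAsFactors = FALSE)
    names(vdf) <- c("row", "label")
    vdf$row <- as.integer(vdf$row)
    for (k in unique(vdf$row)) {
      tab <- table(vdf$label[vdf$row == k])
      top <- tab[tab == max(tab)]
      if (length(top) == 1L) out$label[k] <- names(top)
    }
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t0 = numeric(0), label = character(0), tau = numeric(0),
               peak_ratio = numeric(0), accepted = logical(0))
  list(detections = out, windows = windows)
}

#' Fine-scale large-aperture TDOA by waveform cross-correlation
#'
#' Refines a coarse click-train delay into a precise large-aperture TDOA by
#' cross-correlating the acoustic waveforms themselves. The two snippets are
#' expected to be extracted around the predicted arrival times (the labelled
#' detection time and that time + `coarse_tau`). When the sampling rates
#' differ, the higher-rate snippet is resampled (polyphase) to the lower
#' rate first. The residual delay is estimated with sub-sample interpolation
#' within `+/- search_halfwidth`.
#'
#' @param wave_i Snippet from the labelled instrument.
#' @param fs_i Its sampling rate (Hz).
#' @param wave_j Snippet from the other instrument (extracted `coarse_tau`
#'   later).
#' @param fs_j Its sampling rate (Hz).
#' @param coarse_tau Coarse delay of instrument j relative to instrument i
#'   (s), from [ctc_tdoa()].
#' @param search_halfwidth Residual search half-width (s).
#' @param min_peak Minimum normalized peak correlation for a reliable result.
#' @return A list: `tau` (refined delay of j relative to i, s), `delay_resid`
#'   (s), `peak_norm` (normalized peak correlation), `at_boundary`,
#'   `reliable`, `fs` (common rate used).
#' @export
fine_tdoa <- function(wave_i, fs_i, wave_j, fs_j, coarse_tau,
                      search_halfwidth, min_peak = 0.3) {
  if (fs_i != fs_j) {
    if (fs_i > fs_j) {
      wave_i <- fft_resample(wave_i, fs_i, fs_j)
      fs_i <- fs_j
    } else {
      wave_j <- fft_resample(wave_j, fs_j, fs_i)
      fs_j <- fs_i
    }
  }
  fs <- fs_i
  max_lag <- max(1, ceiling(search_halfwidth * fs))
  cc <- cross_correlation_delay(wave_i, wave_j, max_lag = max_lag)
  e_i <- sum(wave_i^2)
  e_j <- sum(wave_j^2)
  peak_norm <- if (e_i > 0 && e_j > 0) cc$peak / sqrt(e_i * e_j) else 0
  reliable <- !cc$at_boundary && peak_norm >= min_peak
  list(tau = coarse_tau + cc$delay / fs, delay_resid = cc$delay / fs,
       peak_norm = peak_norm, at_boundary = cc$at_boundary,
       reliable = reliable, fs = fs)
}

# Exact band-limited (FFT-domain) resampling for short snippets: zero group
# delay, implicit brick-wall anti-aliasing at the lower Nyquist. Time-domain
# polyphase resamplers carry an uncompensated FIR delay that would bias the
# sub-sample TDOAs measured from the resampled snippets.
fft_resample <- function(x, fs_in, fs_out) {
  # trim so the output length is exact: otherwise the implied output rate
  # differs slightly from fs_out and the time grid is stretched
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  q <- fs_in / g(round(fs_in), round(fs_out))
  n <- floor(length(x) / q) * q
  x <- x[seq_len(n)]
  m <- round(n * fs_out / fs_in)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m) %/% 2L
  Y[1:(keep + 1L)] <- X[1:(keep + 1L)]
  if (keep >= 1L) Y[(m - keep + 1L):m] <- X[(n - keep + 1L):n]
  if (min(n, m) %% 2L == 0L && keep >= 1L) {
    # shared Nyquist bin: split to keep the result real
    Y[keep + 1L] <- Y[keep + 1L] / 2
    Y[m - keep + 1L] <- Y[m - keep + 1L] + Conj(X[keep + 1L]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
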