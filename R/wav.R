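#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for the formats produced by autonomous acoustic
#' recorders and by [write_wav()]: PCM 16-bit, PCM 24-bit and IEEE float32,
#' any channel count. Samples are returned as doubles scaled to roughly
#' `[-1, 1]` (PCM divided by full scale).
#'
#' @param path Path to the WAV file.
#' @return A list with `data` (n x channels numeric matrix), `fs` (Hz),
#'   `bits`, and `format` ("pcm" or "float").
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      buf <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(buf[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(buf[3:4], "integer", 1L, 2L,
                             signed = FALSE, endian = "little"),
        fs = readBin(buf[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(buf[15:16], "integer", 1L, 2L,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: ", path)
  nch <- fmt$n_channels
  if (fmt$audio_format == 3L || (fmt$audio_format == 65534L && fmt$bits == 32L)) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                 endian = "little")
    format <- "float"
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little") / 32768
    format <- "pcm"
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    x <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    x <- ifelse(x >= 8388608, x - 16777216, x) / 8388608
    format <- "pcm"
  } else {
    stop("unsupported WAV sample format: ", fmt$bits, "-bit, code ",
         fmt$audio_format)
  }
  data <- matrix(x, ncol = nch, byrow = TRUE)
  list(data = data, fs = fmt$fs, bits = fmt$bits, format = format)
}

#' Write a WAV file
#'
#' @param data Numeric vector (mono) or n x channels matrix of samples in
#'   `[-1, 1]`.
#' @param fs Sampling rate (Hz).
#' @param path Output path.
#' @param bits 16 or 24 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(data, fs, path, bits = 16L) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  nch <- ncol(data)
  n <- nrow(data)
  interleaved <- as.numeric(t(data))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 24L, 32L)) stop("bits must be 16, 24 or 32")
  bytes_per <- bits %/% 8L
  data_size <- n * nch * bytes_per
  fmt_code <- if (bits == 32L) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(nch, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * nch * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 32L) {
    writeBin(interleaved, con, size = 4L, endian = "little")
  } else if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(interleaved * 32768))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    q <- pmax(-8388608, pmin(8388607, round(interleaved * 8388608)))
    q <- ifelse(q < 0, q + 16777216, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  }
  invisible(path)
}
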