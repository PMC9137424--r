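#' Construct a waveform
#'
#' A light container for a mono audio signal: samples in full-scale units
#' (nominally within \[-1, 1\]), a sample rate in Hz, and optional labelled
#' spans (e.g. the speech portion or the consonant region) given in sample
#' indices.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sample rate in Hz (positive scalar).
#' @param spans Optional data frame with columns `label`, `start`, `end`
#'   (1-based sample indices, inclusive, within the signal).
#' @return An object of class `masksim_wave`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' wave_duration(w)
waveform <- function(samples, rate, spans = NULL) {
  if (!is.numeric(samples) || length(samples) == 0) {
    abort("`samples` must be a non-empty numeric vector.")
  }
  if (!all(is.finite(samples))) abort("`samples` must be finite.")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a positive scalar (Hz).")
  }
  if (is.null(spans)) {
    spans <- tibble(label = character(), start = integer(), end = integer())
  } else {
    spans <- as_tibble(spans)
    stopifnot(all(c("label", "start", "end") %in% names(spans)))
    if (nrow(spans) > 0 &&
        (any(spans$start < 1) || any(spans$end > length(samples)) ||
         any(spans$start > spans$end))) {
      abort("Annotation spans must lie within [1, length(samples)] with start <= end.")
    }
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate), spans = spans),
    class = "masksim_wave"
  )
}

#' @export
print.masksim_wave <- function(x, ...) {
  cat(sprintf(
    "<masksim_wave> %d samples @ %g Hz (%.3f s), %d span(s)\n",
    length(x$samples), x$rate, length(x$samples) / x$rate, nrow(x$spans)
  ))
  if (nrow(x$spans) > 0) {
    for (i in seq_len(nrow(x$spans))) {
      cat(sprintf("  %s: [%d, %d]\n", x$spans$label[i], x$spans$start[i], x$spans$end[i]))
    }
  }
  invisible(x)
}

#' @rdname waveform
#' @param x A `masksim_wave`.
#' @export
wave_duration <- function(x) {
  stopifnot(inherits(x, "masksim_wave"))
  length(x$samples) / x$rate
}

#' Extract the samples of a labelled span
#'
#' @param x A `masksim_wave`.
#' @param label Span label to extract; `NULL` returns all samples.
#' @return Numeric vector of samples.
#' @export
wave_span <- function(x, label = NULL) {
  stopifnot(inherits(x, "masksim_wave"))
  if (is.null(label)) return(x$samples)
  row <- x$spans[x$spans$label == label, ]
  if (nrow(row) == 0) {
    abort(sprintf("Waveform has no span labelled '%s'.", label))
  }
  unlist(lapply(seq_len(nrow(row)), function(i) {
    x$samples[row$start[i]:row$end[i]]
  }))
}

#' Root-mean-square level of a waveform
#'
#' @param x A `masksim_wave` or numeric vector.
#' @param label Optional span label; RMS is computed over that span only.
#' @param db If `TRUE`, return the level in dB re full scale
#'   (`20 * log10(rms)`).
#' @return RMS in linear full-scale units, or dBFS if `db = TRUE`.
#' @export
wave_rms <- function(x, label = NULL, db = FALSE) {
  s <- if (inherits(x, "masksim_wave")) wave_span(x, label) else as.numeric(x)
  r <- sqrt(mean(s^2))
  if (db) 20 * log10(r) else r
}

#' Scale a waveform by a linear gain
#'
#' @param x A `masksim_wave`.
#' @param gain Linear gain factor.
#' @return The scaled waveform; annotations are preserved.
#' @export
wave_scale <- function(x, gain) {
  stopifnot(inherits(x, "masksim_wave"), is.finite(gain))
  x$samples <- x$samples * gain
  x
}

db_to_gain <- function(db) 10^(db / 20)
gain_to_db <- function(g) 20 * log10(g)

#' Read a mono WAV file
#'
#' Supports uncompressed PCM16 and IEEE float32 WAV files. Multichannel
#' files are mixed down by taking the first channel.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(sprintf("Not a RIFF/WAV file: %s", path))
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(sprintf("Not a WAVE file: %s", path))
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = sum(as.integer(fmt_raw[1:2]) * c(1L, 256L)),
        channels = sum(as.integer(fmt_raw[3:4]) * c(1L, 256L)),
        rate     = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits     = sum(as.integer(fmt_raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort(sprintf("Malformed WAV file: %s", path))
  if (fmt$format == 1 && fmt$bits == 16) {
    vals <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                    signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3 && fmt$bits == 32) {
    vals <- readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    abort(sprintf("Unsupported WAV encoding (format %d, %d bit); use PCM16 or float32.",
                  fmt$format, fmt$bits))
  }
  if (fmt$channels > 1) {
    vals <- vals[seq(1, length(vals), by = fmt$channels)]
  }
  waveform(vals, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param x A [waveform()].
#' @param path Output path.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(x, "masksim_wave"))
  format <- match.arg(format)
  n <- length(x$samples)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(x$rate), con, 4, endian = "little")
  writeBin(as.integer(x$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "pcm16") {
    v <- pmin(pmax(round(x$samples * 32768), -32768), 32767)
    writeBin(as.integer(v), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x$samples), con, 4, endian = "little")
  }
  invisible(path)
}
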