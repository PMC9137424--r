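#' Spectral estimation settings
#'
#' Defaults follow the common Welch configuration for long-term speech
#' spectra: 512-point Hamming-windowed segments with a 256-point overlap.
#'
#' @param segment Segment length in samples.
#' @param overlap Overlap between consecutive segments in samples.
#' @param window Window name; only `"hamming"` and `"hann"` are supported.
#' @return A list of class `masksim_spectral_params`.
#' @export
spectral_params <- function(segment = 512, overlap = 256, window = "hamming") {
  stopifnot(segment >= 16, segment %% 2 == 0, overlap >= 0, overlap < segment)
  window <- match.arg(window, c("hamming", "hann"))
  structure(list(segment = as.integer(segment), overlap = as.integer(overlap),
                 window = window),
            class = "masksim_spectral_params")
}

window_vector <- function(params) {
  switch(params$window,
    hamming = signal::hamming(params$segment),
    hann = signal::hanning(params$segment)
  )
}

#' Long-term magnitude spectrum by Welch's averaged periodogram
#'
#' Splits the signal into overlapping windowed segments, averages the
#' one-sided periodograms, and reports the result in dB
#' (`10 * log10` of the averaged power estimate).
#'
#' @param signal A [waveform()].
#' @param params A [spectral_params()].
#' @return A `masksim_spectrum`: list with `frequencies` (Hz, from 0 to
#'   Nyquist), `magnitude_db`, `params` and `rate`.
#' @export
#' @examples
#' w <- waveform(stats::rnorm(44100), 44100)
#' sp <- estimate_magnitude_spectrum(w)
#' length(sp$frequencies)  # 257 bins for the 512-point default
estimate_magnitude_spectrum <- function(signal, params = spectral_params()) {
  stopifnot(inherits(signal, "masksim_wave"))
  n <- length(signal$samples)
  nseg <- params$segment
  if (n < 2 * nseg) {
    abort(sprintf(
      "Signal too short for spectral estimation: %d samples, need at least %d (2 x segment).",
      n, 2 * nseg))
  }
  w <- window_vector(params)
  hop <- nseg - params$overlap
  nfr <- floor((n - nseg) / hop) + 1
  # windowed segment matrix; mvfft runs one FFT per column
  idx <- outer(seq_len(nseg), (seq_len(nfr) - 1L) * hop, `+`)
  M <- matrix(signal$samples[idx], nrow = nseg) * w
  P <- rowMeans(Mod(stats::mvfft(M))^2)[1:(nseg / 2 + 1)]
  structure(
    list(
      frequencies = (0:(nseg / 2)) * signal$rate / nseg,
      magnitude_db = 10 * log10(pmax(P, .Machine$double.xmin)),
      params = params,
      rate = signal$rate
    ),
    class = "masksim_spectrum"
  )
}

#' @export
print.masksim_spectrum <- function(x, ...) {
  cat(sprintf("<masksim_spectrum> %d bins, 0-%g Hz (segment %d, overlap %d, %s)\n",
              length(x$frequencies), max(x$frequencies),
              x$params$segment, x$params$overlap, x$params$window))
  invisible(x)
}

#' Mask attenuation function from paired spectra
#'
#' Attenuation is the dB difference of the reference (no-mask) spectrum
#' relative to the masked spectrum, so positive values mean loss. Values
#' are clamped to `clamp_db` to suppress bins dominated by measurement
#' noise before filter synthesis.
#'
#' @param masked `masksim_spectrum` of the masked recording.
#' @param reference `masksim_spectrum` of the unmasked recording.
#' @param clamp_db Symmetric clamp bound in dB (default 30).
#' @param label Mask label stored as provenance.
#' @return A `masksim_attenuation`: list with `frequencies`,
#'   `attenuation_db`, `rate`, `label`.
#' @export
attenuation_function <- function(masked, reference, clamp_db = 30, label = "mask") {
  stopifnot(inherits(masked, "masksim_spectrum"),
            inherits(reference, "masksim_spectrum"))
  if (length(masked$frequencies) != length(reference$frequencies) ||
      any(abs(masked$frequencies - reference$frequencies) > 1e-9)) {
    abort(sprintf(
      "Frequency grids differ: masked has %d bins to %g Hz, reference %d bins to %g Hz.",
      length(masked$frequencies), max(masked$frequencies),
      length(reference$frequencies), max(reference$frequencies)))
  }
  att <- reference$magnitude_db - masked$magnitude_db
  new_attenuation(masked$frequencies,
                  pmax(-clamp_db, pmin(clamp_db, att)),
                  masked$rate, label)
}

new_attenuation <- function(frequencies, attenuation_db, rate, label = "mask") {
  stopifnot(length(frequencies) == length(attenuation_db),
            all(diff(frequencies) > 0), frequencies[1] == 0)
  structure(
    list(frequencies = as.numeric(frequencies),
         attenuation_db = as.numeric(attenuation_db),
         rate = as.numeric(rate), label = label),
    class = "masksim_attenuation"
  )
}

#' @export
print.masksim_attenuation <- function(x, ...) {
  cat(sprintf("<masksim_attenuation> '%s': %d bins to %g Hz, mean 2-16 kHz %.2f dB\n",
              x$label, length(x$frequencies), max(x$frequencies),
              tryCatch(band_mean_attenuation(x, 2000, 16000), error = function(e) NA)))
  invisible(x)
}

#' Convert an attenuation function to a tibble
#'
#' @param x A `masksim_attenuation`.
#' @param ... Unused.
#' @return A tibble with columns `hz`, `db`, `label`.
#' @export
tidy.masksim_attenuation <- function(x, ...) {
  tibble(hz = x$frequencies, db = x$attenuation_db, label = x$label)
}

#' Mean attenuation over a frequency band
#'
#' Unweighted mean of the attenuation values at all bins whose frequency
#' lies in `[f_lo, f_hi]` (inclusive edges).
#'
#' @param att A `masksim_attenuation`.
#' @param f_lo,f_hi Band edges in Hz.
#' @return Mean attenuation in dB.
#' @export
band_mean_attenuation <- function(att, f_lo = 2000, f_hi = 16000) {
  stopifnot(inherits(att, "masksim_attenuation"))
  if (!(f_lo < f_hi)) abort("`f_lo` must be below `f_hi`.")
  if (f_hi > max(att$frequencies) + 1e-9) {
    abort(sprintf("Band edge %g Hz exceeds the Nyquist grid (%g Hz).",
                  f_hi, max(att$frequencies)))
  }
  sel <- att$frequencies >= f_lo & att$frequencies <= f_hi
  if (!any(sel)) abort(sprintf("No spectral bins in band [%g, %g] Hz.", f_lo, f_hi))
  mean(att$attenuation_db[sel])
}

#' Standard one-third-octave bands
#'
#' Nominal band centers with exact edges at `center * 2^(+-1/6)`.
#'
#' @param f_min,f_max Limits on the returned nominal centers, Hz.
#' @return A tibble with `center`, `lower`, `upper` in Hz.
#' @export
third_octave_bands <- function(f_min = 100, f_max = 16000) {
  nominal <- c(25, 31.5, 40, 50, 63, 80, 100, 125, 160, 200, 250, 315, 400,
               500, 630, 800, 1000, 1250, 1600, 2000, 2500, 3150, 4000, 5000,
               6300, 8000, 10000, 12500, 16000, 20000)
  centers <- nominal[nominal >= f_min & nominal <= f_max]
  tibble(center = centers,
         lower = centers * 2^(-1 / 6),
         upper = centers * 2^(1 / 6))
}

#' Peak one-third-octave band attenuation
#'
#' Computes the mean attenuation in each standard one-third-octave band and
#' returns the maximum together with the nominal center of the band where it
#' occurs. Ties are broken toward the lowest center. Bands whose upper edge
#' exceeds the Nyquist frequency are dropped with a warning.
#'
#' @param att A `masksim_attenuation`.
#' @param f_min,f_max Nominal centers considered (defaults 100 Hz - 16 kHz).
#' @return A tibble with one row: `peak_db`, `center_hz`, and the full
#'   per-band table in the attribute `"bands"`.
#' @export
peak_third_octave_attenuation <- function(att, f_min = 100, f_max = 16000) {
  stopifnot(inherits(att, "masksim_attenuation"))
  bands <- third_octave_bands(f_min, f_max)
  nyq <- max(att$frequencies)
  drop <- bands$upper > nyq
  if (any(drop)) {
    warn(sprintf("Dropping %d one-third-octave band(s) above the Nyquist frequency (%g Hz).",
                 sum(drop), nyq))
    bands <- bands[!drop, ]
  }
  if (nrow(bands) == 0) abort("No one-third-octave band fits under the Nyquist frequency.")
  bands$mean_db <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- att$frequencies >= bands$lower[i] & att$frequencies <= bands$upper[i]
    if (!any(sel)) NA_real_ else mean(att$attenuation_db[sel])
  }, numeric(1))
  bands <- bands[!is.na(bands$mean_db), ]
  best <- which.max(bands$mean_db)  # which.max takes the first, i.e. lowest center
  out <- tibble(peak_db = bands$mean_db[best], center_hz = bands$center[best])
  attr(out, "bands") <- bands
  out
}

#' Band summary of an attenuation function
#'
#' The two headline statistics used to characterize a mask: the mean
#' attenuation between 2 and 16 kHz and the peak one-third-octave band
#' attenuation with its nominal center.
#'
#' @param att A `masksim_attenuation`.
#' @return A one-row tibble: `label`, `mean_2_16k_db`, `peak_third_octave_db`,
#'   `peak_center_hz`.
#' @export
summarize_attenuation <- function(att) {
  pk <- peak_third_octave_attenuation(att)
  tibble(label = att$label,
         mean_2_16k_db = band_mean_attenuation(att, 2000, 16000),
         peak_third_octave_db = pk$peak_db,
         peak_center_hz = pk$center_hz)
}

#' Write / read an attenuation function as a two-column CSV
#'
#' @param att A `masksim_attenuation`.
#' @param path CSV path (columns `hz`, `db`).
#' @return `path` invisibly (write); a `masksim_attenuation` (read).
#' @export
write_attenuation_csv <- function(att, path) {
  readr::write_csv(tibble(hz = att$frequencies, db = att$attenuation_db), path)
  invisible(path)
}

#' @rdname write_attenuation_csv
#' @param rate Sample rate implied by the grid; defaults to `2 * max(hz)`.
#' @param label Mask label.
#' @export
read_attenuation_csv <- function(path, rate = NULL, label = "mask") {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("hz", "db") %in% names(d)))
  new_attenuation(d$hz, d$db, rate %||% (2 * max(d$hz)), label)
}
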