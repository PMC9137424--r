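#' Design a linear-phase FIR filter matching an attenuation function
#'
#' Frequency-sampling design (via [signal::fir2()]) of a symmetric FIR
#' filter whose magnitude response approximates the *inverse* of the
#' attenuation function, i.e. a gain of `10^(-attenuation_db/20)` at every
#' bin. A zero-attenuation input yields the all-pass control filter that is
#' applied to unmasked stimuli so the processing chain is identical across
#' conditions.
#'
#' @param att A `masksim_attenuation` defined on the full 0-Nyquist grid.
#' @param order Filter order; the filter has `order + 1` taps. Must be an
#'   even integer >= 8 (even order keeps the group delay at an integer
#'   number of samples).
#' @return A `masksim_filter`: list with `taps`, `order`, `rate`, `target`.
#' @export
#' @examples
#' att <- synth_attenuation_profile("none")
#' h <- design_mask_filter(att)
#' length(h$taps)  # order + 1 = 129
design_mask_filter <- function(att, order = 128) {
  stopifnot(inherits(att, "masksim_attenuation"))
  if (order < 8) abort("Filter order must be at least 8.")
  if (order %% 2 != 0) abort("Filter order must be even (integer group delay).")
  nyq <- att$rate / 2
  if (abs(max(att$frequencies) - nyq) > 1e-6 || att$frequencies[1] != 0) {
    abort("Attenuation must be defined on the full 0-Nyquist grid for filter design.")
  }
  gain <- db_to_gain(-att$attenuation_db)
  taps <- as.numeric(signal::fir2(order, att$frequencies / nyq, gain))
  sym_err <- max(abs(taps - rev(taps)))
  if (sym_err > 1e-9) {
    abort(sprintf("Designed taps are not symmetric (max asymmetry %.2e); not linear phase.",
                  sym_err))
  }
  structure(list(taps = taps, order = as.integer(order), rate = att$rate,
                 target = att),
            class = "masksim_filter")
}

#' All-pass control filter
#'
#' @param rate Sample rate in Hz.
#' @param order Filter order (even).
#' @param n_bins Number of grid bins for the design.
#' @return A `masksim_filter` with unit magnitude response.
#' @export
all_pass_filter <- function(rate = 44100, order = 128, n_bins = 257) {
  f <- seq(0, rate / 2, length.out = n_bins)
  design_mask_filter(new_attenuation(f, rep(0, n_bins), rate, "all-pass"), order)
}

#' @export
print.masksim_filter <- function(x, ...) {
  cat(sprintf("<masksim_filter> order %d (%d taps) @ %g Hz, target '%s'\n",
              x$order, length(x$taps), x$rate, x$target$label))
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' Direct evaluation of the transfer function at arbitrary frequencies.
#'
#' @param filt A `masksim_filter`.
#' @param frequencies Frequencies in Hz.
#' @return A tibble with `hz`, `magnitude_db`.
#' @export
filter_response <- function(filt, frequencies) {
  stopifnot(inherits(filt, "masksim_filter"))
  k <- seq_along(filt$taps) - 1
  mag <- vapply(frequencies, function(f) {
    Mod(sum(filt$taps * exp(-2i * pi * f * k / filt$rate)))
  }, numeric(1))
  tibble(hz = frequencies, magnitude_db = gain_to_db(pmax(mag, .Machine$double.xmin)))
}

# Full linear convolution, FFT-based for long signals. Returns length
# n + order samples.
fir_convolve <- function(x, taps) {
  n <- length(x)
  ord <- length(taps) - 1
  if (n < 8192) {
    xp <- c(numeric(ord), x, numeric(ord))
    y <- stats::filter(xp, taps, method = "convolution", sides = 1)
    return(as.numeric(y[(ord + 1):(2 * ord + n)]))
  }
  # pad to a 2-3-5-smooth length so the FFT stays O(n log n)
  nfft <- stats::nextn(n + ord, c(2, 3, 5))
  X <- fft(c(x, numeric(nfft - n)))
  H <- fft(c(taps, numeric(nfft - length(taps))))
  Re(fft(X * H, inverse = TRUE))[1:(n + ord)] / nfft
}

#' Apply a mask filter to a waveform
#'
#' Linear convolution with group-delay compensation: the output has the
#' same length as the input, shifted back by `order/2` samples so that it
#' is time-aligned with the input (the tail is zero-padded). Annotation
#' spans are preserved unchanged.
#'
#' @param signal A [waveform()] at the rate the filter was designed for.
#' @param filt A `masksim_filter`.
#' @return A [waveform()].
#' @export
apply_filter <- function(signal, filt) {
  stopifnot(inherits(signal, "masksim_wave"), inherits(filt, "masksim_filter"))
  if (abs(signal$rate - filt$rate) > 1e-6) {
    abort(sprintf("Sample-rate mismatch: signal %g Hz, filter designed for %g Hz.",
                  signal$rate, filt$rate))
  }
  yfull <- fir_convolve(signal$samples, filt$taps)
  half <- filt$order / 2
  y <- yfull[(half + 1):(half + length(signal$samples))]
  waveform(y, signal$rate, signal$spans)
}
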