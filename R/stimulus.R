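#' Calibration map between digital RMS and nominal dB SPL
#'
#' The package has no hardware calibration: sound pressure levels are
#' nominal, defined by the SPL assigned to a full-scale (0 dBFS RMS)
#' signal. With the default of 100 dB SPL at full scale, a 70 dB SPL noise
#' has a digital RMS of -30 dBFS.
#'
#' @param spl_at_full_scale dB SPL corresponding to 0 dBFS RMS.
#' @return A `masksim_calibration` object.
#' @export
calibration_map <- function(spl_at_full_scale = 100) {
  stopifnot(is.finite(spl_at_full_scale))
  structure(list(spl_at_full_scale = spl_at_full_scale),
            class = "masksim_calibration")
}

#' @rdname calibration_map
#' @param cal A `masksim_calibration`.
#' @param spl Nominal level in dB SPL.
#' @return `spl_to_rms()`: linear RMS; `rms_to_spl()`: dB SPL.
#' @export
spl_to_rms <- function(cal, spl) db_to_gain(spl - cal$spl_at_full_scale)

#' @rdname calibration_map
#' @param rms Linear RMS in full-scale units.
#' @export
rms_to_spl <- function(cal, rms) cal$spl_at_full_scale + gain_to_db(rms)

#' Trial timeline
#'
#' Timing of one speech-in-noise trial, in milliseconds from noise onset.
#' The video starts 186 ms after noise onset and shows a neutral face for
#' at least 333 ms before any speech-related movement; acoustic speech
#' starts at `speech_onset_ms`.
#'
#' @param noise_ramp_ms Raised-cosine onset/offset ramp duration.
#' @param video_offset_ms Video start re noise onset.
#' @param neutral_lead_ms Minimum neutral-face lead before speech movement.
#' @param speech_onset_ms Acoustic speech onset re noise onset.
#' @param total_ms Total trial (= noise) duration; `NA` until the target
#'   duration is known (filled in by [mix_trial()]).
#' @return A `masksim_timeline` object.
#' @export
trial_timeline <- function(noise_ramp_ms = 20, video_offset_ms = 186,
                           neutral_lead_ms = 333, speech_onset_ms = 776,
                           total_ms = NA_real_) {
  if (neutral_lead_ms < 333) abort("`neutral_lead_ms` must be at least 333 ms.")
  if (video_offset_ms + neutral_lead_ms > speech_onset_ms) {
    abort("Timeline violates video_offset + neutral_lead <= speech_onset.")
  }
  if (!is.na(total_ms) && total_ms < speech_onset_ms + 2 * noise_ramp_ms) {
    abort("`total_ms` too short for the ramps and the speech onset.")
  }
  structure(list(noise_ramp_ms = noise_ramp_ms, video_offset_ms = video_offset_ms,
                 neutral_lead_ms = neutral_lead_ms, speech_onset_ms = speech_onset_ms,
                 total_ms = total_ms),
            class = "masksim_timeline")
}

#' Speech-shaped noise
#'
#' Seeded Gaussian white noise filtered to the long-term spectrum of a
#' reference speech recording. The shaping filter is a linear-phase FIR
#' designed by frequency sampling on the reference spectrum (normalized to
#' unit peak gain); the output is scaled to `rms` and is bit-identical for
#' a fixed seed.
#'
#' @param reference A `masksim_spectrum` (long-term spectrum of the target
#'   speech material).
#' @param duration_s Duration in seconds (default 30).
#' @param seed Integer seed.
#' @param rms Output RMS in full-scale units (default 0.1, leaving
#'   headroom for later level setting).
#' @param filter_order Order of the shaping filter. Higher than the
#'   mask-filter order so the low-frequency speech spectrum is matched
#'   closely.
#' @return A [waveform()] at the reference's sample rate.
#' @export
make_speech_shaped_noise <- function(reference, duration_s = 30, seed = 1,
                                     rms = 0.1, filter_order = 1024) {
  stopifnot(inherits(reference, "masksim_spectrum"))
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  # power-dB spectrum -> amplitude gain: A = 10^(dB/20)
  gain <- db_to_gain(reference$magnitude_db)
  gain <- gain / max(gain)
  nyq <- reference$rate / 2
  taps <- as.numeric(signal::fir2(filter_order, reference$frequencies / nyq, gain))
  n <- round(duration_s * reference$rate)
  x <- withr::with_seed(seed, rnorm(n))
  y <- fir_convolve(x, taps)[(filter_order / 2 + 1):(filter_order / 2 + n)]
  y <- y * (rms / sqrt(mean(y^2)))
  waveform(y, reference$rate)
}

#' Equalize the speech-portion RMS of a set of tokens
#'
#' Each token is scaled so the RMS of its `speech` span matches the common
#' target level. The default target is the mean speech-span level (in dB)
#' across tokens.
#'
#' @param tokens A list of [waveform()]s, each carrying a span labelled
#'   `"speech"`.
#' @param target_rms Common target RMS (linear). Default: dB mean of the
#'   tokens' speech-span RMS values.
#' @return The list of scaled waveforms.
#' @export
rms_equalize <- function(tokens, target_rms = NULL) {
  stopifnot(is.list(tokens), length(tokens) > 0)
  has_speech <- vapply(tokens, function(t) "speech" %in% t$spans$label, logical(1))
  if (!all(has_speech)) {
    abort(sprintf("Token(s) %s lack a 'speech' span annotation.",
                  paste(which(!has_speech), collapse = ", ")))
  }
  levels <- vapply(tokens, function(t) wave_rms(t, "speech"), numeric(1))
  if (is.null(target_rms)) target_rms <- db_to_gain(mean(gain_to_db(levels)))
  purrr::map2(tokens, levels, function(t, l) wave_scale(t, target_rms / l))
}

raised_cosine_ramp <- function(n) (1 - cos(pi * (seq_len(n) - 0.5) / n)) / 2

#' Assemble one calibrated speech-in-noise trial
#'
#' A contiguous noise segment is excised at random (seeded) from the long
#' noise recording, scaled to `noise_spl` under the calibration map, and
#' given raised-cosine onset/offset ramps. The target is scaled so that
#' its speech-span RMS sits `snr_db` above the noise RMS, then added at
#' the timeline's speech onset. The total duration is the speech onset
#' plus the target duration plus a 333 ms tail and the offset ramp.
#'
#' @param target A [waveform()] with a `"speech"` span.
#' @param noise A [waveform()] at the same rate (e.g. from
#'   [make_speech_shaped_noise()]).
#' @param snr_db Signal-to-noise ratio in dB (speech-span RMS re noise RMS).
#' @param noise_spl Nominal noise level in dB SPL (default 70).
#' @param cal A [calibration_map()].
#' @param timeline A [trial_timeline()]; `total_ms` is computed here.
#' @param seed Integer seed for the noise excision.
#' @return A list with `wave` (the mixed trial), `timeline` (completed),
#'   `noise_rms`, `target_rms` (linear, as realized).
#' @export
mix_trial <- function(target, noise, snr_db = 0, noise_spl = 70,
                      cal = calibration_map(), timeline = trial_timeline(),
                      seed = 1) {
  stopifnot(inherits(target, "masksim_wave"), inherits(noise, "masksim_wave"))
  if (!is.finite(snr_db)) abort("`snr_db` must be finite.")
  if (abs(target$rate - noise$rate) > 1e-6) abort("Target and noise rates differ.")
  rate <- target$rate
  ms <- function(x) round(x * rate / 1000)
  tail_ms <- 333
  total_ms <- timeline$speech_onset_ms + 1000 * wave_duration(target) +
    tail_ms + timeline$noise_ramp_ms
  timeline$total_ms <- total_ms
  n_total <- ms(total_ms)
  if (length(noise$samples) < n_total) {
    abort(sprintf("Noise too short: %d samples available, trial needs %d.",
                  length(noise$samples), n_total))
  }
  start <- withr::with_seed(seed,
    sample.int(length(noise$samples) - n_total + 1, 1))
  seg <- noise$samples[start:(start + n_total - 1)]
  noise_rms_target <- spl_to_rms(cal, noise_spl)
  seg <- seg * (noise_rms_target / sqrt(mean(seg^2)))
  nr <- ms(timeline$noise_ramp_ms)
  ramp <- raised_cosine_ramp(nr)
  seg[1:nr] <- seg[1:nr] * ramp
  seg[(n_total - nr + 1):n_total] <- seg[(n_total - nr + 1):n_total] * rev(ramp)

  sp_rms <- wave_rms(target, "speech")
  tgt_rms <- noise_rms_target * db_to_gain(snr_db)
  tgt <- target$samples * (tgt_rms / sp_rms)
  onset <- ms(timeline$speech_onset_ms)
  mix <- seg
  idx <- (onset + 1):(onset + length(tgt))
  mix[idx] <- mix[idx] + tgt
  if (max(abs(mix)) > 1) {
    abort(sprintf(
      "Mixed trial clips (peak %.2f > 1). Lower `spl_at_full_scale` headroom or the requested levels.",
      max(abs(mix))))
  }
  spans <- tibble(label = c("noise", "speech"),
                  start = c(1L, onset + 1L),
                  end = c(n_total, onset + length(tgt)))
  sp <- target$spans[target$spans$label == "speech", ]
  if (nrow(sp) == 1) {
    spans$start[2] <- onset + sp$start[1]
    spans$end[2] <- onset + sp$end[1]
  }
  list(wave = waveform(mix, rate, spans),
       timeline = timeline,
       noise_rms = noise_rms_target,
       target_rms = tgt_rms)
}

#' Measure the nominal SPL of a waveform span
#'
#' @param x A [waveform()].
#' @param cal A [calibration_map()].
#' @param label Optional span label.
#' @return Nominal level in dB SPL.
#' @export
measure_spl <- function(x, cal = calibration_map(), label = NULL) {
  rms_to_spl(cal, wave_rms(x, label))
}
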