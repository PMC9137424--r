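#' Synthetic long-term speech spectrum
#'
#' A smooth long-term average speech spectrum on the default Welch grid:
#' flat peak region around 300-500 Hz, about -9 dB/octave roll-off above,
#' and a steep roll-off below 200 Hz. Used as the shaping reference for
#' speech-shaped noise and synthetic recording pairs.
#'
#' @param rate Sample rate in Hz.
#' @param n_bins Number of one-sided bins (default 257, the 512-point grid).
#' @return A `masksim_spectrum`.
#' @export
synth_ltass_spectrum <- function(rate = 44100, n_bins = 257) {
  f <- seq(0, rate / 2, length.out = n_bins)
  fk <- pmax(f, 1)
  db <- -9 * log2(pmax(fk, 450) / 450) - 12 * pmax(0, log2(220 / fk))
  structure(list(frequencies = f, magnitude_db = db,
                 params = spectral_params(), rate = rate),
            class = "masksim_spectrum")
}

#' Synthetic mask attenuation profile
#'
#' Smooth attenuation profiles emulating measured face-mask spectra:
#' near 0 dB below 1 kHz, a high-frequency shelf rising over 1-2.5 kHz,
#' and a one-third-octave-scale bump. The shelf and bump amplitudes are
#' solved linearly so that the 2-16 kHz band mean and the peak
#' one-third-octave band mean hit their targets exactly by construction.
#'
#' Presets: `"none"` (0 dB), `"hospital"` (mean 2.4 dB, peak 5.5 dB at
#' 8 kHz), `"fabric"` (mean 8 dB, peak 12.7 dB at 3.15 kHz),
#' `"transparent"` (mean 5.9 dB, peak 11.9 dB at 16 kHz),
#' `"communicator"` (mean 5.5 dB, peak 14.9 dB at 3.55 kHz).
#'
#' @param kind Preset name or `"parametric"`.
#' @param mean_2_16k_db Target band mean 2-16 kHz (parametric).
#' @param peak_db Target peak one-third-octave band mean (parametric).
#' @param peak_hz Bump center in Hz (parametric).
#' @param rate,n_bins Frequency grid (defaults match the Welch grid).
#' @return A `masksim_attenuation`.
#' @export
#' @examples
#' att <- synth_attenuation_profile("fabric")
#' band_mean_attenuation(att, 2000, 16000)  # 8 by construction
synth_attenuation_profile <- function(kind = c("none", "hospital", "fabric",
                                               "transparent", "communicator",
                                               "parametric"),
                                      mean_2_16k_db = NULL, peak_db = NULL,
                                      peak_hz = NULL, rate = 44100, n_bins = 257) {
  kind <- match.arg(kind)
  f <- seq(0, rate / 2, length.out = n_bins)
  label <- kind
  if (kind == "none") {
    return(new_attenuation(f, rep(0, n_bins), rate, "none"))
  }
  presets <- list(
    hospital = list(mean = 2.4, peak = 5.5, hz = 8000),
    fabric = list(mean = 8.0, peak = 12.7, hz = 3150),
    transparent = list(mean = 5.9, peak = 11.9, hz = 16000),
    communicator = list(mean = 5.5, peak = 14.9, hz = 3550)
  )
  if (kind == "parametric") {
    if (is.null(mean_2_16k_db) || is.null(peak_hz)) {
      abort("Parametric profiles need `mean_2_16k_db` and `peak_hz` (and optionally `peak_db`).")
    }
    tgt <- list(mean = mean_2_16k_db, peak = peak_db, hz = peak_hz)
    label <- sprintf("parametric(%g dB @ %g Hz)", mean_2_16k_db, peak_hz)
  } else {
    tgt <- presets[[kind]]
    if (!is.null(mean_2_16k_db)) tgt$mean <- mean_2_16k_db
    if (!is.null(peak_db)) tgt$peak <- peak_db
    if (!is.null(peak_hz)) tgt$hz <- peak_hz
  }
  fk <- pmax(f, 1)
  shelf <- plogis(6 * log2(fk / 1600))
  bump <- exp(-0.5 * (log2(fk / tgt$hz) / 0.45)^2)
  in_mean <- f >= 2000 & f <= 16000
  in_peak <- f >= tgt$hz * 2^(-1 / 6) & f <= tgt$hz * 2^(1 / 6)
  if (is.null(tgt$peak)) {
    s <- tgt$mean / mean(shelf[in_mean])
    b <- 0
  } else {
    A <- matrix(c(mean(shelf[in_mean]), mean(bump[in_mean]),
                  mean(shelf[in_peak]), mean(bump[in_peak])),
                2, 2, byrow = TRUE)
    sol <- solve(A, c(tgt$mean, tgt$peak))
    s <- sol[1]; b <- sol[2]
    if (b < 0) {
      warn("Peak target below the shelf level; dropping the bump.")
      s <- tgt$mean / mean(shelf[in_mean]); b <- 0
    }
  }
  new_attenuation(f, s * shelf + b * bump, rate, label)
}

#' Synthetic masked/unmasked recording pair
#'
#' Ground truth for attenuation recovery: a speech-shaped reference signal
#' and the same signal passed through a high-order linear-phase filter
#' realizing the given attenuation profile, plus small independent
#' measurement noise on the masked channel.
#'
#' @param profile A `masksim_attenuation` (the known ground truth).
#' @param duration_s Duration in seconds (>= 10 recommended, 60 for
#'   sub-dB recovery).
#' @param seed Integer seed.
#' @param noise_db Measurement-noise level in dB relative to the reference
#'   RMS (default -60; `-Inf` disables it).
#' @param realization_order Order of the filter realizing the profile
#'   (default 512, well above the analysis filter so design error does not
#'   contaminate the ground truth).
#' @return A list with `reference` and `masked` [waveform()]s.
#' @export
synth_masked_pair <- function(profile, duration_s = 60, seed = 1,
                              noise_db = -60, realization_order = 512) {
  stopifnot(inherits(profile, "masksim_attenuation"))
  ltass <- synth_ltass_spectrum(profile$rate, length(profile$frequencies))
  reference <- make_speech_shaped_noise(ltass, duration_s, seed = seed)
  filt <- design_mask_filter(profile, order = realization_order)
  masked <- apply_filter(reference, filt)
  if (is.finite(noise_db)) {
    n <- length(masked$samples)
    meas <- withr::with_seed(seed + 1L, rnorm(n))
    meas <- meas * (wave_rms(reference) * db_to_gain(noise_db) / sqrt(mean(meas^2)))
    masked$samples <- masked$samples + meas
  }
  list(reference = reference, masked = masked)
}

#' Estimate a mask attenuation function from a recording pair
#'
#' Convenience wrapper chaining [estimate_magnitude_spectrum()] on both
#' recordings and [attenuation_function()].
#'
#' @param masked,reference [waveform()]s at the same rate.
#' @param params [spectral_params()].
#' @param clamp_db,label Passed to [attenuation_function()].
#' @return A `masksim_attenuation`.
#' @export
estimate_attenuation <- function(masked, reference, params = spectral_params(),
                                 clamp_db = 30, label = "mask") {
  attenuation_function(estimate_magnitude_spectrum(masked, params),
                       estimate_magnitude_spectrum(reference, params),
                       clamp_db = clamp_db, label = label)
}

consonant_synth_table <- function() {
  tibble(
    consonant = c("b", "d", "p", "t", "k", "m", "n", "v", "z", "s", "h", "sh"),
    type = c("stop", "stop", "stop", "stop", "stop", "nasal", "nasal",
             "fricative", "fricative", "fricative", "fricative", "fricative"),
    band_lo = c(300, 2500, 500, 3000, 1500, 150, 200, 500, 3500, 4000, 500, 2000),
    band_hi = c(2000, 4000, 1500, 6000, 3500, 500, 600, 2500, 9000, 10000, 3000, 6000)
  )
}

bandpass_noise <- function(n, rate, f_lo, f_hi, order = 256) {
  nyq <- rate / 2
  grid <- seq(0, 1, length.out = 129)
  gain <- as.numeric(grid * nyq >= f_lo & grid * nyq <= f_hi)
  taps <- as.numeric(signal::fir2(order, grid, gain))
  fir_convolve(rnorm(n), taps)[(order / 2 + 1):(order / 2 + n)]
}

#' Synthesize a CV-like speech token
#'
#' A stylized consonant-vowel token: a consonant segment whose energy
#' concentrates in a consonant-specific band (noise for fricatives, a
#' brief burst for stops, a low harmonic murmur for nasals) followed by a
#' harmonic /i/-like vowel at F0 = 238 Hz with an /i/ formant envelope.
#' Total duration is drawn within 728-941 ms (mean about 856 ms). The
#' returned waveform carries `speech`, `consonant` and `vowel` spans.
#'
#' @param consonant One of [consonants()].
#' @param seed Integer seed.
#' @param rate Sample rate in Hz.
#' @param f0 Fundamental frequency of the vowel in Hz.
#' @return A [waveform()].
#' @export
synth_cv_token <- function(consonant, seed = 1, rate = 44100, f0 = 238) {
  tab <- consonant_synth_table()
  if (!consonant %in% tab$consonant) {
    abort(sprintf("Unknown consonant '%s'; expected one of %s.",
                  consonant, paste(tab$consonant, collapse = ", ")))
  }
  row <- tab[tab$consonant == consonant, ]
  withr::with_seed(seed, {
    dur_ms <- 0
    while (dur_ms < 728 || dur_ms > 941) dur_ms <- rnorm(1, 856, 45)
    ms <- function(x) round(x * rate / 1000)
    n_total <- ms(dur_ms)
    n_pad <- ms(25)
    n_cons <- ms(140)
    n_vow <- n_total - 2 * n_pad - n_cons

    # consonant segment
    cons <- switch(row$type,
      fricative = bandpass_noise(n_cons, rate, row$band_lo, row$band_hi),
      stop = {
        n_burst <- ms(15)
        c(bandpass_noise(n_burst, rate, row$band_lo, row$band_hi),
          rnorm(n_cons - n_burst) * 1e-4)
      },
      nasal = {
        t <- seq_len(n_cons) / rate
        0.6 * sin(2 * pi * f0 * t) + 0.3 * sin(2 * pi * 2 * f0 * t) +
          0.1 * rnorm(n_cons) * 0.05
      })
    cons <- cons / max(sqrt(mean(cons^2)), 1e-12) * 0.05

    # /i/-like vowel: harmonics shaped by formant resonances
    t <- seq_len(n_vow) / rate
    formants <- cbind(c(270, 2290, 3010), c(60, 100, 150))
    harm <- seq(f0, 5500, by = f0)
    amp <- vapply(harm, function(h) {
      sum(1 / sqrt(1 + ((h - formants[, 1]) / formants[, 2])^2))
    }, numeric(1))
    amp <- amp / max(amp)
    vow <- numeric(n_vow)
    phase <- runif(length(harm), 0, 2 * pi)
    for (i in seq_along(harm)) {
      vow <- vow + amp[i] * sin(2 * pi * harm[i] * t + phase[i])
    }
    nr <- ms(10)
    ramp <- raised_cosine_ramp(nr)
    vow[1:nr] <- vow[1:nr] * ramp
    vow[(n_vow - nr + 1):n_vow] <- vow[(n_vow - nr + 1):n_vow] * rev(ramp)
    vow <- vow / sqrt(mean(vow^2)) * 0.1

    samples <- c(numeric(n_pad), cons, vow, numeric(n_pad))
    spans <- tibble(
      label = c("speech", "consonant", "vowel"),
      start = c(n_pad + 1L, n_pad + 1L, n_pad + n_cons + 1L),
      end = c(n_pad + n_cons + n_vow, n_pad + n_cons, n_pad + n_cons + n_vow)
    )
    waveform(samples, rate, spans)
  })
}

#' Synthetic 66-point facial landmark sequence
#'
#' Generates frames of the canonical 66-point layout for a stylized face
#' with smooth periodic jaw/lip motion. The mouth aperture follows a
#' raised-cosine cycle of `motion$aperture_px` peak opening; small seeded
#' Gaussian jitter emulates detector noise. At zero aperture the inner-lip
#' points of the upper and lower rim coincide.
#'
#' @param n_frames Number of frames (>= 1).
#' @param motion List with `aperture_px` (peak mouth opening, default 12),
#'   `period_frames` (cycle length, default 30), `jitter_px` (detector
#'   noise SD, default 0.3).
#' @param seed Integer seed.
#' @param width,height Frame size in pixels.
#' @return A tibble with `frame`, `point_id`, `x`, `y`; every frame
#'   satisfies the landmark-frame invariants.
#' @export
synth_face_landmarks <- function(n_frames = 30,
                                 motion = list(aperture_px = 12,
                                               period_frames = 30,
                                               jitter_px = 0.3),
                                 seed = 1, width = 320, height = 240) {
  stopifnot(n_frames >= 1)
  motion <- modifyList(list(aperture_px = 12, period_frames = 30, jitter_px = 0.3),
                       motion)
  cx <- width / 2; cy <- height / 2
  base_frame <- function(ap) {
    phi <- pi * (0:16) / 16
    jaw_x <- cx - 60 * cos(phi)
    jaw_y <- cy + 85 * sin(phi) + 0.3 * ap * sin(phi)
    brow <- function(xc) {
      xs <- seq(xc - 16, xc + 16, length.out = 5)
      ys <- cy - 38 - 4 * sin(pi * (0:4) / 4)
      list(x = xs, y = ys)
    }
    bl <- brow(cx - 30); br <- brow(cx + 30)
    bridge_x <- rep(cx, 4); bridge_y <- seq(cy - 25, cy + 5, length.out = 4)
    nost_x <- seq(cx - 10, cx + 10, length.out = 5); nost_y <- rep(cy + 14, 5)
    eye <- function(xc) {
      th <- 2 * pi * (0:5) / 6
      list(x = xc + 10 * cos(th), y = cy - 22 + 4 * sin(th))
    }
    el <- eye(cx - 30); er <- eye(cx + 30)
    mouth_y <- cy + 45
    th <- 2 * pi * (0:9) / 10
    out_x <- cx + 22 * cos(th)
    out_y <- mouth_y + (8 + ap / 2) * sin(th)
    in_xs <- cx + c(-12, -4, 4, 12)
    upper_y <- mouth_y - (ap / 2) * c(0.6, 1, 1, 0.6)
    lower_y <- mouth_y + (ap / 2) * c(0.6, 1, 1, 0.6)
    tibble(
      point_id = 0:65,
      x = c(jaw_x, bl$x, br$x, bridge_x, nost_x, el$x, er$x,
            out_x, in_xs, in_xs),
      y = c(jaw_y, bl$y, br$y, bridge_y, nost_y, el$y, er$y,
            out_y, upper_y, lower_y)
    )
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_frames), function(fr) {
      ap <- motion$aperture_px *
        (0.5 - 0.5 * cos(2 * pi * (fr - 1) / motion$period_frames))
      d <- base_frame(ap)
      d$x <- d$x + rnorm(66, 0, motion$jitter_px)
      d$y <- d$y + rnorm(66, 0, motion$jitter_px)
      d$frame <- fr
      validate_landmark_frame(d, width, height)
      d[, c("frame", "point_id", "x", "y")]
    })
  })
}

#' Synthetic video frame image
#'
#' A smooth random grayscale-gradient RGB frame for rasterization tests;
#' carries no facial content.
#'
#' @param width,height Size in pixels.
#' @param seed Integer seed.
#' @return An `height x width x 3` array in `[0, 1]`.
#' @export
synth_frame_image <- function(width = 320, height = 240, seed = 1) {
  withr::with_seed(seed, {
    gx <- matrix(rep(seq(0.2, 0.8, length.out = width), each = height),
                 nrow = height)
    gy <- matrix(rep(seq(0.3, 0.7, length.out = height), times = width),
                 nrow = height)
    noise <- matrix(runif(height * width, -0.05, 0.05), nrow = height)
    base <- pmin(pmax((gx + gy) / 2 + noise, 0), 1)
    array(c(base, base * 0.9, base * 0.8), dim = c(height, width, 3))
  })
}
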