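test_that("Welch spectrum has the canonical grid and finds sinusoid peaks", {
  w <- waveform(rnorm(44100), 44100)
  sp <- estimate_magnitude_spectrum(w)
  expect_length(sp$frequencies, 257)
  expect_equal(sp$frequencies[1], 0)
  expect_equal(max(sp$frequencies), 22050)

  # pure tone at a bin center dominates that bin
  f_bin <- sp$frequencies[30]
  tone <- waveform(sin(2 * pi * f_bin * seq_len(44100) / 44100), 44100)
  spt <- estimate_magnitude_spectrum(tone)
  expect_equal(which.max(spt$magnitude_db), 30)

  expect_error(estimate_magnitude_spectrum(waveform(rnorm(600), 44100)),
               "too short")
})

test_that("long white noise gives a flat averaged periodogram", {
  w <- waveform(withr::with_seed(11, rnorm(30 * 44100)), 44100)
  sp <- estimate_magnitude_spectrum(w)
  sel <- sp$frequencies >= 100 & sp$frequencies <= 20000
  dev <- sp$magnitude_db[sel] - mean(sp$magnitude_db[sel])
  expect_lt(max(abs(dev)), 1)
})

test_that("attenuation is the reference-minus-masked spectral difference", {
  w <- waveform(withr::with_seed(2, rnorm(10 * 44100)), 44100)
  sp <- estimate_magnitude_spectrum(w)
  # identity: zero attenuation everywhere
  att0 <- attenuation_function(sp, sp)
  expect_equal(att0$attenuation_db, rep(0, 257))

  # broadband -6 dB gain oracle
  w6 <- waveform(w$samples * 10^(-6 / 20), 44100)
  att6 <- attenuation_function(estimate_magnitude_spectrum(w6), sp)
  expect_true(all(abs(att6$attenuation_db - 6) < 0.1))

  # clamping bounds extreme differences
  w_big <- waveform(w$samples * 10^(-60 / 20), 44100)
  attc <- attenuation_function(estimate_magnitude_spectrum(w_big), sp)
  expect_true(all(attc$attenuation_db <= 30))

  sp8 <- estimate_magnitude_spectrum(waveform(rnorm(44100), 22050))
  expect_error(attenuation_function(sp8, sp), "grids differ")
})

test_that("filter design produces symmetric taps and matches smooth targets", {
  att <- synth_attenuation_profile("fabric")
  h <- design_mask_filter(att, order = 128)
  expect_length(h$taps, 129)
  expect_lt(max(abs(h$taps - rev(h$taps))), 1e-9)
  expect_error(design_mask_filter(att, order = 4), "at least 8")
  expect_error(design_mask_filter(att, order = 127), "even")

  # smooth -10 dB shelf above 4 kHz: designed response within 1 dB of the
  # target outside a one-third-octave transition band (FFT oracle)
  f <- seq(0, 22050, length.out = 257)
  shelf <- 10 * plogis(12 * log2(pmax(f, 1) / 4000))
  hs <- design_mask_filter(
    masksim:::new_attenuation(f, shelf, 44100, "shelf"), 128)
  fr <- exp(seq(log(60), log(20000), length.out = 300))
  outside <- fr < 4000 * 2^(-1 / 6) | fr > 4000 * 2^(1 / 6)
  resp <- fft_magnitude_db(hs$taps, fr[outside], 44100)
  target <- -10 * plogis(12 * log2(fr[outside] / 4000))
  expect_lt(max(abs(resp - target)), 1)
})

test_that("all-pass control is transparent and filtering is delay-compensated", {
  ap <- all_pass_filter()
  fr <- exp(seq(log(50), log(20000), length.out = 200))
  expect_lt(max(abs(fft_magnitude_db(ap$taps, fr, 44100))), 0.1)

  x <- waveform(withr::with_seed(3, rnorm(44100)), 44100)
  y <- apply_filter(x, ap)
  expect_length(y$samples, length(x$samples))
  expect_lt(sqrt(mean((y$samples - x$samples)^2)), 1e-6)

  expect_error(apply_filter(waveform(rnorm(5000), 22050), ap), "mismatch")
})

test_that("a sinusoid is attenuated by the filter's gain at its frequency", {
  f <- seq(0, 22050, length.out = 257)
  att <- masksim:::new_attenuation(
    f, 12 * plogis(10 * log2(pmax(f, 1) / 4000)), 44100, "hf12")
  h <- design_mask_filter(att, 128)
  t <- seq_len(44100) / 44100
  x <- waveform(sin(2 * pi * 8000 * t), 44100)
  y <- apply_filter(x, h)
  drop_db <- 20 * log10(wave_rms(x) / wave_rms(y))
  expect_lt(abs(drop_db - 12), 0.5)
})

test_that("a fabric filter hits consonants harder than vowels", {
  tok <- synth_cv_token("s", seed = 7)
  h <- design_mask_filter(synth_attenuation_profile("fabric"))
  filt <- apply_filter(tok, h)
  cons_drop <- 20 * log10(wave_rms(tok, "consonant") / wave_rms(filt, "consonant"))
  vow_drop <- 20 * log10(wave_rms(tok, "vowel") / wave_rms(filt, "vowel"))
  expect_gt(cons_drop, vow_drop)
})

test_that("band means behave like means and ignore common offsets", {
  f <- seq(0, 22050, length.out = 257)
  z <- masksim:::new_attenuation(f, rep(0, 257), 44100, "z")
  expect_equal(band_mean_attenuation(z, 2000, 16000), 0)
  c6 <- masksim:::new_attenuation(f, rep(6, 257), 44100, "c")
  expect_equal(band_mean_attenuation(c6, 100, 10000), 6)
  expect_equal(band_mean_attenuation(c6, 3000, 5000), 6)
  expect_error(band_mean_attenuation(c6, 5000, 5000), "f_lo")
  expect_error(band_mean_attenuation(c6, 5000.1, 5000.4), "No spectral bins")

  # invariance to adding a constant to both spectra
  w <- waveform(withr::with_seed(5, rnorm(5 * 44100)), 44100)
  spr <- estimate_magnitude_spectrum(w)
  spm <- estimate_magnitude_spectrum(waveform(w$samples * 0.5, 44100))
  a1 <- band_mean_attenuation(attenuation_function(spm, spr), 2000, 16000)
  spr2 <- spr; spm2 <- spm
  spr2$magnitude_db <- spr2$magnitude_db + 7.3
  spm2$magnitude_db <- spm2$magnitude_db + 7.3
  a2 <- band_mean_attenuation(attenuation_function(spm2, spr2), 2000, 16000)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("peak one-third-octave band is found by band enumeration", {
  # fine grid so even the lowest one-third-octave bands contain bins
  f <- seq(0, 22050, length.out = 2049)
  # constant profile: every band mean is 5; tie broken at the lowest center
  c5 <- masksim:::new_attenuation(f, rep(5, 2049), 44100, "c5")
  pk <- peak_third_octave_attenuation(c5)
  expect_equal(pk$peak_db, 5)
  expect_equal(pk$center_hz, 100)

  # 15 dB notch spanning exactly the 3.15 kHz band
  in_band <- f >= 3150 * 2^(-1 / 6) & f <= 3150 * 2^(1 / 6)
  notch <- masksim:::new_attenuation(f, 15 * in_band, 44100, "notch")
  pk2 <- peak_third_octave_attenuation(notch)
  expect_equal(pk2$center_hz, 3150)
  expect_equal(pk2$peak_db, 15)

  # oracle: enumerate every band mean independently and take the max
  bands <- third_octave_bands(100, 16000)
  means <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- f >= bands$lower[i] & f <= bands$upper[i]
    mean(notch$attenuation_db[sel])
  }, numeric(1))
  expect_equal(pk2$peak_db, max(means))
  expect_equal(pk2$center_hz, bands$center[which.max(means)])
})

test_that("design-apply-estimate round trip recovers smooth profiles", {
  att <- synth_attenuation_profile("hospital")
  h <- design_mask_filter(att, 128)
  x <- waveform(withr::with_seed(9, rnorm(20 * 44100)), 44100)
  y <- apply_filter(x, h)
  rec <- attenuation_function(estimate_magnitude_spectrum(y),
                              estimate_magnitude_spectrum(x))
  sel <- rec$frequencies >= 200 & rec$frequencies <= 10000
  expect_lt(max(abs(rec$attenuation_db[sel] - att$attenuation_db[sel])), 1)
})
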