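test_that("CV tokens have the target duration, F0 structure and spans", {
  for (s in 1:4) {
    tok <- synth_cv_token("b", seed = s)
    dur <- wave_duration(tok) * 1000
    expect_gte(dur, 728)
    expect_lte(dur, 941)
    expect_setequal(tok$spans$label, c("speech", "consonant", "vowel"))
  }
  expect_identical(synth_cv_token("z", seed = 3)$samples,
                   synth_cv_token("z", seed = 3)$samples)
  expect_error(synth_cv_token("q"), "Unknown consonant")

  # vowel is harmonic at F0 ~ 238 Hz: strongest low peak at the fundamental
  tok <- synth_cv_token("m", seed = 2)
  vow <- waveform(rep(wave_span(tok, "vowel"), 3), tok$rate)
  sp <- estimate_magnitude_spectrum(vow)
  low <- sp$frequencies > 100 & sp$frequencies < 360
  peak_hz <- sp$frequencies[low][which.max(sp$magnitude_db[low])]
  expect_lt(abs(peak_hz - 238), 44100 / 512)  # within one bin

  # /s/: consonant-span energy concentrated above 3 kHz
  s_tok <- synth_cv_token("s", seed = 5)
  cons <- waveform(rep(wave_span(s_tok, "consonant"), 4), s_tok$rate)
  spc <- estimate_magnitude_spectrum(cons)
  pow <- 10^(spc$magnitude_db / 10)
  expect_gt(sum(pow[spc$frequencies > 3000]) / sum(pow), 0.7)
})

test_that("attenuation profiles hit their band statistics by construction", {
  none <- synth_attenuation_profile("none")
  expect_true(all(none$attenuation_db == 0))

  fab <- synth_attenuation_profile("fabric")
  expect_lt(abs(band_mean_attenuation(fab, 2000, 16000) - 8.0), 0.2)
  pk <- peak_third_octave_attenuation(fab)
  expect_equal(pk$center_hz, 3150)
  expect_lt(abs(pk$peak_db - 12.7), 0.1)
  low <- fab$frequencies > 0 & fab$frequencies < 1000
  expect_lt(max(abs(fab$attenuation_db[low])), 1)

  hos <- synth_attenuation_profile("hospital")
  expect_lt(abs(band_mean_attenuation(hos, 2000, 16000) - 2.4), 0.1)

  par <- synth_attenuation_profile("parametric", mean_2_16k_db = 6,
                                   peak_db = 10, peak_hz = 4000)
  expect_lt(abs(band_mean_attenuation(par, 2000, 16000) - 6), 1e-6)
  expect_lt(abs(peak_third_octave_attenuation(par)$peak_db - 10), 1e-6)
})

test_that("masked pairs carry their ground-truth profile", {
  none <- synth_attenuation_profile("none")
  pair0 <- synth_masked_pair(none, duration_s = 2, seed = 1, noise_db = -Inf)
  expect_lt(sqrt(mean((pair0$masked$samples - pair0$reference$samples)^2)),
            1e-9)

  fab <- synth_attenuation_profile("fabric")
  pair <- synth_masked_pair(fab, duration_s = 16, seed = 2)
  expect_identical(pair$masked$samples,
                   synth_masked_pair(fab, duration_s = 16, seed = 2)$masked$samples)
  rec <- estimate_attenuation(pair$masked, pair$reference)
  sel <- rec$frequencies >= 200 & rec$frequencies <= 10000
  expect_lt(max(abs(rec$attenuation_db[sel] - fab$attenuation_db[sel])), 1)
})

test_that("synthetic landmark sequences satisfy every frame invariant", {
  lm <- synth_face_landmarks(1, seed = 3)
  expect_equal(nrow(lm), 66)
  expect_silent(validate_landmark_frame(lm, width = 320, height = 240))

  still <- synth_face_landmarks(3, motion = list(aperture_px = 0, jitter_px = 0),
                                seed = 1)
  f1 <- still[still$frame == 1, ]
  upper <- f1[f1$point_id %in% 58:61, ]
  lower <- f1[f1$point_id %in% 62:65, ]
  expect_lt(max(abs(upper$y - lower$y)), 1)  # closed mouth: inner rims meet

  expect_identical(synth_face_landmarks(5, seed = 9),
                   synth_face_landmarks(5, seed = 9))
})

test_that("the listener model is exact at the probability extremes", {
  targets <- sample(consonants(), 400, replace = TRUE)
  all1 <- withr::with_seed(1, simulate_listener(
    targets, c(voicing = 1, manner = 1, place = 1)))
  expect_identical(all1, targets)

  # all-zero transmission: responses uniform over the 12 consonants
  resp <- withr::with_seed(2, simulate_listener(
    sample(rep(consonants(), 1000)), c(voicing = 0, manner = 0, place = 0)))
  gof <- chisq.test(table(factor(resp, levels = consonants())))
  expect_gt(gof$p.value, 0.001)
})

test_that("empirical listener rates match exhaustive enumeration", {
  p <- c(voicing = 0.9, manner = 0.9, place = 0.9)
  expected <- enumerate_listener_rates(0.9, 0.9, 0.9)
  # implementation's own enumeration agrees with the independent oracle
  impl <- listener_expected_rates(p)
  expect_equal(unname(unlist(impl)), unname(expected), tolerance = 1e-12)

  n <- 10000
  targets <- sample(rep(consonants(), ceiling(n / 12))[1:n])
  resp <- withr::with_seed(13, simulate_listener(targets, p))
  sch <- feature_scheme()
  for (f in c("voicing", "manner", "place")) {
    fv <- setNames(sch[[f]], sch$consonant)
    obs <- mean(fv[targets] == fv[resp])
    se <- sqrt(expected[f] * (1 - expected[f]) / n)
    expect_lt(abs(obs - expected[f]), 3 * se)
  }
  obs_acc <- mean(targets == resp)
  se_acc <- sqrt(expected["accuracy"] * (1 - expected["accuracy"]) / n)
  expect_lt(abs(obs_acc - expected["accuracy"]), 3 * se_acc)
})

test_that("feature transmission never falls below the configured probability", {
  for (p in list(c(0.3, 0.6, 0.8), c(0.9, 0.2, 0.5), c(0.5, 0.5, 0.5))) {
    ex <- enumerate_listener_rates(p[1], p[2], p[3])
    expect_gte(ex["voicing"], p[1])
    expect_gte(ex["manner"], p[2])
    expect_gte(ex["place"], p[3])
  }
})

test_that("cohort simulation produces the full factorial trial table", {
  des <- cohort_design(n_per_group = c(CNH = 2, CHL = 2, ANH = 2))
  tr <- simulate_cohort(des, seed = 3)
  # 6 subjects x 11 conditions x 2 runs x 36 trials
  expect_equal(nrow(tr), 6 * 11 * 2 * 36)
  counts <- dplyr::count(tr, subject_id, mask, modality, run)
  expect_true(all(counts$n == 36))
  per_block <- dplyr::count(tr, subject_id, mask, modality, run, target)
  expect_true(all(per_block$n == 3))

  expect_identical(tr, simulate_cohort(des, seed = 3))

  # extreme logits with no heterogeneity: every response correct
  perfect <- listener_params(
    baseline = c(voicing = 20, manner = 20, place = 20),
    effects = tibble::tibble(mask = character(), modality = character(),
                             feature = character(), dlogit = numeric()),
    subject_sd = 0)
  tr2 <- simulate_cohort(cohort_design(n_per_group = c(CNH = 1)), perfect,
                         seed = 1)
  expect_true(all(tr2$target == tr2$response))
})

test_that("calibration inverts expected accuracy of the listener model", {
  q <- calibrate_uniform_transmission(0.6)
  got <- listener_expected_rates(setNames(rep(q, 3),
                                          c("voicing", "manner", "place")))
  expect_equal(got$accuracy, 0.6, tolerance = 1e-6)
  expect_error(calibrate_uniform_transmission(0.01), "attainable")
})
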