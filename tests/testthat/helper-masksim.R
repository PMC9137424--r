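# Shared fixtures and independent oracles for the test suite.

# Independent frequency-response oracle: magnitude of an FIR filter via a
# zero-padded FFT (does not go through filter_response()).
fft_magnitude_db <- function(taps, frequencies, rate, nfft = 2^16) {
  H <- fft(c(taps, numeric(nfft - length(taps))))
  f_grid <- (0:(nfft - 1)) * rate / nfft
  idx <- vapply(frequencies, function(f) which.min(abs(f_grid - f)), integer(1))
  20 * log10(Mod(H[idx]))
}

# Independent even-odd point-in-polygon oracle (ray casting).
ray_cast_inside <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      x_int <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

# Independent enumeration of the feature-channel listener: expected
# accuracy and per-feature transmission for uniform targets, written
# directly from the generative definition.
enumerate_listener_rates <- function(pv, pm, pp) {
  sch <- masksim::feature_scheme()
  cons <- sch$consonant
  probs <- c(pv, pm, pp)
  acc <- 0
  tr <- c(voicing = 0, manner = 0, place = 0)
  for (t in cons) {
    tv <- sch[sch$consonant == t, ]
    for (bv in 0:1) for (bm in 0:1) for (bp in 0:1) {
      bits <- c(bv, bm, bp) == 1
      w <- prod(ifelse(bits, probs, 1 - probs))
      if (all(bits)) {
        cand <- t
      } else {
        keep <- rep(TRUE, 12)
        if (bits[1]) keep <- keep & sch$voicing == tv$voicing
        if (bits[2]) keep <- keep & sch$manner == tv$manner
        if (bits[3]) keep <- keep & sch$place == tv$place
        cand <- cons[keep]
      }
      acc <- acc + w * mean(cand == t) / 12
      for (f in c("voicing", "manner", "place")) {
        fv <- setNames(sch[[f]], cons)
        tr[f] <- tr[f] + w * mean(fv[cand] == fv[t]) / 12
      }
    }
  }
  c(accuracy = acc, tr)
}

# Tiny trial-table fixture: one complete block per condition cell.
make_block_trials <- function(subject = "CNH01", group = "CNH",
                              modality = "AO", mask = "none",
                              responses = NULL) {
  targets <- rep(masksim::consonants(), each = 3)
  if (is.null(responses)) responses <- targets
  tibble::tibble(
    subject_id = subject, group = group, age = 12, modality = modality,
    mask = mask, snr_db = 0, run = 1L,
    token = rep(1:3, times = 12), target = targets, response = responses
  )
}
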