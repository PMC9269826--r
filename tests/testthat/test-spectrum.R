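# FFT magnitude spectra, cardiac bandpass, peak detection, SNR scoring
# and best-candidate selection.

tone <- function(freq, fs = 30, dur = 15, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t)
}

test_that("magnitude spectrum localises tones to one bin", {
  fs <- 30
  s <- magnitude_spectrum(tone(1.2, fs), fs)
  expect_equal(s$frequencies[which.max(s$magnitudes)], 1.2,
               tolerance = fs / length(tone(1.2, fs)))
  flat <- magnitude_spectrum(rep(4, 64), fs)
  expect_true(all(flat$magnitudes[-1] < 1e-9))
  # equal-amplitude tones at 1 and 2 Hz give equal-height maxima
  two <- magnitude_spectrum(tone(1) + tone(2), fs)
  i1 <- which.min(abs(two$frequencies - 1))
  i2 <- which.min(abs(two$frequencies - 2))
  expect_equal(two$magnitudes[i1], two$magnitudes[i2], tolerance = 0.01)
  expect_error(magnitude_spectrum(tone(1), -1), "positive")
})

test_that("bandpass zeroes out-of-band magnitudes and is idempotent", {
  fs <- 30
  # 0.4 Hz sits on an exact bin (6/15), so no leakage survives the mask
  low <- bandpass(magnitude_spectrum(tone(0.4), fs))
  expect_true(all(low$magnitudes < 1e-9))
  inband <- magnitude_spectrum(tone(1.2), fs)
  pk_before <- max(inband$magnitudes)
  bp <- bandpass(inband)
  expect_equal(max(bp$magnitudes), pk_before)
  both <- bandpass(magnitude_spectrum(tone(0.4) + tone(1.2), fs))
  surviving <- both$frequencies[both$magnitudes > 0.05 *
                                  max(both$magnitudes)]
  expect_true(all(abs(surviving - 1.2) < 0.2))
  expect_equal(bandpass(bp)$magnitudes, bp$magnitudes)
})

test_that("dominant peak picks maxima and breaks ties toward low frequency", {
  fs <- 30
  pk <- dominant_peak(bandpass(magnitude_spectrum(tone(1.2), fs)))
  expect_equal(pk$frequency, 1.2, tolerance = 1 / 15)

  spec <- structure(list(frequencies = seq(0, 3, by = 0.1),
                         magnitudes = rep(0, 31), fs = 10, n = 62,
                         band = NULL),
                    class = "rppg_spectrum")
  spec$magnitudes[c(10, 20)] <- c(5, 3)
  expect_equal(dominant_peak(spec)$frequency, spec$frequencies[10])
  spec$magnitudes[c(10, 20)] <- c(4, 4)      # plateau-like tie
  expect_equal(dominant_peak(spec)$frequency, spec$frequencies[10])
  spec$magnitudes[] <- 0
  expect_error(dominant_peak(spec), class = "rppg_no_peak_error")
})

test_that("SNR is peak over in-band mean, scale-invariant and monotone", {
  spec <- structure(list(frequencies = seq(0.7, 3.3, length.out = 10),
                         magnitudes = rep(2, 10), fs = 10, n = 20,
                         band = c(0.66, 3.33)),
                    class = "rppg_spectrum")
  expect_equal(snr(spec, 10), 5)
  expect_equal(snr(spec, 2), 1)              # flat spectrum
  spec2 <- spec
  spec2$magnitudes <- spec$magnitudes * 3
  expect_equal(snr(spec2, 30), snr(spec, 10))
  # doubling the tone amplitude strictly increases SNR under fixed noise
  set.seed(6)
  noise <- rnorm(450, 0, 0.5)
  fs <- 30
  s1 <- bandpass(magnitude_spectrum(tone(1.2) + noise, fs))
  s2 <- bandpass(magnitude_spectrum(tone(1.2, amp = 2) + noise, fs))
  expect_gt(snr(s2, dominant_peak(s2)$magnitude),
            snr(s1, dominant_peak(s1)$magnitude))
})

test_that("frequency-to-BPM conversion matches the passband labels", {
  expect_equal(hr_bpm(1.2), 72)
  expect_equal(hr_bpm(0.66), 39.6)
  expect_identical(floor(hr_bpm(0.66)), 39)
  expect_equal(hr_bpm(3.33), 199.8)
  expect_identical(round(hr_bpm(3.33)), 200)
})

test_that("best-candidate selection maximises SNR across regions and channels", {
  mk <- function(region, prov, snr) {
    vital_candidate(region, prov, 1.2, 10, snr)
  }
  cands <- list(mk("forehead", "R", 2), mk("lips", "G", 7),
                mk("forehead", "B", 5))
  expect_equal(select_best(cands)$snr, 7)
  expect_equal(select_best(cands[2])$region, "lips")
  expect_error(select_best(list()), class = "rppg_no_candidate_error")

  # 25 candidates (5 regions x 5 channels): an injected strong tone wins
  fs <- 30
  set.seed(10)
  cands <- list()
  for (rg in c("forehead", "right_cheek", "left_cheek", "cheeks_nose",
               "lips")) {
    for (ch in c("R", "G", "B", "Gy", "IR")) {
      sig <- rnorm(450, 0, 1)
      if (rg == "cheeks_nose" && ch == "G") sig <- sig + tone(1.5, amp = 8)
      sp <- bandpass(magnitude_spectrum(sig, fs))
      pk <- dominant_peak(sp)
      cands[[length(cands) + 1L]] <-
        vital_candidate(rg, ch, pk$frequency, pk$magnitude,
                        snr(sp, pk$magnitude))
    }
  }
  best <- select_best(cands)
  expect_equal(best$region, "cheeks_nose")
  expect_equal(best$provenance, "G")
  expect_equal(best$hr_bpm, 90, tolerance = 4)
})

test_that("the full chain recovers a noiseless tone within one bin width", {
  fs <- 30
  for (f in c(0.8, 1.2, 2.5)) {
    sig <- tone(f, fs)
    sp <- bandpass(magnitude_spectrum(sig, fs))
    pk <- dominant_peak(sp)
    expect_lte(abs(hr_bpm(pk$frequency) - 60 * f),
               60 * fs / length(sig))
  }
})
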