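test_that("rms and dB conversions follow the 20 uPa reference", {
  t <- (0:47999) / 48000
  expect_equal(rms(audio_clip(sin(2 * pi * 440 * t), 48000)), 1 / sqrt(2),
               tolerance = 1e-6)
  expect_equal(to_db_spl(20e-6), 0)
  expect_equal(to_db_spl(0.02), 60)
  expect_equal(db_to_pa(to_db_spl(0.004)), 0.004)
  expect_error(to_db_spl(0), "positive")
  expect_error(to_db_spl(-1), "positive")
})

test_that("noise-subtracted rms follows the mean-square subtraction rule", {
  clip <- audio_clip(rep(sqrt(5e-6), 100), 48000)  # mean square 5e-6 Pa^2
  r <- noise_subtracted_rms(clip, 1e-6)
  expect_equal(r$pa, 2e-3)
  expect_true(r$reliable)
  # zero noise: identity with plain rms
  expect_equal(noise_subtracted_rms(clip, 0)$pa, rms(clip))
  # over-subtraction is flagged and floored, never an exception
  r2 <- noise_subtracted_rms(clip, 1e-5)
  expect_false(r2$reliable)
  expect_gt(r2$pa, 0)
  expect_error(noise_subtracted_rms(clip, -1), "non-negative")
})

test_that("trial source level averages pressures before the dB transform", {
  expect_equal(trial_source_level(c(0.01, 0.03)), 20 * log10(0.02 / 20e-6))
  expect_equal(trial_source_level(rep(0.004, 5)), to_db_spl(0.004))
  expect_error(trial_source_level(numeric()), "no calls")
  # Jensen: linear-domain mean >= dB-domain mean
  set.seed(5)
  for (i in 1:20) {
    p <- exp(rnorm(8, log(0.01), 0.8))
    expect_gte(trial_source_level(p) + 1e-12, mean(to_db_spl(p)))
  }
})

test_that("averaged PSD has the published resolution and is calibrated", {
  psd <- tone_psd(2000)
  expect_equal(psd$df, 11.71875)        # 48000 / 4096, prints as 11.7
  expect_lt(abs(psd$freqs[which.max(psd$power)] - 2000), psd$df + 1e-9)
  # white-noise Parseval within 2%
  set.seed(2)
  clip <- audio_clip(rnorm(48000 * 2) * 0.01, 48000)
  psd2 <- averaged_psd(clip)
  expect_equal(sum(psd2$power) * psd2$df, mean(clip$samples^2),
               tolerance = 0.02)
  expect_warning(averaged_psd(audio_clip(rnorm(100), 48000)), "shorter")
})

test_that("noise-spectrum subtraction is exact on matching grids", {
  set.seed(3)
  noise <- audio_clip(rnorm(48000), 48000)
  p1 <- averaged_psd(noise)
  # equal spectra -> floored output
  flo <- subtract_psd(p1, p1)
  expect_true(all(flo$power <= 1e-12 * max(p1$power) + 1e-30))
  # zero noise -> identity
  zero <- p1; zero$power <- 0 * zero$power
  expect_equal(subtract_psd(p1, zero)$power, p1$power)
  # grid mismatch -> error
  p2 <- averaged_psd(noise, dft_len = 8192)
  expect_error(subtract_psd(p1, p2), "grids differ")
  # tone + known noise bed: tone-bin density recovered within 10%
  t <- (0:(2 * 48000 - 1)) / 48000
  tone <- 0.05 * sin(2 * pi * 3000 * t)
  bed <- band_limited_noise("D", 2, seed = 4)
  clean <- averaged_psd(audio_clip(tone, 48000))
  noisy <- averaged_psd(audio_clip(tone + bed$samples, 48000))
  sub <- subtract_psd(noisy, averaged_psd(bed))
  i <- which.max(clean$power)
  expect_equal(sub$power[i], clean$power[i], tolerance = 0.1)
})

test_that("harmonic peaks are found at k*f0 and absent peaks are omitted", {
  psd <- tone_psd(c(1500, 3000, 4500), c(1, 0.7, 0.4))
  pk <- harmonic_peaks(psd, 1500, 5)
  expect_equal(pk$k, 1:3)
  expect_lt(max(abs(pk$freq_hz - c(1500, 3000, 4500))), psd$df + 1e-9)
  # pure tone: only the fundamental is returned
  pure <- tone_psd(2000)
  expect_equal(harmonic_peaks(pure, 2000, 3)$k, 1L)
  # tolerance property: a 10% off f0 estimate recovers the same peaks
  pk2 <- harmonic_peaks(psd, 1500 * 1.1, 3)
  expect_equal(pk2$freq_hz, pk$freq_hz[1:3])
  expect_error(harmonic_peaks(tone_psd(400), 6000, 2), "no fundamental")
})

test_that("tilt ratio compares harmonic k with the fundamental", {
  psd <- tone_psd(c(1500, 4500), c(1, 1), dur = 2)
  pk <- harmonic_peaks(psd, 1500, 3)
  expect_equal(tilt_ratio(pk, 3), 1.0, tolerance = 0.05)
  expect_equal(tilt_ratio(pk, 3, type = "density"), 1.0, tolerance = 0.05)
  missing <- tilt_ratio(pk, 2)
  expect_true(is.na(missing))
  expect_match(attr(missing, "reason"), "harmonic 2")
})

test_that("spectrum extrema order correctly and respond to edge_db", {
  # pure tone: edges within the -24 dB mainlobe half-width (~6 bins)
  psd <- tone_psd(2000)
  ex <- spectrum_extrema(psd)
  expect_lte(ex["min_hz"], ex["peak_hz"])
  expect_lte(ex["peak_hz"], ex["max_hz"])
  expect_lt(abs(ex["peak_hz"] - 2000), 2 * psd$df)
  expect_lt(abs(ex["min_hz"] - 2000), 7 * psd$df)
  expect_lt(abs(ex["max_hz"] - 2000), 7 * psd$df)
  # two equal tones bracket the support
  ex2 <- spectrum_extrema(tone_psd(c(2000, 6000), c(1, 1)))
  expect_equal(unname(ex2["min_hz"]), 2000, tolerance = 0.05)
  expect_equal(unname(ex2["max_hz"]), 6000, tolerance = 0.05)
  # widening the edge threshold widens the interval monotonically
  e24 <- spectrum_extrema(psd, edge_db = 24)
  e40 <- spectrum_extrema(psd, edge_db = 40)
  expect_lte(e40["min_hz"], e24["min_hz"])
  expect_gte(e40["max_hz"], e24["max_hz"])
  flat <- psd; flat$power <- rep(1, length(flat$power))
  expect_error(spectrum_extrema(flat), "flat")
})

test_that("fundamental contour tracking recovers constant tones and sweeps", {
  # constant 1600 Hz fundamental
  syl <- syllable_spec("whistle", 0.4, 1600, 1600, c(1), 70)
  clip <- synth_syllable(syl)
  f0 <- f0_measures(clip, c(1100, 2750))
  expect_lt(abs(f0$f0_peak_hz - 1600), 2 * 11.71875)
  expect_lt(abs(f0$f0_start_hz - 1600), 2 * 11.71875)
  expect_lt(abs(f0$f0_end_hz - 1600), 2 * 11.71875)
  # linear sweep endpoints within 2 bins
  syl2 <- syllable_spec("whistle", 0.4, 1500, 2500, c(1), 70)
  f02 <- f0_measures(synth_syllable(syl2), c(1100, 2750))
  expect_lt(abs(f02$f0_start_hz - 1500), 2 * 11.71875)
  expect_lt(abs(f02$f0_end_hz - 2500), 2 * 11.71875)
})

test_that("durations separate whole-call and syllable time", {
  ann <- list(call_id = "c", call_type = "CLC", onset = 0, offset = 0.25,
              syllables = data.frame(type = c("whistle", "whistle"),
                                     onset = c(0, 0.15),
                                     offset = c(0.1, 0.25)))
  d <- durations(ann)
  expect_equal(d$whole_s, 0.25)
  expect_equal(d$per_syllable_s, c(0.1, 0.1))
  expect_equal(d$whole_s - sum(d$per_syllable_s), 0.05)  # the pause
  # chirp annotation at the published mean duration
  ann2 <- list(call_id = "c2", call_type = "chirp", onset = 1,
               offset = 1.0537, syllables = data.frame())
  expect_equal(durations(ann2)$whole_s, 0.0537)
})

test_that("trial noise level uses the first call-free 5 s window", {
  set.seed(9)
  bed <- set_level_db(audio_clip(rnorm(12 * 48000), 48000), 54)
  none <- data.frame(onset_s = numeric(), offset_s = numeric())
  expect_equal(trial_noise_level(bed, none), 54, tolerance = 0.25)
  # a call in the first window pushes the measurement later
  ann <- data.frame(onset_s = 2, offset_s = 4.5)
  ns <- trial_noise_stats(bed, ann)
  expect_gte(ns$window[1], 4.5)
  expect_equal(ns$level_db, 54, tolerance = 0.25)
  # trial shorter than the window errors
  expect_error(trial_noise_level(slice_clip(bed, 0, 3), none), "shorter")
  # fully occupied trial: no clean window
  busy <- data.frame(onset_s = seq(0, 11, by = 1), offset_s = seq(0.9, 11.9, by = 1))
  expect_error(trial_noise_stats(bed, busy), "no call-free window")
})
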