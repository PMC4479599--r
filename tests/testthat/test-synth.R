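test_that("syllable synthesis places harmonics where specified", {
  # pure constant tone
  syl <- syllable_spec("whistle", 0.5, 2000, 2000, c(1), 70)
  psd <- averaged_psd(synth_syllable(syl))
  expect_lt(abs(psd$freqs[which.max(psd$power)] - 2000), psd$df + 1e-9)
  # power weights map to PSD density ratios for constant f0
  syl2 <- syllable_spec("whistle", 0.5, 2000, 2000, c(1, 2.5), 70)
  pk <- harmonic_peaks(averaged_psd(synth_syllable(syl2)), 2000, 2)
  expect_equal(tilt_ratio(pk, 2, type = "density"), 2.5, tolerance = 0.1)
  expect_equal(tilt_ratio(pk, 2), 2.5, tolerance = 0.1)
  # the default chirp duration renders to the expected sample count
  chirp <- chirp_call_spec()
  clip <- synth_syllable(chirp$syllables[[1]])
  expect_lte(abs(length(clip$samples) - 2578), 1)  # 53.7 ms at 48 kHz
  # syllable level is exact after ramping
  expect_equal(to_db_spl(rms(clip)), 75, tolerance = 1e-9)
})

test_that("aliased harmonics are dropped with a warning", {
  syl <- syllable_spec("chirp", 0.1, 9000, 13000, c(1, 1), 75)
  expect_warning(clip <- synth_syllable(syl), "aliased")
  psd <- averaged_psd(clip)
  # where the dropped harmonic 2 would fold back (22-24 kHz) there is only
  # the fundamental's leakage skirt left
  expect_lt(sum(psd$power[psd$freqs > 20000]) / sum(psd$power), 1e-5)
  expect_error(synth_syllable(
    syllable_spec("chirp", 0.1, 25000, 25000, c(1), 70)), "Nyquist")
})

test_that("call assembly matches annotations sample-exactly", {
  spec <- clc_spec()
  sc <- synth_call(spec, 48000, "c1")
  expect_equal(nrow(sc$annotation$syllables), 5)  # 1 chirp + 4 whistles
  d <- durations(sc$annotation)
  expect_equal(d$whole_s, clip_duration(sc$clip))
  # whole-call duration = syllables + pauses exactly (in samples)
  expect_equal(d$whole_s - sum(d$per_syllable_s), sum(round(spec$pauses_s * 48000)) / 48000)
  # zero pauses: whole call equals the syllable sum
  spec0 <- clc_spec(pause_s = 0)
  d0 <- durations(synth_call(spec0)$annotation)
  expect_equal(d0$whole_s, sum(d0$per_syllable_s))
})

test_that("call_spec enforces structural invariants", {
  s <- syllable_spec("chirp", 0.05, 9000, 10000, c(1), 75)
  expect_error(call_spec("chirp", list(s, s)), "single syllable")
  expect_error(call_spec("CLC", list(s)), "at least two")
  expect_error(call_spec("CLC", list(s, s), numeric()), "one pause")
  expect_error(syllable_spec("whistle", 0.2, 1600, 1900, c(0, 1), 70))
})

test_that("the response model transforms specs as advertised", {
  base <- clc_spec()
  model <- default_response_model()
  # identity at zero noise excess
  expect_identical(apply_response(base, 0, "narrow", model), base)
  # lombard arithmetic: 0.5 dB/dB at delta 22 -> +11 dB
  up <- apply_response(base, 22, "narrow", response_model(lombard_slope = 0.5))
  expect_equal(up$syllables[[2]]$level_db - base$syllables[[2]]$level_db, 11)
  # broadband interaction adds slope
  upb <- apply_response(base, 10, "broad",
                        response_model(lombard_slope = 0.5,
                                       lombard_bw_interaction = 0.1))
  expect_equal(upb$syllables[[2]]$level_db - base$syllables[[2]]$level_db, 6)
  # minimum-fundamental shift signs differ by bandwidth
  m <- response_model(min_f0_bw_shift_hz = 60)
  dn <- apply_response(base, 10, "narrow", m)$syllables[[2]]
  db <- apply_response(base, 10, "broad", m)$syllables[[2]]
  expect_equal(min(dn$f0_start_hz, dn$f0_end_hz), 1660)
  expect_equal(min(db$f0_start_hz, db$f0_end_hz), 1540)
  # chirp duration slope in ms/dB
  ch <- apply_response(chirp_call_spec(), 20, "narrow",
                       response_model(duration_slope_ms_per_db = 0.45))
  expect_equal(ch$syllables[[1]]$duration_s, 0.0537 + 0.009)
  # tilt: harmonic-3 energy ratio rises by tilt_slope * delta
  tl <- apply_response(base, 22, "narrow",
                       response_model(tilt_slope_per_db = 0.1))$syllables[[2]]
  w <- tl$harmonic_weights
  expect_equal(w[3] / w[1], 0.8 + 2.2)
})

test_that("programmed tilt changes are recovered end to end", {
  # drive the harmonic-2 energy ratio from 2.5 to 6 and measure it back
  base <- clc_spec()
  w <- base$syllables[[2]]$harmonic_weights
  slope <- (6 - 2.5) / 22 * (w[3] / w[1]) / (w[2] / w[1])  # scale via h3 target
  shifted <- apply_response(base, 22, "narrow",
                            response_model(tilt_slope_per_db = slope))
  res <- measure_injected(shifted, seed = 21)
  w2 <- shifted$syllables[[2]]$harmonic_weights
  expect_equal(w2[2] / w2[1], 6, tolerance = 1e-6)
  # measured harmonic-2 energy ratio of the generated call
  psd <- subtract_psd(averaged_psd(slice_clip(res$trial, res$ann$syllables$onset[2],
                                              res$ann$syllables$offset[2])),
                      res$ns$psd)
  pk <- harmonic_peaks(psd, 1750, 3)
  expect_equal(tilt_ratio(pk, 2), 6, tolerance = 0.15)
})

test_that("simulated experiments are deterministic and correctly sized", {
  cfg <- default_sim_config(seed = 5)
  sim1 <- simulate_experiment(cfg, render_audio = FALSE)
  sim2 <- simulate_experiment(cfg, render_audio = FALSE)
  expect_equal(nrow(sim1$manifest), 36)  # 3 subjects x 12 trials
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$annotations, sim2$annotations)
  # each subject sees each treatment exactly once
  trt <- sim1$manifest[sim1$manifest$trial_type == "treatment", ]
  for (s in unique(trt$subject))
    expect_setequal(trt$treatment[trt$subject == s], LETTERS[1:6])
  # control trials pair each session
  expect_equal(sum(sim1$manifest$trial_type == "control"), 18)
  # placement respects the noise window and separation rules
  expect_true(all(sim1$truth$start_s >= 6))
})

test_that("overcrowded trials fail loudly instead of overlapping calls", {
  cfg <- default_sim_config(clc_rate = 40, trial_s = 20, seed = 2)
  expect_error(simulate_experiment(cfg, render_audio = FALSE),
               "call density too high")
})

test_that("increasing the Lombard slope increases treatment source levels", {
  slopes <- c(0.1, 0.5)
  means <- vapply(slopes, function(sl) {
    cfg <- default_sim_config(model = response_model(lombard_slope = sl),
                              chirp_rate = 0, seed = 33)
    tr <- simulate_experiment(cfg, render_audio = FALSE)$truth
    mean(tr$level_db[tr$trial_type == "treatment" & tr$call_type == "CLC"])
  }, numeric(1))
  expect_gt(means[2], means[1])
})
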