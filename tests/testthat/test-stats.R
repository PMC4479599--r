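make_summaries <- function(seed = 1, model = default_response_model(), ...) {
  cfg <- default_sim_config(model = model, seed = seed, ...)
  sim <- simulate_experiment(cfg, render_audio = FALSE)
  aggregate_trials(truth_to_measurements(sim$truth), sim$manifest)
}

test_that("aggregation follows the trial-mean conventions", {
  manifest <- data.frame(subject = "s1", session = 1,
                         trial_type = c("treatment", "control"),
                         treatment = c("A", "none"),
                         wav_path = c("a.wav", "c.wav"), calibration = 1,
                         stringsAsFactors = FALSE)
  meas <- data.frame(wav_path = "a.wav", call_id = paste0("c", 1:3),
                     call_type = "CLC",
                     source_level_db = to_db_spl(c(0.01, 0.02, 0.03)),
                     level_reliable = TRUE, duration_s = 2,
                     syl_mean_dur_s = 0.3, n_syllables = 5L, min_hz = 1500,
                     peak_hz = 3500, max_hz = 15000, f0_min_hz = 1600,
                     f0_peak_hz = 1750, f0_start_hz = NA, f0_end_hz = NA,
                     tilt_ratio = 2.5, tilt_k = 3L, whistle_level_db = 70,
                     whistle_peak_hz = 3500, trial_noise_db = 64,
                     stringsAsFactors = FALSE)
  s <- aggregate_trials(meas, manifest)
  expect_equal(nrow(s), 2)
  # linear-pressure mean, then dB: mean(0.01, 0.02, 0.03) = 0.02 Pa = 60 dB
  expect_equal(s$clc_source_level_db[s$trial_type == "treatment"], 60)
  # the no-call control trial keeps missing cells, never zeros
  expect_true(is.na(s$clc_source_level_db[s$trial_type == "control"]))
  expect_true(is.na(s$chirp_source_level_db[s$trial_type == "treatment"]))
  # control trial inherits its session's bandwidth class
  expect_equal(s$bandwidth_class, c("narrow", "narrow"))
  # orphan calls are an error
  meas$wav_path[1] <- "zz.wav"
  expect_error(aggregate_trials(meas, manifest), "unknown trials")
})

test_that("a complete 3 x 12 design yields denominator df 30 on every term", {
  # high call rate so every trial has CLCs; long trials keep placement easy
  s <- make_summaries(seed = 4, clc_rate = 15, chirp_rate = 0, trial_s = 240)
  expect_equal(sum(!is.na(s$clc_source_level_db)), 36)
  for (resp in c("clc_source_level_db", "clc_tilt", "clc_duration_s")) {
    f <- fit_ancova(s, resp)
    expect_equal(f$terms$df2, rep(30L, 3))
    expect_equal(f$terms$df1, rep(1L, 3))
    expect_true(all(f$terms$F >= 0))
    expect_true(all(f$terms$p >= 0 & f$terms$p <= 1))
  }
})

test_that("missing cells reduce the denominator df (realized design)", {
  s <- make_summaries(seed = 8, clc_rate = 1, chirp_rate = 0)
  n_obs <- sum(!is.na(s$clc_source_level_db) & !is.na(s$noise_db))
  expect_lt(n_obs, 36)
  f <- fit_ancova(s, "clc_source_level_db")
  expect_equal(unique(f$terms$df2), n_obs - 6L)
})

test_that("with zero subject variance the mixed F matches the OLS oracle", {
  # data built from fixed effects only; subjects carry no shift
  set.seed(10)
  d <- expand.grid(subject = c("s1", "s2", "s3"), session = 1:6,
                   trial_type = c("control", "treatment"),
                   stringsAsFactors = FALSE)
  d$bandwidth_class <- rep(rep(c("narrow", "broad"), each = 3), length.out = nrow(d))
  d$noise_db <- ifelse(d$trial_type == "control", 42,
                       rep(c(44, 54, 64), length.out = nrow(d)))
  d$treatment <- ifelse(d$trial_type == "treatment", "A", "none")
  r <- rnorm(nrow(d), 0, 1)
  r <- r - ave(r, d$subject)  # residuals orthogonal to subjects: the REML
                              # subject variance sits exactly at the 0 boundary
  d$y <- 70 + 0.3 * d$noise_db + 2 * (d$bandwidth_class == "broad") + r
  f <- fit_ancova(d, "y")
  # brute-force OLS ANCOVA with identical coding
  d$nl_c <- d$noise_db - mean(d$noise_db)
  d$bw <- factor(d$bandwidth_class, levels = c("narrow", "broad"))
  contrasts(d$bw) <- contr.sum(2)
  ols <- lm(y ~ nl_c * bw, data = d)
  tt <- summary(ols)$coefficients[2:4, "t value"]
  expect_equal(f$terms$F, unname(tt^2), tolerance = 1e-6)
})

test_that("degenerate designs raise errors naming the aliased term", {
  s <- make_summaries(seed = 12, chirp_rate = 0)
  one_sub <- s[s$subject == "s1", ]
  expect_error(fit_ancova(one_sub, "clc_source_level_db"), "2 subjects")
  narrow_only <- s[s$bandwidth_class == "narrow", ]
  expect_error(fit_ancova(narrow_only, "clc_source_level_db"), "bandwidth")
  flat <- s; flat$noise_db <- 42
  expect_error(fit_ancova(flat, "clc_source_level_db"), "noise")
  expect_error(fit_ancova(s, "nope"), "unknown response")
})

test_that("type-I error of the noise-level term is calibrated", {
  rej <- vapply(1:60, function(i) {
    s <- make_summaries(seed = 1000 + i, model = zero_response_model(),
                        chirp_rate = 0)
    fit_ancova(s, "clc_source_level_db")$terms$p[1] < 0.05
  }, logical(1))
  # binomial 95% band around 0.05 for 60 replicates
  expect_lte(mean(rej), 0.15)
})

test_that("the programmed Lombard slope is recovered without bias", {
  sl <- vapply(1:25, function(i) {
    s <- make_summaries(seed = 2000 + i,
                        model = response_model(lombard_slope = 0.4),
                        chirp_rate = 0)
    fit_ancova(s, "clc_source_level_db")$slope
  }, numeric(1))
  expect_equal(mean(sl), 0.4, tolerance = 0.125)  # 0.05 absolute
})

test_that("delta tables difference paired control/treatment trials", {
  s <- make_summaries(seed = 31, clc_rate = 10, trial_s = 120, chirp_rate = 0)
  dt <- delta_table(s, "clc_f0_min_hz")
  expect_equal(nrow(dt), 18)  # 3 subjects x 6 treatments
  expect_true(all(dt$delta == round(dt$treatment_value - dt$control_value)))
  # broadband shifts are negative, narrowband non-negative by construction
  bank <- treatment_bank()
  bw <- bank$bandwidth_class[match(dt$treatment, bank$name)]
  expect_true(mean(dt$delta[bw == "broad"] < 0) > 0.7)
  expect_true(mean(dt$delta[bw == "narrow"] > 0) > 0.7)
  # identical control/treatment values give a zero delta
  s2 <- s
  s2$clc_f0_min_hz <- 1500
  dt2 <- delta_table(s2, "clc_f0_min_hz")
  expect_true(all(dt2$delta == 0))
})

test_that("reports are deterministic and ordered like the results grid", {
  s <- make_summaries(seed = 41)
  fits <- list(fit_ancova(s, "chirp_duration_s"),
               fit_ancova(s, "clc_source_level_db"),
               fit_ancova(s, "clc_tilt"))
  rp1 <- ancova_report(fits)
  rp2 <- ancova_report(rev(fits))
  expect_identical(rp1$text, rp2$text)  # order is canonical, not input order
  expect_equal(unique(rp1$table$label)[1], "Source level (whole call)")
  expect_equal(nrow(rp1$table), 9)  # 3 responses x 3 terms
  # p-values are formatted to two decimals with a significance flag
  expect_match(rp1$text[2], "\\d+\\.\\d{2}")
  expect_true(any(grepl("\\*", rp1$text)))
})
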