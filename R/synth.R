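## Synthetic vocalization generator: harmonic-stack syllables with linear
## fundamental sweeps, combination long calls (CLCs, one chirp + four whistle
## syllables) and short chirps, a parameterized noise-response model, and a
## seeded end-to-end experiment simulator providing ground truth for every
## measurement and statistic.

#' Syllable specification
#'
#' A syllable is an additive harmonic stack over a linearly swept fundamental.
#' `harmonic_weights` are relative *power* weights per harmonic 1..K (so the
#' energy ratio of harmonic k to the fundamental is `w[k]/w[1]`); amplitudes
#' are their square roots.
#'
#' @param type `"chirp"` or `"whistle"`.
#' @param duration_s Syllable duration, seconds.
#' @param f0_start_hz,f0_end_hz Fundamental contour endpoints (linear sweep).
#' @param harmonic_weights Non-negative power weights, `weights[1] > 0`.
#' @param level_db Syllable rms level, dB re 20 uPa.
#' @return An object of class `syllable_spec`.
#' @export
syllable_spec <- function(type, duration_s, f0_start_hz, f0_end_hz,
                          harmonic_weights, level_db) {
  type <- match.arg(type, c("chirp", "whistle"))
  stopifnot(duration_s > 0, f0_start_hz > 0, f0_end_hz > 0,
            length(harmonic_weights) >= 1, all(harmonic_weights >= 0),
            harmonic_weights[1] > 0, is.finite(level_db))
  structure(list(type = type, duration_s = duration_s,
                 f0_start_hz = f0_start_hz, f0_end_hz = f0_end_hz,
                 harmonic_weights = harmonic_weights, level_db = level_db),
            class = "syllable_spec")
}

#' Call specification
#'
#' @param call_type `"CLC"` or `"chirp"`. A chirp call holds exactly one
#'   chirp syllable and no pauses; a CLC holds two or more syllables with
#'   `length(syllables) - 1` inter-syllable pauses.
#' @param syllables List of [syllable_spec()] objects.
#' @param pauses_s Numeric vector of inter-syllable gaps, seconds.
#' @return An object of class `call_spec`.
#' @export
call_spec <- function(call_type, syllables, pauses_s = numeric()) {
  call_type <- match.arg(call_type, c("CLC", "chirp"))
  stopifnot(all(vapply(syllables, inherits, logical(1), "syllable_spec")))
  if (call_type == "chirp") {
    if (length(syllables) != 1L || length(pauses_s))
      stop("a chirp call is a single syllable with no pauses")
  } else {
    if (length(syllables) < 2L)
      stop("a CLC needs at least two syllables")
    if (length(pauses_s) != length(syllables) - 1L)
      stop("a CLC needs one pause per adjacent syllable pair")
    if (any(pauses_s < 0)) stop("pauses must be non-negative")
  }
  structure(list(call_type = call_type, syllables = syllables,
                 pauses_s = as.numeric(pauses_s)), class = "call_spec")
}

#' Default combination long call: one chirp plus four whistle syllables
#'
#' The whistle fundamental is a mild upsweep within the species' 1.5--2.5 kHz
#' baseline range; control harmonic power weights put 2--3 times the
#' fundamental's energy in the second harmonic. The leading chirp syllable
#' sweeps well above the whistle band.
#'
#' @param whistle_f0 Length-2: whistle fundamental sweep endpoints, Hz.
#' @param whistle_dur Whistle syllable duration, s.
#' @param whistle_weights Whistle harmonic power weights.
#' @param chirp_f0,chirp_dur,chirp_weights Leading chirp syllable parameters.
#' @param level_db Per-syllable rms level, dB re 20 uPa.
#' @param n_whistles Number of whistle syllables.
#' @param pause_s Inter-syllable pause, s.
#' @return A [call_spec()] of type `"CLC"`.
#' @export
clc_spec <- function(whistle_f0 = c(1600, 1900), whistle_dur = 0.35,
                     whistle_weights = c(1, 2.5, 0.8, 0.35, 0.15, 0.06,
                                         0.025, 0.01),
                     chirp_f0 = c(8500, 10500), chirp_dur = 0.055,
                     chirp_weights = c(1, 0.5), level_db = 70,
                     n_whistles = 4, pause_s = 0.15) {
  syl <- c(list(syllable_spec("chirp", chirp_dur, chirp_f0[1], chirp_f0[2],
                              chirp_weights, level_db)),
           replicate(n_whistles,
                     syllable_spec("whistle", whistle_dur, whistle_f0[1],
                                   whistle_f0[2], whistle_weights, level_db),
                     simplify = FALSE))
  call_spec("CLC", syl, rep(pause_s, n_whistles))
}

#' Default short chirp call
#'
#' A single high-fundamental upsweep. The default duration is the 53.7 ms
#' control mean of one study subject; the sweep tops out at 10.5 kHz so the
#' second harmonic stays below the 24 kHz Nyquist limit and the chirp tilt
#' ratio (harmonic 2 / fundamental) remains measurable.
#'
#' @param f0 Length-2 sweep endpoints, Hz.
#' @param duration_s Duration, s.
#' @param weights Harmonic power weights.
#' @param level_db rms level, dB re 20 uPa.
#' @return A [call_spec()] of type `"chirp"`.
#' @export
chirp_call_spec <- function(f0 = c(8500, 10500), duration_s = 0.0537,
                            weights = c(1, 0.5), level_db = 75) {
  call_spec("chirp", list(syllable_spec("chirp", duration_s, f0[1], f0[2],
                                        weights, level_db)))
}

## ---- Noise-response model --------------------------------------------------

#' Parameterized noise-response model
#'
#' Generator-side effect sizes applied to a baseline call when the subject is
#' exposed to noise `delta_db` above ambient. The measurement and statistics
#' modules must recover these effects.
#'
#' @param lombard_slope dB of call level per dB of noise above ambient
#'   (applied to every syllable of both call types).
#' @param lombard_bw_interaction Extra level slope under broadband noise.
#' @param duration_slope_ms_per_db Chirp-call duration increase, ms/dB
#'   (CLC durations are unaffected).
#' @param peak_f0_slope_hz_per_db Upward shift of the upper fundamental
#'   endpoint, Hz/dB (whistle syllables and chirp calls).
#' @param min_f0_bw_shift_hz Magnitude of the shift of the whistle minimum
#'   fundamental: non-negative under narrowband noise, negative under
#'   broadband (chirp minima are unaffected).
#' @param tilt_slope_per_db Increase per dB in the whistle harmonic-3 to
#'   fundamental energy ratio (chirp tilt is unaffected).
#' @return An object of class `response_model`.
#' @export
response_model <- function(lombard_slope = 0, lombard_bw_interaction = 0,
                           duration_slope_ms_per_db = 0,
                           peak_f0_slope_hz_per_db = 0,
                           min_f0_bw_shift_hz = 0, tilt_slope_per_db = 0) {
  vals <- c(lombard_slope, lombard_bw_interaction, duration_slope_ms_per_db,
            peak_f0_slope_hz_per_db, min_f0_bw_shift_hz, tilt_slope_per_db)
  stopifnot(all(is.finite(vals)))
  structure(list(lombard_slope = lombard_slope,
                 lombard_bw_interaction = lombard_bw_interaction,
                 duration_slope_ms_per_db = duration_slope_ms_per_db,
                 peak_f0_slope_hz_per_db = peak_f0_slope_hz_per_db,
                 min_f0_bw_shift_hz = min_f0_bw_shift_hz,
                 tilt_slope_per_db = tilt_slope_per_db),
            class = "response_model")
}

#' Zero response model: no reaction to noise
#' @return A [response_model()] with every slope zero.
#' @export
zero_response_model <- function() response_model()

#' Default response model emulating a strong noise response
#'
#' Effect directions follow the study findings: a Lombard effect slightly
#' stronger in broadband noise, longer chirps, upward peak-fundamental
#' shifts, bandwidth-dependent minimum-fundamental shifts, and decreased
#' spectral tilt (more high-harmonic energy) in CLCs.
#'
#' @return A [response_model()].
#' @export
default_response_model <- function()
  response_model(lombard_slope = 0.5, lombard_bw_interaction = 0.05,
                 duration_slope_ms_per_db = 0.45,
                 peak_f0_slope_hz_per_db = 5, min_f0_bw_shift_hz = 60,
                 tilt_slope_per_db = 0.12)

f0_hi_idx <- function(s) if (s$f0_end_hz >= s$f0_start_hz) "f0_end_hz" else "f0_start_hz"
f0_lo_idx <- function(s) if (s$f0_end_hz >= s$f0_start_hz) "f0_start_hz" else "f0_end_hz"

#' Apply a noise-response model to a baseline call spec
#'
#' With `delta_db = 0` the baseline is returned unchanged. Otherwise syllable
#' levels gain `(lombard_slope + interaction[broadband]) * delta_db`; chirp
#' calls lengthen; whistle upper fundamental endpoints (and the chirp-call
#' sweep top) shift up; whistle lower endpoints shift by the
#' bandwidth-signed minimum-fundamental shift; and whistle harmonic weights
#' above the fundamental are scaled so the harmonic-3/fundamental energy
#' ratio increases by `tilt_slope_per_db * delta_db`.
#'
#' @param base A [call_spec()].
#' @param delta_db Noise level above ambient, dB (>= 0).
#' @param bandwidth_class `"narrow"` or `"broad"`.
#' @param model A [response_model()].
#' @return A modified [call_spec()].
#' @export
apply_response <- function(base, delta_db, bandwidth_class, model) {
  if (delta_db < 0) stop("'delta_db' must be non-negative")
  if (delta_db == 0) return(base)
  bandwidth_class <- match.arg(bandwidth_class, c("narrow", "broad"))
  broad <- bandwidth_class == "broad"
  lom <- (model$lombard_slope +
          if (broad) model$lombard_bw_interaction else 0) * delta_db
  out <- base
  for (i in seq_along(out$syllables)) {
    s <- out$syllables[[i]]
    s$level_db <- s$level_db + lom
    if (base$call_type == "chirp") {
      s$duration_s <- s$duration_s +
        model$duration_slope_ms_per_db * delta_db / 1000
      s[[f0_hi_idx(s)]] <- s[[f0_hi_idx(s)]] +
        model$peak_f0_slope_hz_per_db * delta_db
    }
    if (s$type == "whistle") {
      s[[f0_hi_idx(s)]] <- s[[f0_hi_idx(s)]] +
        model$peak_f0_slope_hz_per_db * delta_db
      shift <- if (broad) -abs(model$min_f0_bw_shift_hz)
               else abs(model$min_f0_bw_shift_hz)
      s[[f0_lo_idx(s)]] <- max(s[[f0_lo_idx(s)]] + shift, 1)
      w <- s$harmonic_weights
      if (length(w) >= 3L && w[3] > 0) {
        g <- 1 + model$tilt_slope_per_db * delta_db * w[1] / w[3]
        if (g < 0) {
          warning("tilt adjustment drove harmonic weights negative; clipped at 0")
          g <- 0
        }
        w[-1] <- w[-1] * g
        s$harmonic_weights <- w
      }
    }
    out$syllables[[i]] <- s
  }
  out
}

#' Per-call natural variability
#'
#' Adds the study's high call-to-call variability: a call-wide level jitter
#' (normal on the dB scale), relative normal jitter on syllable and pause
#' durations and on the fundamental endpoints (draws truncated at 2.5 sd so
#' chirp harmonics stay below Nyquist), and lognormal jitter on the
#' above-fundamental harmonic weights.
#'
#' @param spec A [call_spec()].
#' @param sd_level_db Level jitter sd, dB.
#' @param sd_dur_rel Relative duration jitter sd.
#' @param sd_f0_rel Relative fundamental jitter sd.
#' @param sdlog_weights Lognormal sd of upper harmonic weights.
#' @return A jittered [call_spec()]. Consumes random draws.
#' @export
jitter_call_spec <- function(spec, sd_level_db = 1.5, sd_dur_rel = 0.08,
                             sd_f0_rel = 0.03, sdlog_weights = 0.2) {
  rtnorm <- function(n, sd) {
    z <- rnorm(n, 0, sd)
    pmin(pmax(z, -2.5 * sd), 2.5 * sd)
  }
  dl <- rtnorm(1, sd_level_db)
  ff <- 1 + rtnorm(1, sd_f0_rel)
  out <- spec
  for (i in seq_along(out$syllables)) {
    s <- out$syllables[[i]]
    s$level_db <- s$level_db + dl
    s$duration_s <- max(s$duration_s * (1 + rtnorm(1, sd_dur_rel)), 0.015)
    s$f0_start_hz <- s$f0_start_hz * ff
    s$f0_end_hz <- s$f0_end_hz * ff
    if (length(s$harmonic_weights) > 1L) {
      k <- length(s$harmonic_weights) - 1L
      s$harmonic_weights[-1] <- s$harmonic_weights[-1] *
        exp(rtnorm(k, sdlog_weights))
    }
    out$syllables[[i]] <- s
  }
  if (length(out$pauses_s))
    out$pauses_s <- pmax(out$pauses_s * (1 + rtnorm(length(out$pauses_s),
                                                    sd_dur_rel)), 0.01)
  out
}

## ---- Rendering -------------------------------------------------------------

#' Synthesize one syllable
#'
#' Additive harmonic synthesis `sum_k sqrt(w_k) sin(k phi(t))` with `phi` the
#' integrated linear fundamental sweep, 5 ms raised-cosine onset/offset ramps,
#' scaled to the syllable's rms level after ramping. Harmonics that would
#' exceed the Nyquist frequency are dropped with a warning.
#'
#' @param spec A [syllable_spec()].
#' @param rate Sampling rate, Hz.
#' @return An [audio_clip()].
#' @export
synth_syllable <- function(spec, rate = 48000) {
  n <- round(spec$duration_s * rate)
  if (n < 2L) stop("syllable too short to render")
  t <- (0:(n - 1)) / rate
  sweep <- (spec$f0_end_hz - spec$f0_start_hz) / spec$duration_s
  phi <- 2 * pi * (spec$f0_start_hz * t + 0.5 * sweep * t^2)
  fmax <- max(spec$f0_start_hz, spec$f0_end_hz)
  k_all <- seq_along(spec$harmonic_weights)
  keep <- k_all * fmax < rate / 2
  if (!keep[1]) stop("fundamental exceeds Nyquist frequency")
  if (any(!keep))
    warning(sprintf("dropped aliased harmonic(s) %s",
                    paste(k_all[!keep], collapse = ", ")))
  x <- numeric(n)
  for (k in k_all[keep & spec$harmonic_weights > 0])
    x <- x + sqrt(spec$harmonic_weights[k]) * sin(k * phi)
  nr <- min(round(0.005 * rate), floor((n - 1) / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
    x[1:nr] <- x[1:nr] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  set_level_db(audio_clip(x, rate), spec$level_db)
}

## Sample-exact layout of a call: syllable sample counts, pause sample
## counts, syllable start offsets and the total length. Shared by the
## renderer and the annotation builder so bounds always match the audio.
call_layout <- function(spec, rate) {
  ns <- vapply(spec$syllables, function(s) round(s$duration_s * rate),
               numeric(1))
  np <- round(spec$pauses_s * rate)
  s0 <- cumsum(c(0, head(ns, -1) + c(np, 0)[seq_len(max(length(ns) - 1, 0))]))
  list(ns = ns, np = np, s0 = s0, total = sum(ns) + sum(np))
}

## Annotation implied by a spec, without rendering any audio.
spec_annotation <- function(spec, rate = 48000, call_id = "call") {
  lay <- call_layout(spec, rate)
  types <- vapply(spec$syllables, `[[`, character(1), "type")
  list(call_id = call_id, call_type = spec$call_type,
       onset = 0, offset = lay$total / rate,
       syllables = data.frame(type = types, onset = lay$s0 / rate,
                              offset = (lay$s0 + lay$ns) / rate,
                              stringsAsFactors = FALSE))
}

#' Synthesize a call and its sample-exact annotation
#'
#' @param spec A [call_spec()].
#' @param rate Sampling rate, Hz.
#' @param call_id Identifier recorded in the annotation.
#' @return A list with `clip` ([audio_clip()]) and `annotation` (a per-call
#'   record as produced by [annotation_calls()]); annotation bounds coincide
#'   exactly with the rendered sample extents.
#' @export
synth_call <- function(spec, rate = 48000, call_id = "call") {
  lay <- call_layout(spec, rate)
  x <- numeric(lay$total)
  for (i in seq_along(spec$syllables)) {
    cl <- synth_syllable(spec$syllables[[i]], rate)
    stopifnot(length(cl$samples) == lay$ns[i])
    x[(lay$s0[i] + 1):(lay$s0[i] + lay$ns[i])] <- cl$samples
  }
  list(clip = audio_clip(x, rate),
       annotation = spec_annotation(spec, rate, call_id))
}

## Expected measurement values implied by a call spec (the generator's truth).
spec_truth <- function(spec, rate = 48000) {
  syl <- spec$syllables
  ns <- vapply(syl, function(s) round(s$duration_s * rate), numeric(1))
  np <- round(spec$pauses_s * rate)
  p2 <- vapply(syl, function(s) db_to_pa(s$level_db)^2, numeric(1))
  total <- sum(ns) + sum(np)
  level_db <- to_db_spl(sqrt(sum(ns * p2) / total))
  types <- vapply(syl, `[[`, character(1), "type")
  main <- if (spec$call_type == "CLC") which(types == "whistle") else 1L
  f0_lo <- min(vapply(syl[main], function(s) min(s$f0_start_hz, s$f0_end_hz),
                      numeric(1)))
  f0_hi <- max(vapply(syl[main], function(s) max(s$f0_start_hz, s$f0_end_hz),
                      numeric(1)))
  f0_mid <- (f0_lo + f0_hi) / 2  # flat-band argmax proxy for a linear sweep
  w <- syl[[main[1]]]$harmonic_weights
  tilt_k <- if (spec$call_type == "CLC") 3L else 2L
  tilt <- if (length(w) >= tilt_k) w[tilt_k] / w[1] else NA_real_
  kpk <- which.max(w)
  # highest non-aliased harmonic over all syllables sets the upper edge
  top_hz <- max(vapply(syl, function(s) {
    fh <- max(s$f0_start_hz, s$f0_end_hz)
    kk <- seq_along(s$harmonic_weights)
    kk <- kk[kk * fh < rate / 2 & s$harmonic_weights > 0]
    if (length(kk)) max(kk) * fh else fh
  }, numeric(1)))
  list(level_db = level_db, duration_s = total / rate,
       syl_mean_dur_s = mean(ns[main]) / rate, n_syllables = length(syl),
       f0_min_hz = f0_lo, f0_peak_hz = f0_mid,
       peak_hz = if (spec$call_type == "CLC") kpk * f0_mid else f0_mid,
       min_hz = f0_lo,
       max_hz = if (spec$call_type == "CLC") top_hz else f0_hi,
       tilt_ratio = tilt, tilt_k = tilt_k,
       whistle_level_db = if (spec$call_type == "CLC")
         to_db_spl(mean(sqrt(p2[main]))) else NA_real_,
       whistle_peak_hz = if (spec$call_type == "CLC")
         kpk * f0_mid else NA_real_)
}

## ---- Experiment simulation --------------------------------------------------

#' Simulation configuration
#'
#' Defines the study conditions: subjects with baseline call specs and
#' per-trial call rates, the treatment bank, ambient level, trial length and
#' the master seed. Each subject receives 12 trials: 6 sessions pairing one
#' control trial with one treatment trial, the six treatments permuted at
#' random per subject.
#'
#' @param subjects List of subject entries, each a list with `name`,
#'   `clc` ([call_spec()]), `chirp` ([call_spec()]), `clc_rate` and
#'   `chirp_rate` (expected calls per trial, Poisson).
#' @param model A [response_model()].
#' @param bank Treatment bank (see [treatment_bank()]).
#' @param ambient_db Ambient level during control trials, dB re 20 uPa.
#' @param trial_s Trial length, seconds.
#' @param rate Sampling rate, Hz.
#' @param seed Master seed fixing every downstream draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(subjects, model = default_response_model(),
                       bank = treatment_bank(), ambient_db = 42,
                       trial_s = 60, rate = 48000, seed = 1) {
  stopifnot(length(subjects) >= 1, inherits(model, "response_model"))
  structure(list(subjects = subjects, model = model, bank = bank,
                 ambient_db = ambient_db, trial_s = trial_s, rate = rate,
                 seed = seed), class = "sim_config")
}

#' Default simulation configuration
#'
#' Three subjects producing both call types, with per-subject baseline level
#' and fundamental offsets (the between-subject variance absorbed by the
#' random intercept in the analysis), 60 s trials, and call rates scaled to
#' desk-size trials.
#'
#' @param n_subjects Number of subjects.
#' @param clc_rate,chirp_rate Expected calls per trial and type.
#' @param model A [response_model()].
#' @param trial_s Trial length, seconds.
#' @param seed Master seed.
#' @param ambient_db Ambient level, dB re 20 uPa.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(n_subjects = 3, clc_rate = 4, chirp_rate = 8,
                               model = default_response_model(), trial_s = 60,
                               seed = 1, ambient_db = 42) {
  lev_off <- seq(-3, 3, length.out = max(n_subjects, 2))[seq_len(n_subjects)]
  f0_off <- seq(-60, 60, length.out = max(n_subjects, 2))[seq_len(n_subjects)]
  subjects <- lapply(seq_len(n_subjects), function(i) {
    list(name = sprintf("s%d", i),
         clc = clc_spec(whistle_f0 = c(1600, 1900) + f0_off[i],
                        level_db = 70 + lev_off[i]),
         chirp = chirp_call_spec(level_db = 75 + lev_off[i]),
         clc_rate = clc_rate, chirp_rate = chirp_rate)
  })
  sim_config(subjects, model = model, trial_s = trial_s, seed = seed,
             ambient_db = ambient_db)
}

place_calls <- function(durations_s, trial_s, t_min = 6, sep_s = 0.5,
                        end_margin_s = 0.5) {
  n <- length(durations_s)
  if (!n) return(numeric())
  slack <- (trial_s - end_margin_s) - t_min - sum(durations_s) -
    sep_s * (n - 1)
  if (slack < 0)
    stop("call density too high to place calls without overlap")
  u <- sort(runif(n)) * slack
  t_min + u + cumsum(c(0, head(durations_s, -1) + sep_s))
}

#' Simulate a full playback experiment
#'
#' Draws the complete experiment (treatment order, call counts, per-call
#' response + jitter, placement) from the config's seed, then optionally
#' renders one WAV per trial: a noise bed (ambient white noise for control
#' trials, the band-limited stimulus for treatment trials) with calls added
#' at non-overlapping random times. The truth table records every generated
#' parameter; identical seeds give identical truth whether or not audio is
#' rendered.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (required when `render_audio = TRUE` or
#'   when CSV output is wanted); created if missing.
#' @param render_audio Render and write trial WAVs (default TRUE). With
#'   FALSE only the manifest/annotations/truth tables are produced, which is
#'   orders of magnitude faster and is used for statistical calibration.
#' @return Invisibly, a list with `manifest`, `annotations`, `truth`
#'   data frames and (when written) their file paths.
#' @export
simulate_experiment <- function(config, out_dir = NULL, render_audio = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (render_audio && is.null(out_dir))
    stop("'out_dir' is required when rendering audio")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  bank <- config$bank
  manifest <- list(); truths <- list(); anns <- list(); render <- list()

  for (sub in config$subjects) {
    treat_order <- sample(bank$name)
    for (sess in seq_along(treat_order)) {
      tr <- bank[bank$name == treat_order[sess], ]
      for (ttype in sample(c("control", "treatment"))) {
        wav <- sprintf("wav/%s_s%02d_%s.wav", sub$name, sess, ttype)
        is_trt <- ttype == "treatment"
        delta <- if (is_trt) tr$target_db - config$ambient_db else 0
        noise_db <- if (is_trt) tr$target_db else config$ambient_db
        n_clc <- rpois(1, sub$clc_rate)
        n_chirp <- rpois(1, sub$chirp_rate)
        types <- sample(rep(c("CLC", "chirp"), c(n_clc, n_chirp)))
        specs <- lapply(types, function(ct) {
          base <- if (ct == "CLC") sub$clc else sub$chirp
          jitter_call_spec(apply_response(base, delta, tr$bandwidth_class,
                                          config$model))
        })
        durs <- vapply(specs, function(sp)
          call_layout(sp, config$rate)$total / config$rate, numeric(1))
        starts <- round(place_calls(durs, config$trial_s) * config$rate) /
          config$rate
        bed_seeds <- sample.int(2^31 - 2, 2)

        manifest[[length(manifest) + 1L]] <- data.frame(
          subject = sub$name, session = sess, trial_type = ttype,
          treatment = if (is_trt) tr$name else "none", wav_path = wav,
          calibration = 1.0, stringsAsFactors = FALSE)

        if (length(specs)) {
          ids <- sprintf("%s_s%02d_%s_c%03d", sub$name, sess, ttype,
                         seq_along(specs))
          tt <- lapply(seq_along(specs), function(i) {
            tv <- spec_truth(specs[[i]], config$rate)
            data.frame(subject = sub$name, session = sess, trial_type = ttype,
                       treatment = if (is_trt) tr$name else "none",
                       bandwidth_class = tr$bandwidth_class,
                       noise_db = noise_db, delta_db = delta, wav_path = wav,
                       call_id = ids[i], call_type = types[i],
                       start_s = starts[i],
                       level_db = tv$level_db, duration_s = tv$duration_s,
                       syl_mean_dur_s = tv$syl_mean_dur_s,
                       n_syllables = tv$n_syllables,
                       f0_min_hz = tv$f0_min_hz, f0_peak_hz = tv$f0_peak_hz,
                       min_hz = tv$min_hz, peak_hz = tv$peak_hz,
                       max_hz = tv$max_hz, tilt_ratio = tv$tilt_ratio,
                       tilt_k = tv$tilt_k,
                       whistle_level_db = tv$whistle_level_db,
                       whistle_peak_hz = tv$whistle_peak_hz,
                       stringsAsFactors = FALSE)
          })
          truths[[length(truths) + 1L]] <- do.call(rbind, tt)
        }
        render[[length(render) + 1L]] <- list(
          wav = wav, is_trt = is_trt, tr = tr, specs = specs, starts = starts,
          ids = if (length(specs)) sprintf("%s_s%02d_%s_c%03d", sub$name,
                                           sess, ttype, seq_along(specs))
                else character(), bed_seeds = bed_seeds)
      }
    }
  }

  manifest <- do.call(rbind, manifest)
  truth <- if (length(truths)) do.call(rbind, truths) else NULL

  for (rn in render) {
    if (length(rn$specs)) {
      shifted <- lapply(seq_along(rn$specs), function(i) {
        a <- spec_annotation(rn$specs[[i]], config$rate, rn$ids[i])
        a$onset <- a$onset + rn$starts[i]
        a$offset <- a$offset + rn$starts[i]
        a$syllables$onset <- a$syllables$onset + rn$starts[i]
        a$syllables$offset <- a$syllables$offset + rn$starts[i]
        a
      })
      anns[[length(anns) + 1L]] <- calls_to_annotations(shifted, rn$wav)
    }
    if (render_audio) {
      n <- round(config$trial_s * config$rate)
      set.seed(rn$bed_seeds[1])
      bed <- set_level_db(audio_clip(rnorm(n), config$rate),
                          config$ambient_db)
      if (rn$is_trt)
        bed <- band_limited_noise(rn$tr, config$trial_s, config$rate,
                                  seed = rn$bed_seeds[2])
      x <- bed$samples
      for (i in seq_along(rn$specs)) {
        i0 <- round(rn$starts[i] * config$rate) + 1L
        smp <- synth_call(rn$specs[[i]], config$rate, rn$ids[i])$clip$samples
        x[i0:(i0 + length(smp) - 1L)] <- x[i0:(i0 + length(smp) - 1L)] + smp
      }
      dir.create(file.path(out_dir, dirname(rn$wav)), recursive = TRUE,
                 showWarnings = FALSE)
      write_wav(audio_clip(x, config$rate), file.path(out_dir, rn$wav))
    }
  }
  annotations <- if (length(anns)) do.call(rbind, anns) else NULL

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(manifest = file.path(out_dir, "manifest.csv"),
                  annotations = file.path(out_dir, "annotations.csv"),
                  truth = file.path(out_dir, "truth.csv"))
    write.csv(manifest, paths$manifest, row.names = FALSE)
    if (!is.null(annotations))
      write.csv(annotations, paths$annotations, row.names = FALSE)
    if (!is.null(truth)) write.csv(truth, paths$truth, row.names = FALSE)
  }
  invisible(list(manifest = manifest, annotations = annotations,
                 truth = truth, paths = paths))
}

#' Convert a truth table to measurement-table form
#'
#' Maps the generator's per-call ground truth onto the column layout produced
#' by [measure_trials()], so the aggregation and ANCOVA stages can run
#' directly on truth. Used for statistical calibration at scales where
#' rendering audio would be wasteful; the audio-to-measurement chain is
#' validated separately by the generator-measurement closure tests.
#'
#' @param truth Truth `data.frame` from [simulate_experiment()].
#' @return A measurement-style `data.frame`.
#' @export
truth_to_measurements <- function(truth) {
  data.frame(wav_path = truth$wav_path, call_id = truth$call_id,
             call_type = truth$call_type, source_level_db = truth$level_db,
             level_reliable = TRUE, duration_s = truth$duration_s,
             syl_mean_dur_s = truth$syl_mean_dur_s,
             n_syllables = truth$n_syllables, min_hz = truth$min_hz,
             peak_hz = truth$peak_hz, max_hz = truth$max_hz,
             f0_min_hz = truth$f0_min_hz, f0_peak_hz = truth$f0_peak_hz,
             f0_start_hz = NA_real_, f0_end_hz = NA_real_,
             tilt_ratio = truth$tilt_ratio, tilt_k = truth$tilt_k,
             whistle_level_db = truth$whistle_level_db,
             whistle_peak_hz = truth$whistle_peak_hz,
             trial_noise_db = truth$noise_db, stringsAsFactors = FALSE)
}
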