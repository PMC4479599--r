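# Shared fixtures: build a trial clip by injecting a synthesized call into a
# noise bed, with matching annotations, and measure it.

shift_annotation <- function(ann, t0) {
  ann$onset <- ann$onset + t0
  ann$offset <- ann$offset + t0
  ann$syllables$onset <- ann$syllables$onset + t0
  ann$syllables$offset <- ann$syllables$offset + t0
  ann
}

# Inject a rendered call into a bed at t0 seconds; returns the trial clip.
inject_call <- function(bed, clip, t0) {
  x <- bed$samples
  i0 <- round(t0 * bed$rate) + 1L
  idx <- i0:(i0 + length(clip$samples) - 1L)
  stopifnot(max(idx) <= length(x))
  x[idx] <- x[idx] + clip$samples
  audio_clip(x, bed$rate)
}

# Synthesize `spec` into a bed and measure it. bed_db = NULL gives a near
# noiseless (10 dB ambient) bed; bed = an audio_clip is used as-is.
measure_injected <- function(spec, bed_db = NULL, bed = NULL, trial_s = 15,
                             t0 = 6, seed = 1,
                             params = measurement_params()) {
  set.seed(seed)
  sc <- synth_call(spec, 48000, "call1")
  if (is.null(bed))
    bed <- set_level_db(audio_clip(rnorm(trial_s * 48000), 48000),
                        if (is.null(bed_db)) 10 else bed_db)
  trial <- inject_call(bed, sc$clip, t0)
  ann <- shift_annotation(sc$annotation, t0)
  ns <- trial_noise_stats(trial, calls_to_annotations(list(ann), "t.wav"),
                          params = params)
  list(m = measure_call(trial, ann, ns, params),
       truth = lombardlab:::spec_truth(spec, 48000),
       ns = ns, trial = trial, ann = ann)
}

# A pure-tone psd at frequency f (optionally several tones with amplitudes a).
tone_psd <- function(f, a = rep(1, length(f)), dur = 1, rate = 48000, ...) {
  t <- (0:(dur * rate - 1)) / rate
  x <- numeric(length(t))
  for (i in seq_along(f)) x <- x + a[i] * sin(2 * pi * f[i] * t)
  averaged_psd(audio_clip(x, rate), ...)
}

extdata <- function(name) system.file("extdata", name, package = "lombardlab")
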