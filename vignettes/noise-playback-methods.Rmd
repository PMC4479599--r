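---
title: "Measuring noise-induced vocal modification: models, procedures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring noise-induced vocal modification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lombardlab)
```

`lombardlab` re-creates, as tested code, the analysis chain of a
noise-playback experiment on cotton-top tamarin vocalizations: band-limited
noise stimuli at calibrated levels, acoustic measurement of combination long
calls (CLCs) and chirps, and a repeated-measures ANCOVA relating call
features to noise level and bandwidth. This vignette documents the science
the package implements, the parameters that matter, and the design choices
made where the original description left the procedure open.

## The experimental design being emulated

Subjects sit in a sound-attenuated chamber while noise plays from a speaker;
a calibrated microphone records vocalizations at 48 kHz. Each subject
receives six sessions, each pairing one control trial (no noise, ambient
about 42 dB re 20 μPa rms) and one treatment trial using one of six noise
treatments: {narrowband 1.5–6.5 kHz, broadband 0.1–10 kHz} × {high, medium,
low} levels. Published material names only the level range, 44–64 dB re
20 μPa (2–22 dB above ambient); the package defaults to the grid
{64, 54, 44} dB, configurable via `treatment_bank(levels = ...)`.

The two call types differ in structure and in which measurements apply. A
CLC is one short chirp syllable plus about four whistle syllables separated
by pauses; whistles are strongly harmonic with fundamentals near
1.4–2 kHz and most energy in the second harmonic. Stand-alone chirps are
~50–80 ms upsweeps with fundamentals near 10 kHz, leaving at most two
harmonics below the 24 kHz Nyquist limit.

## Stimulus synthesis

`band_limited_noise()` filters Gaussian white noise with a zero-phase
forward–backward Butterworth band-pass (order 4 per pass) and scales the
result exactly to the target level. Because two passes double the
attenuation, the design corners are pre-widened by
$(10^{3/20}-1)^{1/8} \approx 0.895$ so that the *measured* −3 dB points land
on the nominal band edges; tests verify the edges to within 5% and at least
40 dB of out-of-band rejection. The playback-system harmonic coloration
visible in real recordings of such stimuli is deliberately not emulated — it
is a hardware artifact irrelevant to the measurement method.

## The synthetic-call generator

Syllables are additive harmonic stacks over a linearly swept fundamental:
$x(t) = \sum_k \sqrt{w_k}\,\sin(k\,\phi(t))$ with $\phi$ the integrated
sweep, 5 ms raised-cosine ramps, and an exact rms level applied after
ramping. The weights $w_k$ are *power* weights, so the energy ratio of
harmonic $k$ to the fundamental is $w_k/w_1$ by construction — this is what
makes the generator a usable oracle for spectral-tilt measurement.

Key baseline choices, set once from the published summary values:

- **Whistles**: fundamental upsweep 1600→1900 Hz by default, with
  per-subject offsets spanning roughly 1.5–2 kHz. The published per-subject
  control minima (1393–1716 Hz) constrain the *across-subject* baseline
  range; the within-syllable sweep must stay modest, because a sweep of a
  full octave-like extent would make harmonic $k$ occupy $k$ times the sweep
  width and neighboring harmonics would overlap in frequency, leaving the
  third-harmonic tilt statistic unmeasurable by any spectral method.
  Control weights put 2–3× the fundamental's energy in harmonic 2
  (`w = c(1, 2.5, 0.8, ...)`), the published control condition.
- **Chirps**: 53.7 ms duration (a published control mean) and an
  8.5→10.5 kHz upsweep. The sweep tops out at 10.5 kHz so that harmonic 2
  stays below Nyquist even after +10% jitter; a 12 kHz fundamental would put
  harmonic 2 at the folding frequency, the synthesizer would drop it, and
  chirp tilt would be unmeasurable — mirroring the original observation that
  the recording chain limited chirps to two harmonics.
- **Per-call variability**: published material reports high inter- and
  intra-individual variability without distributions. The generator uses a
  call-wide normal jitter of 1.5 dB on level, 8% relative normal jitter on
  durations and pauses, 3% on fundamentals (truncated at 2.5 sd to protect
  the Nyquist margin), and lognormal (sd 0.2) jitter on upper harmonic
  weights. All are arguments of `jitter_call_spec()`.

### The noise-response model

`response_model()` holds the generator-side effect sizes that measurement
and statistics must recover, applied by `apply_response()` to a baseline
spec for a trial with noise `delta_db` above ambient:

| parameter | units | applies to | default (strong response) |
|---|---|---|---|
| `lombard_slope` | dB/dB | all syllables, both call types | 0.5 |
| `lombard_bw_interaction` | dB/dB | extra slope, broadband | 0.05 |
| `duration_slope_ms_per_db` | ms/dB | chirp calls | 0.45 |
| `peak_f0_slope_hz_per_db` | Hz/dB | whistle and chirp sweep tops | 5 |
| `min_f0_bw_shift_hz` | Hz | whistle sweep bottoms; + narrow, − broad | 60 |
| `tilt_slope_per_db` | per dB | whistle harmonic-3/fundamental ratio | 0.12 |

The defaults emulate the response pattern reported for this species:
a Lombard effect slightly stronger under broadband noise, longer chirps
(~0.45 ms/dB ≈ 5.5 ms over the mid-range noise excess), upward
peak-fundamental shifts, minimum-fundamental shifts whose sign depends on
bandwidth, and decreased spectral tilt in CLCs. Chirp tilt, chirp minima and
CLC durations are deliberately left without a response, matching the
null results for those features. Tilt changes scale all upper harmonics by a
common factor, so the harmonic-3 ratio rises by exactly
`tilt_slope_per_db * delta_db`; because syllable level is set after the
weights, a large tilt change makes the *fundamental* absolutely fainter —
the same "faint fundamental" appearance described for real high-noise calls,
and the reason minimum-fundamental measurement is intrinsically harder in
the loudest treatments.

With `delta_db = 0` (and for `zero_response_model()`) the baseline is
returned unchanged.

### Trials and placement

`simulate_experiment()` permutes the six treatments across sessions per
subject, draws Poisson call counts per trial and type, and places calls at
random non-overlapping times with ≥0.5 s separation, starting after 6 s so
that the first 5 s of every trial stays vocalization-free for the noise
measurement. Overcrowded draws raise an error rather than overlapping calls.
Treatment trials use the band-limited stimulus as the noise bed; control
trials use white ambient noise at 42 dB. (The ambient bed is omitted under
playback: at the lowest treatment level the difference is about 2 dB of bed
energy, and folding it in would make the noise covariate nonlinear in the
programmed response — the generator defines its conditions so that call
levels are exactly linear in the measured noise level.)

Trial length defaults to 60 s — a desk-scale stand-in for the original
12-minute trials with call counts kept near the published per-trial rates —
and the tests and examples use 15–30 s trials with proportionally fewer
calls. The truth table records every generated per-call parameter; identical
seeds give identical truth whether or not audio is rendered, because the
per-trial noise beds draw from seeds fixed during the truth phase.

## Measurement procedures

All spectral analysis uses Welch averaging with a 1024-point Hamming window,
75% overlap, and 4× zero-padding to a 4096-point DFT. At 48 kHz the bin
spacing is 48000/4096 = 11.72 Hz; the window alone would give 46.9 Hz, so
the published 11.7 Hz resolution pins down the zero-padding factor.

- **Levels.** Trial noise is the level of the first call-free 5 s window.
  Received call pressure is $\sqrt{\mathrm{ms}(call) - \mathrm{ms}(noise)}$;
  over-subtraction is clamped at a floor and flagged (never an exception),
  and any call whose mean square is below twice the noise mean square is
  flagged unreliable. Trial source level averages call pressures linearly,
  then converts to dB — the order matters and is asserted in tests. Source
  level here means the received level at the calibrated microphone; no
  distance back-propagation is applied, matching the original convention.
- **Spectral tilt.** Harmonic peaks are local PSD maxima within
  $k f_0 (1 \pm 0.15)$ search windows on the noise-subtracted spectrum;
  candidates below a leakage floor are treated as absent. The tilt ratio is
  the *energy* of harmonic $k$ relative to the fundamental (band-integrated
  over the search window), $k = 3$ for CLCs and $k = 2$ for chirps. Energy,
  not peak density, is the right statistic for frequency-modulated calls:
  harmonic $k$ of a sweep is spread over $k$ times the sweep width, so peak
  densities are biased low by roughly $1/k$ while energies recover the
  programmed $w_k/w_1$ — the generator-closure tests would catch the
  difference immediately, and only the energy reading reproduces the
  published control condition of 2–3× the fundamental's energy in
  harmonic 2. Peak densities remain available via
  `tilt_ratio(type = "density")`.
- **Spectral edges.** "Outermost inflection points" are operationalized as
  the outermost frequencies where the 5-bin median-smoothed PSD still
  reaches 24 dB below the peak (`edge_db`, configurable). The resolution of
  this reading is set by the analysis window: a 1024-point Hamming mainlobe
  is about 70 Hz (≈6 bins) wide at −24 dB, so even a pure tone's edges sit
  ~6 bins from its peak — edge-based measures are comparisons, not absolute
  frequencies, and the tests treat them accordingly (paired differences
  cancel the bias).
- **Fundamental measures.** The contour is the frame-wise PSD argmax inside
  a fundamental band (CLC default 1100–2750 Hz — the top must stay below
  half the lowest second harmonic or the tracker locks onto the stronger
  harmonic 2; chirp default 5–16 kHz). Contour endpoints come from a linear
  fit of frame frequency on frame time evaluated at the clip edges, removing
  the half-window bias of the outermost frames; for the linear sweeps the
  generator produces, endpoints are recovered within 2 bins. `f0_min` and
  `f0_peak` are then read from the fundamental-only spectrum (the PSD masked
  to the contour range ± 200 Hz), using *contiguous* edge detection from
  the peak outward: the fundamental spectrum is unimodal by construction,
  and the contiguous rule keeps residual noise islands left over from
  spectrum subtraction from faking an outer edge. For CLCs all fundamental
  measures are taken per whistle syllable (whistle clips contain no pauses
  or chirp components) and combined: minimum over syllables for `f0_min`,
  mean for `f0_peak`. For a linear sweep the fundamental PSD is nearly flat,
  so its argmax is approximately uniform over the swept band; the generator
  truth therefore records the band midpoint for `f0_peak`.

## The statistical model

Calls are aggregated to trial means (`aggregate_trials()`): missing cells —
a subject producing no calls of a type in a trial — stay missing, never
zero or imputed. Control trials inherit the bandwidth class of their
session's treatment trial and carry the measured ambient as their noise
level, so noise level enters as a single continuous covariate spanning
control and treatment trials.

`fit_ancova()` fits `response ~ noise_level * bandwidth + (1 | subject)` by
REML via `lme4`, with the covariate mean-centered and the bandwidth factor
under sum-to-zero contrasts so that each term is a one-degree-of-freedom
marginal (Type-III-style) test: F is the squared Wald t of the term's
coefficient. Denominator degrees of freedom use the containment rule
$n - \mathrm{rank}([X\,Z])$; a complete 3-subject × 12-trial design gives
$36 - 6 = 30$, the value a SAS-style mixed fit reports for this design, and
unbalanced designs yield whatever the realized data support (e.g. 26 when a
subject skips a few treatments). Only a subject intercept is random: three
subjects cannot identify random slopes, and a single denominator df per
term implies the simple structure. With zero estimated subject variance the
F statistics collapse exactly onto the fixed-effects-only ANCOVA, which the
tests verify against an OLS oracle.

Calibration, checked by simulation in the acceptance suite: under a zero
response model the noise-level term rejects at close to the nominal 5% rate
(band 2–10% over 200 replicate experiments), and a programmed Lombard slope
of 0.4 dB/dB is recovered within ±0.05 with ≥80% power over 100 replicates.
These replicate runs use the generator's truth tables directly
(`simulate_experiment(render_audio = FALSE)` + `truth_to_measurements()`);
rendering and re-measuring hundreds of full-audio experiments would add
hours of computation while testing nothing new, because the audio →
measurement link is validated separately by the closure and noise-robustness
suites at the per-call level.

## What passing tests do and do not show

The generator produces strongly harmonic, linearly swept, stationary-noise
trials with known annotations. Passing closure tests therefore demonstrates
that the measurement chain is unbiased *for signals of this class* at the
tested SNRs (levels within 0.2 dB noiseless and 0.5 dB at ~6 dB SNR; tilt
within 10% noiseless and 20% at ~10 dB SNR after spectrum subtraction). Real
recordings add reverberation, cage noise, nonstationary ambient sound,
amplitude-modulated and nonlinearly swept calls, and imperfect manual
annotations — none of which are emulated, and all of which would widen these
error bars. The statistical calibration likewise conditions on the
generator's jitter model (normal/lognormal, independent across calls);
heavy-tailed or serially correlated call variation would change the
operating characteristics.

## Numerical and degenerate-input conventions

Noise over-subtraction floors at a small positive value with an explicit
flag; PSD subtraction floors at $10^{-12}$ of the call spectrum's peak;
clips shorter than one analysis window are zero-padded with a warning;
aliased harmonics are dropped with a warning at synthesis; tilt adjustments
that would drive harmonic weights negative clip at zero with a warning; an
all-zero clip cannot be level-scaled; and rank-deficient ANCOVA designs
error naming the aliased term. Annotation tables are validated row by row
(call bounds, syllable nesting and ordering, the control/treatment–bandwidth
pairing), and every validation error names the offending row.
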