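## Calibrated band-limited white-noise playback treatments.
##
## The treatment bank crosses two bandwidth classes (narrowband 1.5-6.5 kHz,
## broadband 0.1-10 kHz) with three in-cage levels. Levels are dB re 20 uPa
## rms; with the default 42 dB ambient the bank spans 2-22 dB of noise excess.

#' The six-treatment noise bank
#'
#' Treatments A--C are narrowband (1500--6500 Hz, 5 kHz bandwidth) and D--F
#' broadband (100--10000 Hz), each at high/medium/low target levels.
#'
#' @param levels Length-3 numeric, dB re 20 uPa rms for the high, medium and
#'   low members of each bandwidth class. Default `c(64, 54, 44)`.
#' @return A `data.frame` with columns `name`, `low_hz`, `high_hz`,
#'   `target_db`, `bandwidth_class`.
#' @export
treatment_bank <- function(levels = c(64, 54, 44)) {
  stopifnot(length(levels) == 3, all(is.finite(levels)))
  if (any(levels < 44 - 1e-9) || any(levels > 64 + 1e-9))
    stop("treatment levels must lie within [44, 64] dB re 20 uPa")
  data.frame(name = LETTERS[1:6],
             low_hz = c(rep(1500, 3), rep(100, 3)),
             high_hz = c(rep(6500, 3), rep(10000, 3)),
             target_db = c(levels, levels),
             bandwidth_class = rep(c("narrow", "broad"), each = 3),
             stringsAsFactors = FALSE)
}

lookup_treatment <- function(treatment, bank = treatment_bank()) {
  if (is.character(treatment) && length(treatment) == 1L) {
    row <- bank[bank$name == treatment, , drop = FALSE]
    if (!nrow(row)) stop("unknown treatment: ", treatment)
    return(row)
  }
  stopifnot(is.data.frame(treatment), nrow(treatment) == 1L)
  treatment
}

#' Scale a clip to a target sound pressure level
#'
#' @param clip An [audio_clip()].
#' @param target_db Target rms level, dB re 20 uPa.
#' @return The rescaled clip; its rms pressure equals
#'   `20e-6 * 10^(target_db/20)` exactly (to float precision).
#' @export
set_level_db <- function(clip, target_db) {
  r <- rms(clip)
  if (r <= 0) stop("cannot set level of an all-zero clip")
  clip$samples <- clip$samples * (db_to_pa(target_db) / r)
  clip
}

## Two passes of an order-n Butterworth attenuate 3 dB where a single pass
## attenuates 1.5 dB, so design edges are pre-widened by g = 0.4125^(1/(2n))
## to put the measured (two-pass) -3 dB points on the nominal band edges.
## Solving the two-pass Butterworth response 1/(1 + w^(2n))^2 = 10^(-3/10)
## gives w^(2n) = 10^(3/20) - 1 (= 0.4125) at each pass' design edge.
bp_edge_gain <- function(order) (10^(3 / 20) - 1)^(1 / (2 * order))

#' Generate a band-limited white-noise stimulus
#'
#' Gaussian white noise band-pass filtered with a zero-phase
#' forward-backward Butterworth filter (order 4 per pass) and scaled to the
#' treatment's target level. Design edges are pre-widened so the measured
#' two-pass -3 dB points fall on the nominal band edges.
#'
#' @param treatment A treatment name (`"A"`..`"F"`) or a one-row bank entry.
#' @param duration_s Duration in seconds (> 0).
#' @param rate Sampling rate, Hz.
#' @param seed Optional integer; fixes the waveform exactly.
#' @param bank Treatment bank used to resolve names.
#' @return An [audio_clip()] at the treatment's target level.
#' @export
band_limited_noise <- function(treatment, duration_s, rate = 48000,
                               seed = NULL, bank = treatment_bank()) {
  if (duration_s <= 0) stop("'duration_s' must be positive")
  tr <- lookup_treatment(treatment, bank)
  if (tr$high_hz >= rate / 2)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 tr$high_hz, rate / 2))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- round(duration_s * rate)
  x <- rnorm(n)
  g <- bp_edge_gain(4)
  bf <- signal::butter(4, c(tr$low_hz * g, tr$high_hz / g) / (rate / 2),
                       type = "pass")
  y <- signal::filtfilt(bf, x)
  set_level_db(audio_clip(y, rate), tr$target_db)
}
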