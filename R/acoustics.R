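## Acoustic measurement primitives: rms levels with noise-energy subtraction,
## Welch power spectral densities with noise-spectrum subtraction, harmonic
## peak detection, spectral-tilt ratios, spectral extrema, fundamental
## contours, and durations.

#' Root-mean-square pressure of a clip
#' @param clip An [audio_clip()].
#' @return rms pressure in pascals.
#' @export
rms <- function(clip) {
  if (!length(clip$samples)) stop("empty clip")
  sqrt(mean(clip$samples^2))
}

#' Convert pressure to sound pressure level
#' @param p Pressure in pascals (> 0).
#' @return Level in dB re 20 uPa.
#' @export
to_db_spl <- function(p) {
  if (any(!is.finite(p) | p <= 0))
    stop("pressure must be positive (noise over-subtraction upstream?)")
  20 * log10(p / P_REF_PA)
}

#' Convert sound pressure level to pressure
#' @param db Level in dB re 20 uPa.
#' @return Pressure in pascals.
#' @export
db_to_pa <- function(db) P_REF_PA * 10^(db / 20)

#' Trial background-noise statistics from a call-free window
#'
#' Finds the first window of `window_s` seconds containing no annotated call
#' and returns its level, mean-square pressure and averaged PSD. Implements
#' the convention of measuring trial noise from a 5 s vocalization-free clip.
#'
#' @param trial_clip Full-trial [audio_clip()].
#' @param annotations Annotation rows for this trial (may be empty).
#' @param window_s Window length in seconds (default 5).
#' @param step_s Scan step between candidate window onsets.
#' @param params Measurement parameters, see [measurement_params()].
#' @return A list with `level_db`, `noise_ms` (Pa^2), `psd`, and the window
#'   `c(from, to)` in seconds.
#' @export
trial_noise_stats <- function(trial_clip, annotations, window_s = 5,
                              step_s = 0.5, params = measurement_params()) {
  dur <- clip_duration(trial_clip)
  if (dur < window_s)
    stop(sprintf("trial (%.2f s) shorter than noise window (%g s)", dur, window_s))
  on <- annotations$onset_s; off <- annotations$offset_s
  t0 <- 0
  repeat {
    if (t0 + window_s > dur + 1e-9)
      stop("no call-free window of ", window_s, " s found in trial")
    clean <- !length(on) || all(off <= t0 | on >= t0 + window_s)
    if (clean) break
    t0 <- t0 + step_s
  }
  w <- slice_clip(trial_clip, trial_clip$start_time + t0,
                  trial_clip$start_time + t0 + window_s)
  ms <- mean(w$samples^2)
  list(level_db = to_db_spl(sqrt(ms)), noise_ms = ms,
       psd = averaged_psd(w, params$window_len, params$overlap, params$dft_len),
       window = c(t0, t0 + window_s))
}

#' Trial noise level in dB re 20 uPa
#' @inheritParams trial_noise_stats
#' @return Noise level of the first call-free window, dB re 20 uPa.
#' @export
trial_noise_level <- function(trial_clip, annotations, window_s = 5,
                              step_s = 0.5)
  trial_noise_stats(trial_clip, annotations, window_s, step_s)$level_db

#' Noise-subtracted rms pressure of a call clip
#'
#' The received call pressure is the square root of the clip's mean-square
#' pressure minus the trial's mean-square noise. Over-subtraction is clamped
#' at a small floor and the result is flagged unreliable whenever the clip's
#' mean square is less than twice the noise mean square (call energy below
#' noise energy).
#'
#' @param call_clip [audio_clip()] covering the call.
#' @param noise_ms Mean-square noise pressure, Pa^2 (>= 0).
#' @return A list with `pa` (pressure, Pa) and `reliable` (logical).
#' @export
noise_subtracted_rms <- function(call_clip, noise_ms) {
  if (noise_ms < 0) stop("'noise_ms' must be non-negative")
  ms <- mean(call_clip$samples^2)
  floor_ms <- max(noise_ms * 1e-6, .Machine$double.xmin)
  list(pa = sqrt(max(ms - noise_ms, floor_ms)),
       reliable = ms >= 2 * noise_ms)
}

#' Trial source level from per-call pressures
#'
#' Calls are averaged in the linear pressure domain first and the mean is
#' then converted to dB re 20 uPa (mean-then-dB, not dB-then-mean).
#'
#' @param call_levels_pa Numeric vector of per-call rms pressures, Pa.
#' @return Trial source level, dB re 20 uPa.
#' @export
trial_source_level <- function(call_levels_pa) {
  if (!length(call_levels_pa)) stop("no calls in trial")
  to_db_spl(mean(call_levels_pa))
}

## ---- Power spectral density ----------------------------------------------

#' Welch averaged power spectral density
#'
#' Hamming-windowed overlapping segments, zero-padded 4x by default so the
#' bin spacing at 48 kHz is 48000/4096 = 11.72 Hz. Clips shorter than one
#' window are zero-padded to a single segment with a warning.
#'
#' @param clip An [audio_clip()].
#' @param window_len Segment length in samples (default 1024).
#' @param overlap Fractional overlap between segments (default 0.75).
#' @param dft_len DFT length; zero-pads each segment (default 4096).
#' @return An object of class `psd`: list with `freqs` (Hz), `power`
#'   (Pa^2/Hz, one-sided), `df` (bin spacing), and window metadata.
#' @export
averaged_psd <- function(clip, window_len = 1024, overlap = 0.75,
                         dft_len = 4096) {
  x <- clip$samples; fs <- clip$rate
  if (dft_len < window_len) stop("'dft_len' must be >= 'window_len'")
  if (length(x) < window_len) {
    warning("clip shorter than one window; using a single zero-padded segment")
    x <- c(x, numeric(window_len - length(x)))
  }
  w <- hamming_window(window_len)
  hop <- max(1L, round(window_len * (1 - overlap)))
  starts <- seq(1L, length(x) - window_len + 1L, by = hop)
  seg <- matrix(0, nrow = dft_len, ncol = length(starts))
  idx <- 0:(window_len - 1L)
  for (j in seq_along(starts)) seg[1:window_len, j] <- x[starts[j] + idx] * w
  spec <- Mod(stats::mvfft(seg))^2
  nbin <- dft_len %/% 2 + 1L
  pw <- rowMeans(spec[1:nbin, , drop = FALSE]) / (fs * sum(w^2))
  scale <- rep(2, nbin); scale[1] <- 1
  if (dft_len %% 2 == 0) scale[nbin] <- 1
  structure(list(freqs = (0:(nbin - 1L)) * fs / dft_len, power = pw * scale,
                 df = fs / dft_len, window_len = window_len,
                 overlap = overlap, dft_len = dft_len, n_segments = length(starts)),
            class = "psd")
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins, df = %.4f Hz, %d segment(s)\n",
              length(x$freqs), x$df, x$n_segments))
  invisible(x)
}

#' Subtract a noise spectrum from a call spectrum
#'
#' Per-bin subtraction on identical frequency grids; negative results are
#' clamped at a floor of `1e-12` times the call spectrum's peak.
#'
#' @param call_psd,noise_psd `psd` objects on the same grid.
#' @return A `psd` with the noise removed.
#' @export
subtract_psd <- function(call_psd, noise_psd) {
  if (length(call_psd$freqs) != length(noise_psd$freqs) ||
      any(abs(call_psd$freqs - noise_psd$freqs) > 1e-9))
    stop("frequency grids differ; PSDs must share window/dft parameters")
  out <- call_psd
  out$power <- pmax(call_psd$power - noise_psd$power,
                    1e-12 * max(call_psd$power))
  out
}

## ---- Harmonic structure and spectral tilt ---------------------------------

#' Locate harmonic peaks in a power spectrum
#'
#' For each harmonic index `k = 1..k_max`, searches a window
#' `k * f0_est * (1 +/- tol)` for a local maximum. A candidate must be a true
#' local maximum and exceed `min_rel` times the strongest located peak;
#' harmonics without such a peak are omitted. Each returned harmonic also
#' carries the band-integrated energy of its search window, used for
#' energy-based tilt ratios.
#'
#' @param psd A `psd` object (typically noise-subtracted).
#' @param f0_est Estimated fundamental frequency, Hz.
#' @param k_max Highest harmonic to search (CLC convention 8, chirp 2).
#' @param tol Relative half-width of each harmonic search window.
#' @param min_rel Minimum peak density relative to the strongest peak.
#' @return A `data.frame` with columns `k`, `freq_hz`, `density`, `energy`.
#' @export
harmonic_peaks <- function(psd, f0_est, k_max, tol = 0.15, min_rel = 1e-4) {
  if (f0_est <= 0 || f0_est > max(psd$freqs))
    stop("'f0_est' outside the PSD frequency range")
  rows <- list()
  for (k in seq_len(k_max)) {
    lo <- k * f0_est * (1 - tol); hi <- k * f0_est * (1 + tol)
    idx <- which(psd$freqs >= lo & psd$freqs <= hi)
    if (length(idx) < 3L) next
    p <- psd$power[idx]
    j <- idx[which.max(p)]
    if (psd$power[j] < 1e-6 * max(psd$power)) next  # leakage floor, no peak
    is_local_max <- j > 1L && j < length(psd$power) &&
      psd$power[j] >= psd$power[j - 1L] && psd$power[j] >= psd$power[j + 1L] &&
      (psd$power[j] > psd$power[j - 1L] || psd$power[j] > psd$power[j + 1L])
    if (!is_local_max) next
    rows[[length(rows) + 1L]] <-
      data.frame(k = k, freq_hz = psd$freqs[j], density = psd$power[j],
                 energy = sum(psd$power[idx]) * psd$df)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(k = integer(), freq_hz = numeric(), density = numeric(),
               energy = numeric())
  if (nrow(out)) {
    keep <- out$density >= min_rel * max(out$density)
    out <- out[keep, , drop = FALSE]
  }
  if (!nrow(out) || !1L %in% out$k)
    stop("no fundamental peak found near ", round(f0_est), " Hz")
  rownames(out) <- NULL
  out
}

#' Spectral-tilt ratio of harmonic k to the fundamental
#'
#' The ratio of energy in harmonic `k` to energy in the fundamental
#' (CLC convention k = 3, chirp convention k = 2). `type = "density"` uses
#' the peak spectral densities instead; for frequency-modulated calls the
#' density ratio is biased low by the wider sweep extent of higher harmonics,
#' so energy is the default.
#'
#' @param peaks Output of [harmonic_peaks()].
#' @param k Harmonic index to compare with the fundamental.
#' @param type `"energy"` (default) or `"density"`.
#' @return The ratio, or `NA` (with a `reason` attribute) when harmonic `k`
#'   was not located.
#' @export
tilt_ratio <- function(peaks, k, type = c("energy", "density")) {
  type <- match.arg(type)
  if (!k %in% peaks$k) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("harmonic %d not found", k)
    return(out)
  }
  v <- peaks[[type]]
  v[peaks$k == k] / v[peaks$k == 1L]
}

## ---- Spectral extrema and fundamental contour ------------------------------

#' Minimum, peak and maximum frequency of a spectrum
#'
#' Peak frequency is the PSD argmax. Minimum and maximum frequencies
#' operationalize the manual "outermost inflection point" reading as the
#' outermost frequencies at which the median-smoothed PSD still reaches
#' `edge_db` below the peak.
#'
#' @param psd A `psd` object.
#' @param edge_db Edge threshold below the peak, dB (default 24).
#' @param smooth_bins Running-median width in bins (odd; default 5).
#' @param contiguous If `TRUE`, edges are read from the contiguous
#'   above-threshold region around the peak (first crossing outward from the
#'   peak) instead of the outermost crossings. Used for fundamental-only
#'   spectra, which are unimodal by construction, to keep residual noise
#'   islands after spectrum subtraction from faking an outer edge.
#' @return Named numeric vector `c(min_hz, peak_hz, max_hz)`.
#' @export
spectrum_extrema <- function(psd, edge_db = 24, smooth_bins = 5,
                             contiguous = FALSE) {
  p <- psd$power
  if (max(p) <= 0 || diff(range(p)) == 0)
    stop("flat spectrum: no extrema defined")
  sm <- runmed(p, smooth_bins)
  pk <- which.max(p)
  thr <- max(sm) * 10^(-edge_db / 10)
  above <- sm >= thr
  if (contiguous) {
    lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- pk; while (hi < length(above) && above[hi + 1L]) hi <- hi + 1L
  } else {
    lo <- min(which(above)); hi <- max(which(above))
  }
  c(min_hz = psd$freqs[lo], peak_hz = psd$freqs[pk],
    max_hz = psd$freqs[hi])
}

#' Fundamental-frequency measures of a voiced clip
#'
#' The contour is tracked frame-wise as the PSD argmax inside `band`
#' (chosen below half the second harmonic); contour endpoints are read from
#' a linear fit of frame frequency on frame time, evaluated at the clip
#' edges, which removes the half-window bias of the outermost frames.
#' `f0_min` and `f0_peak` are then measured on the fundamental-only power
#' spectrum: the averaged PSD masked to the contour's range plus `margin_hz`,
#' with `f0_peak` the masked argmax and `f0_min` the lower
#' [spectrum_extrema()] edge.
#'
#' @param clip [audio_clip()] of one voiced syllable or call.
#' @param band Numeric length-2: frequency band containing the fundamental.
#' @param params Measurement parameters, see [measurement_params()].
#' @param margin_hz Mask margin around the tracked contour range.
#' @param noise_psd Optional noise `psd` to subtract before masking.
#' @return List with `f0_min_hz`, `f0_peak_hz`, `f0_start_hz`, `f0_end_hz`
#'   (contour endpoints), and `contour` (data frame `time_s`, `f0_hz`).
#'   All values `NA` when no voiced frames are found.
#' @export
f0_measures <- function(clip, band, params = measurement_params(),
                        margin_hz = 200, noise_psd = NULL) {
  wl <- params$window_len; hop <- max(1L, round(wl * (1 - params$overlap)))
  x <- clip$samples; fs <- clip$rate
  if (length(x) < wl) x <- c(x, numeric(wl - length(x)))
  starts <- seq(1L, length(x) - wl + 1L, by = hop)
  w <- hamming_window(wl)
  nfft <- params$dft_len
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(in_band)) stop("fundamental band outside spectrum")
  seg <- matrix(0, nrow = nfft, ncol = length(starts))
  for (j in seq_along(starts)) seg[1:wl, j] <- x[starts[j] + 0:(wl - 1L)] * w
  spec <- Mod(stats::mvfft(seg))^2
  bandpow <- spec[in_band, , drop = FALSE]
  fmax <- apply(bandpow, 2, max)
  voiced <- fmax >= 1e-3 * max(fmax)
  if (!any(voiced))
    return(list(f0_min_hz = NA_real_, f0_peak_hz = NA_real_,
                f0_start_hz = NA_real_, f0_end_hz = NA_real_,
                contour = data.frame(time_s = numeric(), f0_hz = numeric())))
  tcen <- (starts - 1L + wl / 2) / fs
  f0 <- freqs[in_band[apply(bandpow, 2, which.max)]]
  contour <- data.frame(time_s = tcen[voiced], f0_hz = f0[voiced])
  dur <- clip_duration(clip)
  if (nrow(contour) >= 3L && sd(contour$time_s) > 0) {
    fit <- lm(f0_hz ~ time_s, data = contour)
    ends <- as.numeric(predict_line(fit, c(0, dur)))
  } else ends <- rep(median(contour$f0_hz), 2)
  ends <- pmin(pmax(ends, band[1]), band[2])

  psd <- averaged_psd(clip, wl, params$overlap, nfft)
  if (!is.null(noise_psd)) psd <- subtract_psd(psd, noise_psd)
  lo <- max(band[1], min(contour$f0_hz) - margin_hz)
  hi <- min(band[2], max(contour$f0_hz) + margin_hz)
  mask <- psd$freqs >= lo & psd$freqs <= hi
  fund <- psd
  fund$power[!mask] <- 1e-12 * max(psd$power[mask])
  ex <- spectrum_extrema(fund, params$edge_db, contiguous = TRUE)
  list(f0_min_hz = unname(ex["min_hz"]), f0_peak_hz = unname(ex["peak_hz"]),
       f0_start_hz = ends[1], f0_end_hz = ends[2], contour = contour)
}

predict_line <- function(fit, x) coef(fit)[1] + coef(fit)[2] * x

#' Whole-call and per-syllable durations
#'
#' Whole-call duration includes inter-syllable pauses; per-syllable durations
#' exclude them, so `whole - sum(per_syllable)` equals the summed pauses.
#'
#' @param annotation A per-call record (see [annotation_calls()]).
#' @return List with `whole_s` and numeric `per_syllable_s`.
#' @export
durations <- function(annotation) {
  list(whole_s = annotation$offset - annotation$onset,
       per_syllable_s = annotation$syllables$offset - annotation$syllables$onset)
}
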