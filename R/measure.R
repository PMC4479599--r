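## Composition of the acoustic primitives into per-call measurement records,
## mirroring the manual measurement scheme: CLCs measured on the whole call
## and per syllable, chirps on the fundamental contour only.

#' Measurement parameters
#'
#' Spectral analysis settings shared by all measurement operations. Defaults
#' reproduce an 11.72 Hz bin spacing at 48 kHz (1024-point Hamming window,
#' 75% overlap, 4x zero-padding to a 4096-point DFT).
#'
#' @param window_len Welch segment length, samples.
#' @param overlap Fractional segment overlap.
#' @param dft_len DFT length (zero-padding).
#' @param edge_db Spectral-edge threshold below the peak, dB.
#' @param harm_tol Relative half-width of harmonic search windows.
#' @param clc_f0_band Frequency band (Hz) searched for the CLC whistle
#'   fundamental. The upper edge must stay below twice the lowest expected
#'   fundamental (half the second harmonic), or the tracker can lock onto
#'   the stronger second harmonic.
#' @param chirp_f0_band Frequency band (Hz) searched for the chirp
#'   fundamental.
#' @return A list of class `measurement_params`.
#' @export
measurement_params <- function(window_len = 1024, overlap = 0.75,
                               dft_len = 4096, edge_db = 24, harm_tol = 0.15,
                               clc_f0_band = c(1100, 2750),
                               chirp_f0_band = c(5000, 16000)) {
  structure(list(window_len = window_len, overlap = overlap,
                 dft_len = dft_len, edge_db = edge_db, harm_tol = harm_tol,
                 clc_f0_band = clc_f0_band, chirp_f0_band = chirp_f0_band),
            class = "measurement_params")
}

measurement_na_row <- function() {
  data.frame(call_id = NA_character_, call_type = NA_character_,
             source_level_db = NA_real_, level_reliable = NA,
             duration_s = NA_real_, syl_mean_dur_s = NA_real_,
             n_syllables = NA_integer_, min_hz = NA_real_, peak_hz = NA_real_,
             max_hz = NA_real_, f0_min_hz = NA_real_, f0_peak_hz = NA_real_,
             f0_start_hz = NA_real_, f0_end_hz = NA_real_,
             tilt_ratio = NA_real_, tilt_k = NA_integer_,
             whistle_level_db = NA_real_, whistle_peak_hz = NA_real_,
             trial_noise_db = NA_real_, stringsAsFactors = FALSE)
}

#' Measure one annotated call
#'
#' Produces the full per-call measurement record: noise-subtracted source
#' level, whole-call and per-syllable durations, spectral extrema, spectral
#' tilt (third harmonic for CLCs, second for chirps), and
#' fundamental-frequency measures. CLCs are measured on the whole call and
#' the whistle syllables; all chirp frequency measures are taken on the
#' fundamental contour.
#'
#' @param trial_clip Full-trial [audio_clip()].
#' @param annotation A per-call record (see [annotation_calls()]).
#' @param noise_stats Trial noise statistics from [trial_noise_stats()].
#' @param params Measurement parameters, see [measurement_params()].
#' @return A one-row `data.frame`; failed sub-measures are `NA` with the
#'   reliability flag carried in `level_reliable`.
#' @export
measure_call <- function(trial_clip, annotation, noise_stats,
                         params = measurement_params()) {
  out <- measurement_na_row()
  out$call_id <- annotation$call_id
  out$call_type <- annotation$call_type
  out$trial_noise_db <- noise_stats$level_db

  cl <- slice_clip(trial_clip, annotation$onset, annotation$offset)
  lev <- noise_subtracted_rms(cl, noise_stats$noise_ms)
  out$source_level_db <- to_db_spl(lev$pa)
  out$level_reliable <- lev$reliable

  dd <- durations(annotation)
  out$duration_s <- dd$whole_s
  out$n_syllables <- length(dd$per_syllable_s)

  psd <- averaged_psd(cl, params$window_len, params$overlap, params$dft_len)
  psd_sub <- subtract_psd(psd, noise_stats$psd)

  if (annotation$call_type == "CLC") {
    ex <- spectrum_extrema(psd_sub, params$edge_db)
    out$min_hz <- ex["min_hz"]; out$peak_hz <- ex["peak_hz"]
    out$max_hz <- ex["max_hz"]
    out$tilt_k <- 3L
    wh <- annotation$syllables[annotation$syllables$type == "whistle", ,
                               drop = FALSE]
    if (nrow(wh)) {
      # fundamental measures are taken syllable-wise: whistle clips contain
      # no pauses or chirp components, so contour tracking stays on the
      # fundamental even under playback noise
      out$syl_mean_dur_s <- mean(wh$offset - wh$onset)
      wl <- wp <- fmin <- fpk <- rep(NA_real_, nrow(wh))
      f0_all <- numeric()
      for (i in seq_len(nrow(wh))) {
        sc <- slice_clip(trial_clip, wh$onset[i], wh$offset[i])
        wl[i] <- noise_subtracted_rms(sc, noise_stats$noise_ms)$pa
        spsd <- subtract_psd(averaged_psd(sc, params$window_len,
                                          params$overlap, params$dft_len),
                             noise_stats$psd)
        wp[i] <- spectrum_extrema(spsd, params$edge_db)["peak_hz"]
        f0 <- f0_measures(sc, params$clc_f0_band, params,
                          noise_psd = noise_stats$psd)
        fmin[i] <- f0$f0_min_hz; fpk[i] <- f0$f0_peak_hz
        if (i == 1L) { out$f0_start_hz <- f0$f0_start_hz }
        if (i == nrow(wh)) { out$f0_end_hz <- f0$f0_end_hz }
        f0_all <- c(f0_all, f0$contour$f0_hz)
      }
      out$whistle_level_db <- to_db_spl(mean(wl))
      out$whistle_peak_hz <- mean(wp, na.rm = TRUE)
      out$f0_min_hz <- if (any(!is.na(fmin))) min(fmin, na.rm = TRUE)
                       else NA_real_
      out$f0_peak_hz <- mean(fpk, na.rm = TRUE)
      if (length(f0_all)) {
        pk <- tryCatch(harmonic_peaks(psd_sub, median(f0_all), 8L,
                                      params$harm_tol),
                       error = function(e) NULL)
        if (!is.null(pk)) out$tilt_ratio <- tilt_ratio(pk, 3L)
      }
    }
  } else {
    f0 <- f0_measures(cl, params$chirp_f0_band, params,
                      noise_psd = noise_stats$psd)
    out$f0_min_hz <- f0$f0_min_hz; out$f0_peak_hz <- f0$f0_peak_hz
    out$f0_start_hz <- f0$f0_start_hz; out$f0_end_hz <- f0$f0_end_hz
    out$tilt_k <- 2L
    if (nrow(f0$contour)) {
      # chirp frequency measures use the fundamental contour only
      lo <- max(params$chirp_f0_band[1], min(f0$contour$f0_hz) - 200)
      hi <- min(params$chirp_f0_band[2], max(f0$contour$f0_hz) + 200)
      fund <- psd_sub
      mask <- fund$freqs >= lo & fund$freqs <= hi
      fund$power[!mask] <- 1e-12 * max(fund$power[mask])
      ex <- spectrum_extrema(fund, params$edge_db, contiguous = TRUE)
      out$min_hz <- ex["min_hz"]; out$peak_hz <- ex["peak_hz"]
      out$max_hz <- ex["max_hz"]
      pk <- tryCatch(harmonic_peaks(psd_sub, median(f0$contour$f0_hz), 2L,
                                    params$harm_tol),
                     error = function(e) NULL)
      if (!is.null(pk)) out$tilt_ratio <- tilt_ratio(pk, 2L)
    }
    out$syl_mean_dur_s <- out$duration_s
  }
  rownames(out) <- NULL
  out
}

#' Measure every annotated call in a set of trials
#'
#' Reads each trial WAV named in the manifest, derives its noise statistics
#' from the first call-free 5 s window, and measures every annotated call.
#'
#' @param manifest Trial manifest (see [load_manifest()]).
#' @param annotations Annotation table (see [load_annotations()]).
#' @param params Measurement parameters.
#' @param base_dir Directory WAV paths are relative to.
#' @return A `data.frame` of per-call measurements joined with `wav_path`.
#' @export
measure_trials <- function(manifest, annotations,
                           params = measurement_params(), base_dir = ".") {
  res <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    wav <- manifest$wav_path[i]
    clip <- read_wav(file.path(base_dir, wav), manifest$calibration[i])
    ann <- annotations[annotations$wav_path == wav, , drop = FALSE]
    ns <- trial_noise_stats(clip, ann, params = params)
    calls <- annotation_calls(ann)
    if (!length(calls)) next
    rows <- lapply(calls, function(cc) measure_call(clip, cc, ns, params))
    m <- do.call(rbind, rows)
    m <- cbind(wav_path = wav, m, stringsAsFactors = FALSE)
    res[[i]] <- m
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
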