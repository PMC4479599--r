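## Calibrated audio clips, WAV round-trip, and the tabular glue (trial
## manifests, call annotations) that ties recordings to subjects and calls.

#' Construct an audio clip
#'
#' An `audio_clip` is a mono pressure waveform in pascals together with its
#' sampling rate and the start time of the clip within its parent recording.
#'
#' @param samples Numeric vector of instantaneous pressure, in pascals.
#' @param rate Sampling rate in samples/second (default 48000, the rate used
#'   for all synthetic material in this package).
#' @param start_time Start of the clip within the parent recording, seconds.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate = 48000, start_time = 0) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("'samples' must be a non-empty numeric vector")
  if (!all(is.finite(samples))) stop("'samples' must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("'rate' must be a single positive number")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 start_time = as.numeric(start_time)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.3f s), start %.3f s\n",
              length(x$samples), x$rate, clip_duration(x), x$start_time))
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate

#' Extract a time slice of a clip
#'
#' Times are interpreted on the half-open interval `[from, to)` relative to
#' the parent recording (i.e. including `start_time`).
#'
#' @param clip An `audio_clip`.
#' @param from,to Slice bounds in seconds.
#' @return An `audio_clip` whose `start_time` is `from`.
#' @export
slice_clip <- function(clip, from, to) {
  if (to <= from) stop("'to' must be greater than 'from'")
  i0 <- floor((from - clip$start_time) * clip$rate) + 1L
  i1 <- ceiling((to - clip$start_time) * clip$rate)
  if (i0 < 1L || i1 > length(clip$samples))
    stop(sprintf("slice [%g, %g) outside clip bounds", from, to))
  audio_clip(clip$samples[i0:i1], clip$rate, start_time = from)
}

## ---- WAV (RIFF) reading and writing -------------------------------------
## Canonical dialect: 32-bit IEEE float, mono. PCM 16/24/32 accepted on read.
## Calibration is a single scalar, pascals per full scale.

#' Read a mono WAV file as a calibrated pressure waveform
#'
#' @param path Path to a mono PCM (16/24/32-bit) or IEEE-float (32/64-bit)
#'   WAV file.
#' @param calibration Pascals per full-scale unit; full-scale digital values
#'   map to `calibration` Pa.
#' @return An [audio_clip()] with samples in pascals.
#' @export
read_wav <- function(path, calibration = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      blk <- readBin(con, "raw", sz)
      u16 <- function(off) sum(as.integer(blk[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(blk[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
      if (fmt$format == 65534L && sz >= 40) fmt$format <- u16(24)  # extensible
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data): ", path)
  if (fmt$channels != 1L)
    stop(sprintf("expected mono audio, got %d channels: %s", fmt$channels, path))

  x <- switch(as.character(fmt$format),
    "1" = switch(as.character(fmt$bits),
      "16" = readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                     signed = TRUE, endian = "little") / 32768,
      "24" = pcm24_to_double(data_raw),
      "32" = readBin(data_raw, "integer", length(data_raw) / 4, size = 4,
                     endian = "little") / 2147483648,
      stop("unsupported PCM bit depth: ", fmt$bits)),
    "3" = readBin(data_raw, "double", length(data_raw) / (fmt$bits / 8),
                  size = fmt$bits / 8, endian = "little"),
    stop("unsupported WAV format code: ", fmt$format))
  audio_clip(x * calibration, rate = fmt$rate)
}

pcm24_to_double <- function(raw) {
  m <- matrix(as.integer(raw), nrow = 3)
  v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}

#' Write a clip as a 32-bit float mono WAV file
#'
#' Inverse of [read_wav()]: pascal samples are divided by `calibration`
#' before writing, so `read_wav(write_wav(clip))` round-trips.
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @param calibration Pascals per full-scale unit used on the way back in.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, calibration = 1.0) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples / calibration
  n <- length(x)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  data_bytes <- 4L * n
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(4 + 24 + 12 + 8 + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16)
  w_u16(3); w_u16(1)                       # IEEE float, mono
  w_u32(clip$rate)
  w_u32(clip$rate * 4); w_u16(4); w_u16(32)
  writeChar("fact", con, eos = NULL); w_u32(4); w_u32(n)
  writeChar("data", con, eos = NULL); w_u32(data_bytes)
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

## ---- Trial manifest ------------------------------------------------------

MANIFEST_COLS <- c("subject", "session", "trial_type", "treatment",
                   "wav_path", "calibration")

#' Load and validate a trial manifest
#'
#' A manifest has one row per trial with columns
#' `subject,session,trial_type,treatment,wav_path,calibration`.
#' `trial_type` is `control` or `treatment`; `treatment` is one of `A`--`F`
#' for treatment trials and `none` (or empty) for control trials.
#'
#' @param path CSV file path.
#' @return A `data.frame` of validated trial records.
#' @export
load_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  df$treatment[is.na(df$treatment) | df$treatment == ""] <- "none"
  errs <- character()
  bad <- function(rows, why) if (length(rows))
    errs <<- c(errs, sprintf("row %d: %s", rows, why))
  bad(which(!df$trial_type %in% c("control", "treatment")),
      "trial_type must be 'control' or 'treatment'")
  bad(which(!df$treatment %in% c(LETTERS[1:6], "none")),
      "treatment must be one of A-F or 'none'")
  bad(which(df$trial_type == "control" & df$treatment != "none"),
      "control trial must have treatment 'none'")
  bad(which(df$trial_type == "treatment" & df$treatment == "none"),
      "treatment trial must name a treatment A-F")
  bad(which(!is.finite(df$calibration) | df$calibration <= 0),
      "calibration must be a positive number")
  if (length(errs)) stop("invalid manifest:\n  ", paste(errs, collapse = "\n  "))
  df
}

## ---- Call annotations ----------------------------------------------------

ANNOTATION_COLS <- c("wav_path", "call_id", "call_type", "onset_s", "offset_s",
                     "syllable_index", "syllable_type", "syl_onset_s",
                     "syl_offset_s")

#' Load and validate a call-annotation table
#'
#' One row per syllable (rows with `syllable_index` NA carry a call with no
#' syllable breakdown, allowed only for chirps). Times are seconds within
#' the trial recording, half-open intervals `[onset, offset)`. Syllables must
#' nest inside the call bounds, be non-overlapping, and be time-ordered;
#' chirp calls have zero or one syllable entry.
#'
#' @param path CSV file path.
#' @return A `data.frame` of validated annotation rows.
#' @seealso [annotation_calls()] to split the table into per-call records.
#' @export
load_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing))
    stop("annotations are missing columns: ", paste(missing, collapse = ", "))
  errs <- character()
  bad <- function(rows, why) if (length(rows))
    errs <<- c(errs, sprintf("row %d: %s", rows, why))
  bad(which(!df$call_type %in% c("CLC", "chirp")),
      "call_type must be 'CLC' or 'chirp'")
  bad(which(!(df$offset_s > df$onset_s)), "call offset must exceed onset")
  has_syl <- !is.na(df$syllable_index)
  bad(which(has_syl & !df$syllable_type %in% c("chirp", "whistle")),
      "syllable_type must be 'chirp' or 'whistle'")
  bad(which(has_syl & !(df$syl_offset_s > df$syl_onset_s)),
      "syllable offset must exceed onset")
  bad(which(has_syl & (df$syl_onset_s < df$onset_s - 1e-9 |
                       df$syl_offset_s > df$offset_s + 1e-9)),
      "syllable outside call bounds")
  key <- paste(df$wav_path, df$call_id)
  for (k in unique(key)) {
    idx <- which(key == k & has_syl)
    if (length(idx) > 1L) {
      idx <- idx[order(df$syllable_index[idx])]
      o <- df$syl_onset_s[idx]; f <- df$syl_offset_s[idx]
      bad(idx[-1][which(o[-1] < f[-length(f)] - 1e-9)],
          "syllables overlap or are out of order")
    }
    cidx <- which(key == k)
    if (df$call_type[cidx[1]] == "chirp" && sum(has_syl[cidx]) > 1L)
      bad(cidx[2], "chirp call has more than one syllable entry")
  }
  if (length(errs))
    stop("invalid annotations:\n  ", paste(errs, collapse = "\n  "))
  df
}

#' Split an annotation table into per-call records
#'
#' @param annotations Annotation `data.frame` (see [load_annotations()]).
#' @param wav_path Optional filter to a single recording.
#' @return A list of call records, each a list with `call_id`, `call_type`,
#'   `onset`, `offset` and a `syllables` data frame (`type`, `onset`,
#'   `offset`).
#' @export
annotation_calls <- function(annotations, wav_path = NULL) {
  df <- annotations
  if (!is.null(wav_path)) df <- df[df$wav_path == wav_path, , drop = FALSE]
  if (!nrow(df)) return(list())
  key <- paste(df$wav_path, df$call_id, sep = "\r")
  lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
         function(idx) {
    d <- df[idx, , drop = FALSE]
    syl <- d[!is.na(d$syllable_index), , drop = FALSE]
    syl <- syl[order(syl$syllable_index), , drop = FALSE]
    list(call_id = d$call_id[1], call_type = d$call_type[1],
         onset = d$onset_s[1], offset = d$offset_s[1],
         syllables = data.frame(type = syl$syllable_type,
                                onset = syl$syl_onset_s,
                                offset = syl$syl_offset_s,
                                stringsAsFactors = FALSE))
  })
}

#' Flatten per-call records into an annotation table
#'
#' Inverse of [annotation_calls()]; used by the simulator.
#'
#' @param calls List of call records.
#' @param wav_path Recording the calls belong to.
#' @return Annotation `data.frame` with the standard columns.
#' @export
calls_to_annotations <- function(calls, wav_path) {
  rows <- lapply(calls, function(cl) {
    ns <- nrow(cl$syllables)
    if (ns == 0L)
      return(data.frame(wav_path = wav_path, call_id = cl$call_id,
                        call_type = cl$call_type, onset_s = cl$onset,
                        offset_s = cl$offset, syllable_index = NA_integer_,
                        syllable_type = NA_character_, syl_onset_s = NA_real_,
                        syl_offset_s = NA_real_, stringsAsFactors = FALSE))
    data.frame(wav_path = wav_path, call_id = cl$call_id,
               call_type = cl$call_type, onset_s = cl$onset,
               offset_s = cl$offset, syllable_index = seq_len(ns),
               syllable_type = cl$syllables$type,
               syl_onset_s = cl$syllables$onset,
               syl_offset_s = cl$syllables$offset, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
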