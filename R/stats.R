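## Trial-level aggregation and the repeated-measures ANCOVA
## (noise level continuous x bandwidth factor, random subject intercept).

#' Registry of analysis responses
#'
#' The fifteen response variables of the standard results grid, in reporting
#' order: nine CLC responses followed by six chirp responses.
#'
#' @return A `data.frame` with `response` (trial-summary column name),
#'   `call_type` and `label`.
#' @export
response_registry <- function() {
  data.frame(
    response = c("clc_source_level_db", "clc_whistle_level_db",
                 "clc_duration_s", "clc_whistle_dur_s", "clc_f0_peak_hz",
                 "clc_f0_min_hz", "clc_peak_hz", "clc_whistle_peak_hz",
                 "clc_tilt",
                 "chirp_source_level_db", "chirp_duration_s", "chirp_peak_hz",
                 "chirp_max_hz", "chirp_min_hz", "chirp_tilt"),
    call_type = rep(c("CLC", "chirp"), c(9, 6)),
    label = c("Source level (whole call)", "Source level (whistles)",
              "Duration (whole call)", "Duration (whistles)",
              "Peak fundamental frequency", "Minimum fundamental frequency",
              "Peak frequency (whole call)", "Peak frequency (whistles)",
              "Spectral tilt",
              "Source level", "Duration", "Peak frequency",
              "Maximum frequency", "Minimum frequency", "Spectral tilt"),
    stringsAsFactors = FALSE)
}

linear_mean_db <- function(db) to_db_spl(mean(db_to_pa(db)))

#' Aggregate per-call measurements to trial summaries
#'
#' One row per manifest trial. Source levels are averaged in the linear
#' pressure domain and converted to dB (the trial source-level convention);
#' all other responses are plain means over the trial's calls of that type.
#' Trials in which a subject produced no calls of a type keep that cell
#' missing (never zero). Control trials inherit the bandwidth class of their
#' session's treatment trial, and their noise level is the measured ambient.
#'
#' @param measurements Per-call measurement table ([measure_trials()] or
#'   [truth_to_measurements()]).
#' @param manifest Trial manifest.
#' @param bank Treatment bank used to map treatments to bandwidth classes.
#' @return A trial-summary `data.frame` with design columns (`subject`,
#'   `session`, `trial_type`, `treatment`, `bandwidth_class`, `noise_db`)
#'   and one column per registry response.
#' @export
aggregate_trials <- function(measurements, manifest, bank = treatment_bank()) {
  orphan <- setdiff(unique(measurements$wav_path), manifest$wav_path)
  if (length(orphan))
    stop("calls reference unknown trials: ", paste(orphan, collapse = ", "))
  bw_of <- setNames(bank$bandwidth_class, bank$name)
  out <- manifest[, c("subject", "session", "trial_type", "treatment",
                      "wav_path")]
  out$bandwidth_class <- NA_character_
  is_trt <- out$trial_type == "treatment"
  out$bandwidth_class[is_trt] <- bw_of[out$treatment[is_trt]]
  for (i in which(!is_trt)) {
    mate <- which(out$subject == out$subject[i] &
                  out$session == out$session[i] & is_trt)
    if (length(mate)) out$bandwidth_class[i] <- out$bandwidth_class[mate[1]]
  }
  out$noise_db <- NA_real_
  reg <- response_registry()
  for (r in reg$response) out[[r]] <- NA_real_

  for (i in seq_len(nrow(out))) {
    m <- measurements[measurements$wav_path == out$wav_path[i], , drop = FALSE]
    if (!nrow(m)) next
    out$noise_db[i] <- mean(m$trial_noise_db, na.rm = TRUE)
    clc <- m[m$call_type == "CLC", , drop = FALSE]
    ch <- m[m$call_type == "chirp", , drop = FALSE]
    mn <- function(x) if (length(x) && any(!is.na(x))) mean(x, na.rm = TRUE)
                      else NA_real_
    if (nrow(clc)) {
      out$clc_source_level_db[i] <- linear_mean_db(clc$source_level_db)
      out$clc_whistle_level_db[i] <-
        if (any(!is.na(clc$whistle_level_db)))
          linear_mean_db(clc$whistle_level_db[!is.na(clc$whistle_level_db)])
        else NA_real_
      out$clc_duration_s[i] <- mn(clc$duration_s)
      out$clc_whistle_dur_s[i] <- mn(clc$syl_mean_dur_s)
      out$clc_f0_peak_hz[i] <- mn(clc$f0_peak_hz)
      out$clc_f0_min_hz[i] <- mn(clc$f0_min_hz)
      out$clc_peak_hz[i] <- mn(clc$peak_hz)
      out$clc_whistle_peak_hz[i] <- mn(clc$whistle_peak_hz)
      out$clc_tilt[i] <- mn(clc$tilt_ratio)
    }
    if (nrow(ch)) {
      out$chirp_source_level_db[i] <- linear_mean_db(ch$source_level_db)
      out$chirp_duration_s[i] <- mn(ch$duration_s)
      out$chirp_peak_hz[i] <- mn(ch$peak_hz)
      out$chirp_max_hz[i] <- mn(ch$max_hz)
      out$chirp_min_hz[i] <- mn(ch$min_hz)
      out$chirp_tilt[i] <- mn(ch$tilt_ratio)
    }
  }
  out
}

#' Fit the repeated-measures ANCOVA for one response
#'
#' Model: `response ~ noise_level * bandwidth + (1 | subject)` with noise
#' level continuous (mean-centered) and bandwidth a two-level factor under
#' sum-to-zero contrasts, fitted by REML ([lme4::lmer()]). Each term's F is
#' the squared Wald t of its single coefficient (Type-III-style marginal
#' test); the denominator degrees of freedom use the containment rule
#' `n - rank([X Z])`, which yields 30 for a complete 3-subject x 12-trial
#' design.
#'
#' @param table Trial-summary table from [aggregate_trials()].
#' @param response Name of the response column.
#' @return An object of class `ancova_fit`: list with `response`, `terms`
#'   (data frame: `term`, `F`, `df1`, `df2`, `p`), `n`, `slope` (the
#'   noise-level coefficient, per dB) and the fitted model.
#' @export
fit_ancova <- function(table, response) {
  if (!response %in% names(table)) stop("unknown response: ", response)
  d <- table[!is.na(table[[response]]) & !is.na(table$noise_db) &
             !is.na(table$bandwidth_class), , drop = FALSE]
  if (length(unique(d$subject)) < 2L)
    stop("need at least 2 subjects with data for '", response, "'")
  if (length(unique(d$noise_db)) < 2L)
    stop("need at least 2 distinct noise levels; 'noise_db' term is aliased")
  if (length(unique(d$bandwidth_class)) < 2L)
    stop("design is rank deficient: 'bandwidth' term is aliased")
  d$nl_c <- d$noise_db - mean(d$noise_db)
  d$bw <- factor(d$bandwidth_class, levels = c("narrow", "broad"))
  contrasts(d$bw) <- stats::contr.sum(2)
  d$y <- d[[response]]
  d$subject <- factor(d$subject)

  fit <- lme4::lmer(y ~ nl_c * bw + (1 | subject), data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                      check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  vc <- as.matrix(vcov(fit))
  X <- lme4::getME(fit, "X")
  Z <- model.matrix(~ 0 + subject, d)
  ddf <- nrow(d) - qr(cbind(X, Z))$rank
  if (ddf < 1L) stop("no residual degrees of freedom")
  idx <- c(nl = 2L, bw = 3L, int = 4L)
  Fv <- (beta[idx] / sqrt(diag(vc)[idx]))^2
  terms <- data.frame(term = c("noise_level", "bandwidth", "interaction"),
                      F = unname(Fv), df1 = 1L, df2 = ddf,
                      p = unname(pf(Fv, 1, ddf, lower.tail = FALSE)),
                      stringsAsFactors = FALSE)
  structure(list(response = response, terms = terms, n = nrow(d),
                 slope = unname(beta[2L]), model = fit),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ANCOVA for %s (n = %d trials)\n", x$response, x$n))
  t <- x$terms
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-12s F(%d,%d) = %6.2f, p = %.3f\n", t$term[i], t$df1[i],
                t$df2[i], t$F[i], t$p[i]))
  invisible(x)
}

#' Per-subject control/treatment differences
#'
#' For every (subject, treatment) pair, the response's control value (from
#' the session's paired control trial), treatment value, and the difference
#' `treatment - control`. Frequency responses are rounded to integer hertz.
#'
#' @param summaries Trial-summary table from [aggregate_trials()].
#' @param response Response column name.
#' @return A `data.frame` with `subject`, `treatment`, `control_value`,
#'   `treatment_value`, `delta`; missing pairs give `NA` deltas.
#' @export
delta_table <- function(summaries, response) {
  is_hz <- grepl("_hz$", response)
  trt <- summaries[summaries$trial_type == "treatment", , drop = FALSE]
  rows <- lapply(seq_len(nrow(trt)), function(i) {
    ctl <- summaries[summaries$subject == trt$subject[i] &
                     summaries$session == trt$session[i] &
                     summaries$trial_type == "control", , drop = FALSE]
    cv <- if (nrow(ctl)) ctl[[response]][1] else NA_real_
    tv <- trt[[response]][i]
    if (is_hz) { cv <- round(cv); tv <- round(tv) }
    data.frame(subject = trt$subject[i], treatment = trt$treatment[i],
               control_value = cv, treatment_value = tv, delta = tv - cv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$subject, out$treatment), , drop = FALSE]
}

#' Results grid for a set of ANCOVA fits
#'
#' Assembles the response-by-term grid (F, dfs, p per term) in the registry's
#' deterministic order, plus a fixed-format text rendering with p-values to
#' two decimals and a significance flag at p <= 0.05.
#'
#' @param results List of `ancova_fit` objects.
#' @return A list with `table` (data frame) and `text` (character vector of
#'   formatted lines).
#' @export
ancova_report <- function(results) {
  if (!length(results)) stop("no results to report")
  reg <- response_registry()
  resp <- vapply(results, `[[`, character(1), "response")
  ord <- order(match(resp, reg$response))
  results <- results[ord]
  rows <- lapply(results, function(r) {
    t <- r$terms
    lab <- reg$label[match(r$response, reg$response)]
    data.frame(response = r$response,
               label = if (is.na(lab)) r$response else lab,
               call_type = reg$call_type[match(r$response, reg$response)],
               term = t$term, F = t$F, df1 = t$df1, df2 = t$df2, p = t$p,
               significant = t$p <= 0.05, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  wide <- tab[tab$term == "noise_level", c("label", "call_type")]
  fmt <- function(term, what) {
    s <- tab[tab$term == term, ]
    if (what == "F") sprintf("%.2f", s$F)
    else sprintf("%.2f%s", s$p, ifelse(s$significant, " *", ""))
  }
  text <- c(sprintf("%-34s %-6s %10s %8s %10s %8s %10s %8s", "Response",
                    "Type", "F[NL]", "p", "F[BW]", "p", "F[NLxBW]", "p"),
            sprintf("%-34s %-6s %10s %8s %10s %8s %10s %8s", wide$label,
                    wide$call_type,
                    fmt("noise_level", "F"), fmt("noise_level", "p"),
                    fmt("bandwidth", "F"), fmt("bandwidth", "p"),
                    fmt("interaction", "F"), fmt("interaction", "p")))
  list(table = tab, text = text)
}
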