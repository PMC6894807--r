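# Agreement between the source airflow and the bench-replayed airflow:
# per-cycle relative amplitude and period bias (mean, SD, percentiles,
# trimmed statistics, regression, Bland-Altman limits), per-cycle waveform
# Pearson correlation split by obstruction, and apnea-event agreement
# (sensitivity, PPV, onset and duration bias).

#' Pair source and bench breathing cycles
#'
#' Greedy nearest-onset matching within `window_s`: each source cycle is
#' paired with the closest unused bench cycle whose onset differs by at
#' most the window.
#'
#' @param source_cycles,bench_cycles `breath_cycles` tables sorted by
#'   onset.
#' @param window_s maximum onset difference, s.
#' @return list with `pairs` (data.frame `source`, `bench` row indices,
#'   `offset_s`), `unmatched_source`, `unmatched_bench` (row indices).
#' @export
match_cycles <- function(source_cycles, bench_cycles, window_s = 1.5) {
  ns <- nrow(source_cycles); nb <- nrow(bench_cycles)
  pairs <- data.frame(source = integer(0), bench = integer(0),
                      offset_s = numeric(0))
  used <- logical(nb)
  if (ns && nb) {
    for (i in seq_len(ns)) {
      d <- abs(bench_cycles$onset_s - source_cycles$onset_s[i])
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= window_s) {
        used[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          source = i, bench = j,
          offset_s = bench_cycles$onset_s[j] - source_cycles$onset_s[i]))
      }
    }
  }
  list(pairs = pairs,
       unmatched_source = setdiff(seq_len(ns), pairs$source),
       unmatched_bench = which(!used))
}

# rolling per-cycle amplitude baseline of one trace: the running 2-minute
# mean over normal-breathing cycles (event cycles would drag the baseline
# down right after every event)
relative_amplitudes <- function(cycles, window_s = 120) {
  n <- nrow(cycles)
  out <- numeric(n)
  pool <- cycles$label == "normal"
  glob <- if (any(pool)) mean(cycles$amplitude[pool]) else
    mean(cycles$amplitude)
  for (i in seq_len(n)) {
    sel <- pool & cycles$onset_s >= cycles$onset_s[i] - window_s &
           cycles$onset_s < cycles$onset_s[i]
    bl <- if (any(sel)) mean(cycles$amplitude[sel]) else glob
    out[i] <- cycles$amplitude[i] / max(bl, .Machine$double.eps)
  }
  out
}

bias_stats <- function(diff, x = NULL, y = NULL) {
  qs <- quantile(diff, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  inb <- diff >= qs[1] & diff <= qs[3]
  reg <- if (!is.null(x) && length(unique(x)) > 1) {
    fit <- lm(y ~ x)
    as.numeric(coef(fit))
  } else c(NA_real_, NA_real_)
  m <- mean(diff); s <- sd(diff)
  list(mean = m, sd = s,
       p2.5 = qs[1], median = qs[2], p97.5 = qs[3],
       trimmed_mean = mean(diff[inb]), trimmed_sd = sd(diff[inb]),
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       regression_intercept = reg[1], regression_slope = reg[2],
       n = length(diff))
}

#' Per-cycle amplitude and period agreement
#'
#' For each matched pair, the relative amplitude (peak-to-valley amplitude
#' normalized by the trace's own rolling 2-minute amplitude baseline) and
#' the total cycle time are compared bench minus source. Amplitude bias is
#' reported in percentage points; period bias in seconds. Besides mean and
#' SD, the 2.5/50/97.5 percentiles, the statistics of the central 95% of
#' cycles, the regression of bench on source, and Bland-Altman limits of
#' agreement are returned.
#'
#' @param source_cycles,bench_cycles `breath_cycles` tables.
#' @param pairs pairing from [match_cycles()].
#' @param relative use relative (baseline-normalized) amplitudes
#'   (default) or absolute ones.
#' @return list with `amplitude` and `ttot` statistics lists and `n_pairs`.
#' @export
amplitude_ttot_agreement <- function(source_cycles, bench_cycles, pairs,
                                     relative = TRUE) {
  p <- pairs$pairs
  if (nrow(p) < 2)
    stop("amplitude_ttot_agreement: need at least two matched pairs")
  if (relative) {
    as_ <- relative_amplitudes(source_cycles)[p$source] * 100
    ab <- relative_amplitudes(bench_cycles)[p$bench] * 100
  } else {
    as_ <- source_cycles$amplitude[p$source]
    ab <- bench_cycles$amplitude[p$bench]
  }
  ts <- source_cycles$ttot_s[p$source]
  tb <- bench_cycles$ttot_s[p$bench]
  list(amplitude = bias_stats(ab - as_, as_, ab),
       ttot = bias_stats(tb - ts, ts, tb),
       n_pairs = nrow(p))
}

#' Per-cycle waveform correlation
#'
#' Pearson correlation between each matched pair of cycle waveforms,
#' resampled to the shorter cycle's length; pairs with fewer than
#' `min_samples` airflow samples are excluded, zero-variance cycles are
#' skipped. Reported as mean and SD, separately for obstructed (OA/OH) and
#' unobstructed source cycles.
#'
#' @param source_cycles,bench_cycles `breath_cycles` tables.
#' @param pairs pairing from [match_cycles()].
#' @param flow_source,flow_bench the two airflow series.
#' @param rate sampling rate, Hz.
#' @param min_samples minimum samples per cycle (default 40).
#' @return list with `unobstructed` and `obstructed` (`mean`, `sd`, `n`)
#'   and `n_excluded`.
#' @export
morphology_correlation <- function(source_cycles, bench_cycles, pairs,
                                   flow_source, flow_bench, rate = 20,
                                   min_samples = 40L) {
  p <- pairs$pairs
  r <- rep(NA_real_, nrow(p))
  obstructed <- logical(nrow(p))
  excluded <- 0L
  for (k in seq_len(nrow(p))) {
    cs <- source_cycles[p$source[k], ]
    cb <- bench_cycles[p$bench[k], ]
    sa <- round(cs$onset_s * rate) + 1L
    sb <- min(length(flow_source), round(cs$end_s * rate))
    ba <- round(cb$onset_s * rate) + 1L
    bb <- min(length(flow_bench), round(cb$end_s * rate))
    ws <- flow_source[sa:sb]; wb <- flow_bench[ba:bb]
    if (length(ws) < min_samples || length(wb) < min_samples) {
      excluded <- excluded + 1L
      next
    }
    m <- min(length(ws), length(wb))
    rs <- approx(seq_along(ws), ws, xout = seq(1, length(ws), length.out = m))$y
    rb <- approx(seq_along(wb), wb, xout = seq(1, length(wb), length.out = m))$y
    if (sd(rs) <= .Machine$double.eps || sd(rb) <= .Machine$double.eps) next
    r[k] <- cor(rs, rb)
    obstructed[k] <- cs$label %in% c("OA", "OH")
  }
  ok <- !is.na(r)
  summ <- function(sel) {
    v <- r[ok & sel]
    list(mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1) sd(v) else NA_real_, n = length(v))
  }
  list(unobstructed = summ(!obstructed), obstructed = summ(obstructed),
       n_excluded = excluded)
}

#' Apnea-event agreement
#'
#' Apneas from the two traces are matched when their intervals overlap by
#' at least `overlap_frac` of the shorter event. Sensitivity is matched
#' over source apneas, PPV matched over bench apneas; onset differences
#' and a duration regression with Bland-Altman limits are reported for the
#' matched pairs.
#'
#' @param source_events,bench_events events data.frames (apneas are rows
#'   with kind OA/CA or NA kind from flow-only detection).
#' @param overlap_frac minimum overlap fraction of the shorter event.
#' @return list with `sensitivity`, `ppv`, `n_source`, `n_bench`,
#'   `n_matched`, `onset_diff` (`mean`, `sd`) and `duration` bias
#'   statistics (NULL when under two matches).
#' @export
apnea_agreement <- function(source_events, bench_events, overlap_frac = 0.5) {
  is_ap <- function(ev) is.na(ev$kind) | ev$kind %in% c("OA", "CA")
  se <- source_events[is_ap(source_events), , drop = FALSE]
  be <- bench_events[is_ap(bench_events), , drop = FALSE]
  ns <- nrow(se); nb <- nrow(be)
  used <- logical(nb)
  onset_d <- numeric(0); dur_s <- numeric(0); dur_b <- numeric(0)
  for (i in seq_len(ns)) {
    s0 <- se$onset_s[i]; s1 <- s0 + se$duration_s[i]
    best <- 0; bj <- NA_integer_
    for (j in seq_len(nb)) {
      if (used[j]) next
      b0 <- be$onset_s[j]; b1 <- b0 + be$duration_s[j]
      ov <- min(s1, b1) - max(s0, b0)
      short <- min(s1 - s0, b1 - b0)
      if (ov > 0 && ov / short >= overlap_frac && ov > best) {
        best <- ov; bj <- j
      }
    }
    if (!is.na(bj)) {
      used[bj] <- TRUE
      onset_d <- c(onset_d, be$onset_s[bj] - s0)
      dur_s <- c(dur_s, se$duration_s[i])
      dur_b <- c(dur_b, be$duration_s[bj])
    }
  }
  n_match <- length(onset_d)
  list(sensitivity = if (ns) n_match / ns else NA_real_,
       ppv = if (nb) n_match / nb else NA_real_,
       n_source = ns, n_bench = nb, n_matched = n_match,
       onset_diff = list(mean = if (n_match) mean(onset_d) else NA_real_,
                         sd = if (n_match > 1) sd(onset_d) else NA_real_),
       duration = if (n_match >= 2) bias_stats(dur_b - dur_s, dur_s, dur_b)
                  else NULL)
}

#' Full source-versus-bench evaluation report
#'
#' Detects cycles and apneas on the bench trace (airflow only), pairs them
#' with the source-side results, and assembles amplitude/period agreement,
#' waveform correlation and apnea agreement into one report.
#'
#' @param flow_source source airflow series.
#' @param source_cycles labelled source `breath_cycles`.
#' @param source_events source events data.frame.
#' @param flow_bench bench airflow series.
#' Cycle-level agreement (amplitude, period, morphology) is computed over
#' normal and hypopnea breathing; apneic cycles are compared at the event
#' level only.
#'
#' @param rate sampling rate, Hz.
#' @param config `evaluation` section of [default_config()].
#' @param events_config `events` section (for the bench-side apnea
#'   detection thresholds).
#' @return object of class `evaluation_report`: list with `amplitude`,
#'   `ttot`, `pearson`, `apnea`, `n_cycles`, `bench_cycles`,
#'   `bench_events`.
#' @export
evaluate_bench <- function(flow_source, source_cycles, source_events,
                           flow_bench, rate = 20,
                           config = default_config()$evaluation,
                           events_config = default_config()$events) {
  bench <- analyse_flow_trace(flow_bench, rate, events_config)
  pairs <- match_cycles(source_cycles, bench$cycles, config$match_window_s)
  keep <- !(source_cycles$label[pairs$pairs$source] %in% c("OA", "CA"))
  pairs$pairs <- pairs$pairs[keep, , drop = FALSE]
  agree <- amplitude_ttot_agreement(source_cycles, bench$cycles, pairs)
  pear <- morphology_correlation(source_cycles, bench$cycles, pairs,
                                 flow_source, flow_bench, rate,
                                 config$min_cycle_samples)
  apn <- apnea_agreement(source_events, bench$events, config$overlap_frac)
  structure(list(amplitude = agree$amplitude, ttot = agree$ttot,
                 n_cycles = agree$n_pairs, pearson = pear, apnea = apn,
                 bench_cycles = bench$cycles, bench_events = bench$events),
            class = "evaluation_report")
}

#' Evaluate two bare airflow traces symmetrically
#'
#' Both traces go through the identical flow-only analysis
#' ([analyse_flow_trace()]) before pairing and agreement; evaluating a
#' trace against itself therefore returns exact identities (zero biases,
#' r = 1, sensitivity = PPV = 1).
#'
#' @param flow_source,flow_bench airflow series.
#' @param rate sampling rate, Hz.
#' @param config,events_config as in [evaluate_bench()].
#' @return an `evaluation_report`.
#' @export
evaluate_traces <- function(flow_source, flow_bench, rate = 20,
                            config = default_config()$evaluation,
                            events_config = default_config()$events) {
  src <- analyse_flow_trace(flow_source, rate, events_config)
  evaluate_bench(flow_source, src$cycles, src$events, flow_bench, rate,
                 config, events_config)
}

#' Cycle and apnea detection on a bare airflow trace
#'
#' The bench produces airflow only, so breath onsets use the flow path
#' exclusively and apneas are excursion drops without the
#' confirmation-channel requirement (no second channel exists on the
#' bench).
#'
#' @param flow airflow series.
#' @param rate sampling rate, Hz.
#' @param events_config `events` section of [default_config()].
#' @return list with `cycles`, `events`, `excursion`.
#' @export
analyse_flow_trace <- function(flow, rate = 20,
                               events_config = default_config()$events) {
  pv <- detect_peaks_valleys(flow, rate)
  pv <- rescue_missed_cycles(flow, pv$peaks, pv$valleys, rate)
  if (length(pv$peaks) < 2 || length(pv$valleys) < 2)
    return(list(cycles = empty_cycles(), events = empty_events(),
                excursion = NULL))
  exc <- compute_excursion(flow, pv$peaks, pv$valleys, rate)
  cycles <- detect_breath_onsets(flow, exc, rate = rate)
  apneas <- detect_apneas(exc, NULL, rate,
                          flow_frac = events_config$apnea_flow_frac,
                          min_dur_s = events_config$min_dur_s,
                          max_dur_s = events_config$max_dur_s,
                          require_confirmation = FALSE)
  hypo <- detect_hypopneas(exc, NULL, apneas, rate,
                           min_drop = events_config$hypopnea_drop,
                           apnea_flow_frac = events_config$apnea_flow_frac,
                           min_dur_s = events_config$min_dur_s,
                           max_dur_s = events_config$max_dur_s,
                           require_confirmation = FALSE)
  mark <- function(ev, lab) {
    for (k in seq_len(nrow(ev))) {
      t1 <- ev$onset_s[k] + ev$duration_s[k]
      hit <- cycles$onset_s < t1 & cycles$end_s > ev$onset_s[k]
      cycles$label[hit] <<- lab
    }
  }
  mark(hypo, "OH")
  mark(apneas, "OA")
  list(cycles = cycles, events = apneas, excursion = exc)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  cycles paired: %d\n", x$n_cycles))
  cat(sprintf("  amplitude bias: %.2f%% +/- %.2f%%\n",
              x$amplitude$mean, x$amplitude$sd))
  cat(sprintf("  Ttot bias: %.3f +/- %.3f s\n", x$ttot$mean, x$ttot$sd))
  cat(sprintf("  Pearson r (unobstructed): %.3f +/- %.3f (n=%d)\n",
              x$pearson$unobstructed$mean, x$pearson$unobstructed$sd,
              x$pearson$unobstructed$n))
  if (x$pearson$obstructed$n)
    cat(sprintf("  Pearson r (obstructed): %.3f +/- %.3f (n=%d)\n",
                x$pearson$obstructed$mean, x$pearson$obstructed$sd,
                x$pearson$obstructed$n))
  cat(sprintf("  apnea sensitivity %.3f, PPV %.3f (matched %d)\n",
              x$apnea$sensitivity, x$apnea$ppv, x$apnea$n_matched))
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  keep <- report[c("amplitude", "ttot", "n_cycles", "pearson", "apnea")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
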