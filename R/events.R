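# Apnea/hypopnea detection and obstructive/central typing, following
# AASM-2012-style rules: apneas are excursion drops on the nasal-pressure
# scale (>= 90%, i.e. flow excursion <= sqrt(0.10) of the 2-min baseline),
# hypopneas are flow-excursion drops >= 30%, both confirmed against a
# second flow-sensitive channel (naso-buccal thermistance, else RIP flow)
# to exclude mouth breathing, and bounded at 3 minutes to exclude sensor
# displacement. Apneas are typed by significant effort attempts in the
# reference RIP band; hypopneas by snoring, thoracoabdominal paradox or
# inspiratory flow limitation.

empty_events <- function() {
  data.frame(kind = character(0), onset_s = numeric(0),
             duration_s = numeric(0), baseline_excursion = numeric(0),
             evidence = character(0), n_attempts = integer(0),
             n_sig_attempts = integer(0), stringsAsFactors = FALSE)
}

# mean of `x` over [t0, t1) seconds, clipped to the series
window_mean <- function(x, rate, t0, t1) {
  i0 <- max(1L, floor(t0 * rate) + 1L)
  i1 <- min(length(x), ceiling(t1 * rate))
  if (i1 < i0) return(NA_real_)
  mean(x[i0:i1])
}

# relative drop of the confirmation-channel excursion during an event vs
# its pre/post baselines
confirm_drop <- function(confirm_exc, rate, onset_s, end_s, baseline_s = 60) {
  ev <- window_mean(confirm_exc, rate, onset_s, end_s)
  pre <- window_mean(confirm_exc, rate, onset_s - baseline_s, onset_s)
  post <- window_mean(confirm_exc, rate, end_s, end_s + baseline_s)
  base <- mean(c(pre, post), na.rm = TRUE)
  if (!is.finite(base) || base <= .Machine$double.eps) return(0)
  1 - ev / base
}

#' Detect apnea candidate events
#'
#' Intervals where the airflow excursion stays at or below
#' `flow_frac` (default `sqrt(0.10)`, the flow-scale image of a >= 90%
#' nasal-pressure drop) of the 2-minute pre-event baseline, lasting
#' 10-180 s, and showing a simultaneous excursion drop greater than
#' `confirm_min_drop` in the confirmation channel. Kind is left unset; see
#' [classify_apnea()].
#'
#' @param exc an `excursion_track` of the airflow (or bare excursion
#'   series).
#' @param confirm_exc excursion series of the confirmation channel
#'   (thermistance if recorded, else RIP flow); `NULL` skips confirmation
#'   (events flagged unconfirmed and dropped unless
#'   `require_confirmation = FALSE`).
#' @param rate sampling rate, Hz.
#' @param flow_frac apnea threshold on the flow-excursion scale.
#' @param min_dur_s,max_dur_s scored duration bounds, s.
#' @param baseline_s excursion baseline window, s.
#' @param confirm_min_drop required confirmation drop (fraction).
#' @param confirm_baseline_s confirmation pre/post baseline window, s.
#' @param require_confirmation drop unconfirmed events (default TRUE).
#' @return events data.frame (`kind` = NA).
#' @export
detect_apneas <- function(exc, confirm_exc, rate = 20,
                          flow_frac = sqrt(0.10), min_dur_s = 10,
                          max_dur_s = 180, baseline_s = 120,
                          confirm_min_drop = 0.20, confirm_baseline_s = 60,
                          require_confirmation = TRUE) {
  x <- if (inherits(exc, "excursion_track")) exc$excursion else as.numeric(exc)
  runs <- low_excursion_runs(x, rate, frac = flow_frac,
                             baseline_s = baseline_s,
                             min_dur_s = min_dur_s, max_dur_s = max_dur_s)
  if (!nrow(runs)) return(empty_events())
  ev <- data.frame(kind = NA_character_, onset_s = runs$start_s,
                   duration_s = runs$end_s - runs$start_s,
                   baseline_excursion = runs$baseline,
                   evidence = "", n_attempts = 0L, n_sig_attempts = 0L,
                   stringsAsFactors = FALSE)
  if (is.null(confirm_exc)) {
    if (require_confirmation) {
      if (nrow(ev)) warning("detect_apneas: no confirmation channel; ",
                            nrow(ev), " unconfirmed event(s) dropped")
      return(empty_events())
    }
    return(ev)
  }
  drops <- vapply(seq_len(nrow(ev)), function(k)
    confirm_drop(confirm_exc, rate, ev$onset_s[k],
                 ev$onset_s[k] + ev$duration_s[k], confirm_baseline_s),
    numeric(1))
  ev[drops > confirm_min_drop, , drop = FALSE]
}

#' Type an apnea as obstructive or central
#'
#' Breath attempts are the reference-RIP peaks inside the event; an
#' attempt is significant when the RIP excursion at its peak time reaches
#' `sig_frac` (10%) of the RIP excursion baseline (mean over 1 min before
#' and after the event). At least one significant attempt makes the event
#' obstructive (OA), otherwise central (CA).
#'
#' Attempts with peaks within `edge_guard_s` of either event boundary are
#' ignored: the detected boundary cuts through transition breaths whose
#' excursion still carries pre/post-event amplitude.
#'
#' @param event one-row events data.frame.
#' @param rip_ref reference RIP series (chosen by
#'   [select_reference_rip()]).
#' @param exc_rip excursion series of `rip_ref`.
#' @param rate sampling rate, Hz.
#' @param sig_frac significance threshold (fraction of baseline).
#' @param baseline_s pre/post baseline window, s.
#' @param edge_guard_s boundary guard band, s.
#' @return the event row with `kind` set and attempt counts filled;
#'   attribute `attempts`: data.frame `time_s`, `significant`.
#' @export
classify_apnea <- function(event, rip_ref, exc_rip, rate = 20,
                           sig_frac = 0.10, baseline_s = 60,
                           edge_guard_s = 2) {
  t0 <- event$onset_s; t1 <- event$onset_s + event$duration_s
  i0 <- max(1L, floor(t0 * rate) + 1L)
  i1 <- min(length(rip_ref), ceiling(t1 * rate))
  attempts <- data.frame(time_s = numeric(0), significant = logical(0))
  if (i1 - i0 > rate) {
    pk <- ampd(rip_ref[i0:i1], max_scale = round(10 * rate)) + i0 - 1L
    g <- round(edge_guard_s * rate)
    if (i1 - i0 > 2 * g + rate) pk <- pk[pk >= i0 + g & pk <= i1 - g]
    if (length(pk)) {
      pre <- window_mean(exc_rip, rate, t0 - baseline_s, t0)
      post <- window_mean(exc_rip, rate, t1, t1 + baseline_s)
      base <- mean(c(pre, post), na.rm = TRUE)
      sig <- exc_rip[pk] >= sig_frac * base
      attempts <- data.frame(time_s = (pk - 1) / rate, significant = sig)
    }
  }
  event$kind <- if (any(attempts$significant)) "OA" else "CA"
  event$n_attempts <- nrow(attempts)
  event$n_sig_attempts <- sum(attempts$significant)
  attr(event, "attempts") <- attempts
  event
}

#' Detect hypopnea candidate events
#'
#' Intervals with an airflow-excursion reduction of at least
#' `min_drop` (30%) --- but above the apnea threshold --- relative to the
#' 2-minute pre-event baseline, lasting 10-180 s, with a confirmation-
#' channel excursion drop of at least `confirm_min_drop` (10%). Intervals
#' overlapping detected apneas are trimmed or dropped (apneas take
#' precedence).
#'
#' @param exc airflow `excursion_track` or series.
#' @param confirm_exc confirmation-channel excursion series (`NULL`: as in
#'   [detect_apneas()]).
#' @param apneas events data.frame from [detect_apneas()].
#' @param rate sampling rate, Hz.
#' @param min_drop minimum excursion reduction (fraction).
#' @param apnea_flow_frac lower excursion bound (the apnea threshold).
#' @param min_dur_s,max_dur_s duration bounds, s.
#' @param baseline_s excursion baseline window, s.
#' @param confirm_min_drop,confirm_baseline_s confirmation rule.
#' @param require_confirmation drop unconfirmed events.
#' @return events data.frame (`kind` = NA).
#' @export
detect_hypopneas <- function(exc, confirm_exc, apneas = empty_events(),
                             rate = 20, min_drop = 0.30,
                             apnea_flow_frac = sqrt(0.10),
                             min_dur_s = 10, max_dur_s = 180,
                             baseline_s = 120, confirm_min_drop = 0.10,
                             confirm_baseline_s = 60,
                             require_confirmation = TRUE) {
  x <- if (inherits(exc, "excursion_track")) exc$excursion else as.numeric(exc)
  runs <- low_excursion_runs(x, rate, frac = 1 - min_drop,
                             baseline_s = baseline_s,
                             min_dur_s = min_dur_s, max_dur_s = max_dur_s)
  if (!nrow(runs)) return(empty_events())
  # apnea precedence: subtract apnea spans, keep the longest remainder
  keep <- logical(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    s <- runs$start_s[k]; e <- runs$end_s[k]
    if (nrow(apneas)) {
      for (j in seq_len(nrow(apneas))) {
        a0 <- apneas$onset_s[j]; a1 <- a0 + apneas$duration_s[j]
        if (a0 < e && a1 > s) {
          left <- a0 - s; right <- e - a1
          if (left >= right) e <- min(e, a0) else s <- max(s, a1)
        }
      }
    }
    runs$start_s[k] <- s; runs$end_s[k] <- e
    keep[k] <- (e - s) >= min_dur_s
  }
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(empty_events())
  ev <- data.frame(kind = NA_character_, onset_s = runs$start_s,
                   duration_s = runs$end_s - runs$start_s,
                   baseline_excursion = runs$baseline,
                   evidence = "", n_attempts = 0L, n_sig_attempts = 0L,
                   stringsAsFactors = FALSE)
  if (is.null(confirm_exc)) {
    if (require_confirmation) {
      if (nrow(ev)) warning("detect_hypopneas: no confirmation channel; ",
                            nrow(ev), " unconfirmed event(s) dropped")
      return(empty_events())
    }
    return(ev)
  }
  drops <- vapply(seq_len(nrow(ev)), function(k)
    confirm_drop(confirm_exc, rate, ev$onset_s[k],
                 ev$onset_s[k] + ev$duration_s[k], confirm_baseline_s),
    numeric(1))
  ev[drops >= confirm_min_drop, , drop = FALSE]
}

# inspiratory span of a cycle: onset to the downward zero-crossing of the
# flow after the inspiratory peak (sample indices)
cycle_insp_span <- function(flow, cycle, rate) {
  a <- max(1L, round(cycle$onset_s * rate) + 1L)
  b <- min(length(flow), round(cycle$end_s * rate))
  if (b <= a) return(NULL)
  pk <- min(b, max(a, round(cycle$insp_peak_s * rate) + 1L))
  seg <- flow[pk:b]
  dn <- which(seg <= 0)
  end <- if (length(dn)) pk + dn[1] - 1L else pk + (b - pk) %/% 2L
  c(a, min(end, b))
}

#' Detect snoring on one breathing cycle
#'
#' Compares the mean audio power between the inspiratory and expiratory
#' phases; snoring is called when inspiration exceeds expiration by
#' `power_ratio`.
#'
#' @param audio 20 Hz audio-power series.
#' @param cycle one-row `breath_cycles` entry.
#' @param flow airflow series (defines the phase boundary).
#' @param rate sampling rate, Hz.
#' @param power_ratio required inspiratory/expiratory power ratio.
#' @return logical flag.
#' @export
detect_snore <- function(audio, cycle, flow, rate = 20, power_ratio = 2) {
  span <- cycle_insp_span(flow, cycle, rate)
  if (is.null(span)) return(FALSE)
  a <- max(1L, round(cycle$onset_s * rate) + 1L)
  b <- min(length(audio), round(cycle$end_s * rate))
  insp <- audio[span[1]:span[2]]
  if (span[2] + 1L > b) return(FALSE)
  expi <- audio[(span[2] + 1L):b]
  mean(insp) > power_ratio * mean(expi)
}

#' Detect thoracoabdominal paradox on one breathing cycle
#'
#' Paradox is called when, within the cycle, the thoracic peak is
#' temporally closer to the abdominal valley than to the abdominal peak
#' (antiphase movement of the two bands).
#'
#' @param rip_thorax,rip_abdomen 20 Hz RIP series.
#' @param cycle one-row `breath_cycles` entry.
#' @param rate sampling rate, Hz.
#' @return logical flag (`FALSE` when either band has no usable extrema).
#' @export
detect_paradox <- function(rip_thorax, rip_abdomen, cycle, rate = 20) {
  a <- max(1L, round(cycle$onset_s * rate) + 1L)
  b <- min(length(rip_thorax), round(cycle$end_s * rate))
  if (b - a < 4) return(FALSE)
  th <- rip_thorax[a:b]; ab <- rip_abdomen[a:b]
  if (stats::sd(th) <= .Machine$double.eps ||
      stats::sd(ab) <= .Machine$double.eps) return(FALSE)
  t_th_pk <- which.max(th)
  t_ab_pk <- which.max(ab)
  t_ab_vl <- which.min(ab)
  abs(t_th_pk - t_ab_vl) < abs(t_th_pk - t_ab_pk)
}

#' Type a hypopnea as obstructive or central
#'
#' Obstructive when any cycle of the event shows snoring, paradox or
#' inspiratory flow limitation; central when none does. The evidence set
#' is recorded. Flow-limitation evidence alone must appear on at least
#' `min_ifl_cycles` cycles: the shape classifier sees one noisy
#' inspiration at a time, and a single-cycle call is not robust evidence
#' of obstruction.
#'
#' @param event one-row events data.frame.
#' @param snore,paradox,ifl logical vectors, one element per cycle of the
#'   event.
#' @param min_ifl_cycles minimum flow-limited cycles for ifl evidence.
#' @return the event row with `kind` and `evidence` set.
#' @export
classify_hypopnea <- function(event, snore, paradox, ifl,
                              min_ifl_cycles = 2L) {
  ev <- c(if (any(snore)) "snore", if (any(paradox)) "paradox",
          if (sum(ifl) >= min_ifl_cycles) "ifl")
  event$kind <- if (length(ev)) "OH" else "CH"
  event$evidence <- paste(ev, collapse = ",")
  event
}

#' Detect and classify all sleep-disordered-breathing events
#'
#' Runs apnea and hypopnea detection on the airflow excursion, types each
#' apnea by significant RIP attempts and each hypopnea by
#' snore/paradox/flow-limitation evidence, and labels the breathing cycles
#' with the event kinds.
#'
#' @param rec preprocessed `polygraph_record`.
#' @param cycles `breath_cycles` from [detect_breath_onsets()].
#' @param exc airflow `excursion_track`.
#' @param config `events` section of [default_config()].
#' @param ifl_model optional trained `ifl_model`; `NULL` disables the
#'   flow-limitation criterion.
#' @param rate sampling rate, Hz.
#' @return list with `events` (data.frame, sorted by onset), `cycles`
#'   (labels filled), and `attempts` (list of per-apnea attempt tables).
#' @export
detect_events <- function(rec, cycles, exc, config = default_config()$events,
                          ifl_model = NULL, rate = 20) {
  flow <- rec$vsource
  confirm <- if (!is.null(rec$derived$thermistance))
    rec$derived$thermistance else rec$derived$rip_flow
  confirm_exc <- channel_excursion(confirm, rate)
  thorax <- rec$derived$rip_thorax
  abdomen <- rec$derived$rip_abdomen
  exc_th <- channel_excursion(thorax, rate)
  exc_ab <- channel_excursion(abdomen, rate)

  apneas <- detect_apneas(exc, confirm_exc, rate,
                          flow_frac = config$apnea_flow_frac,
                          min_dur_s = config$min_dur_s,
                          max_dur_s = config$max_dur_s,
                          confirm_min_drop = config$confirm_drop_apnea,
                          confirm_baseline_s = config$confirm_baseline_s)
  attempts <- list()
  if (nrow(apneas)) {
    out <- vector("list", nrow(apneas))
    for (k in seq_len(nrow(apneas))) {
      evk <- apneas[k, , drop = FALSE]
      ref <- select_reference_rip(thorax, abdomen,
                                  list(start_s = evk$onset_s,
                                       end_s = evk$onset_s + evk$duration_s),
                                  rate)
      if (ref$flat) {
        evk$kind <- "CA"
        attempts[[k]] <- data.frame(time_s = numeric(0),
                                    significant = logical(0))
      } else {
        ch <- if (ref$channel == "rip_thorax") thorax else abdomen
        ce <- if (ref$channel == "rip_thorax") exc_th else exc_ab
        evk <- classify_apnea(evk, ch, ce, rate,
                              sig_frac = config$attempt_sig_frac,
                              baseline_s = config$attempt_baseline_s)
        attempts[[k]] <- attr(evk, "attempts")
      }
      out[[k]] <- evk
    }
    apneas <- do.call(rbind, out)
  }

  hypopneas <- detect_hypopneas(exc, confirm_exc, apneas, rate,
                                min_drop = config$hypopnea_drop,
                                apnea_flow_frac = config$apnea_flow_frac,
                                min_dur_s = config$min_dur_s,
                                max_dur_s = config$max_dur_s,
                                confirm_min_drop = config$confirm_drop_hypopnea,
                                confirm_baseline_s = config$confirm_baseline_s)
  if (nrow(hypopneas)) {
    amp_bl <- rolling_pre_baseline(exc$upper_env, rate, 120)
    out <- vector("list", nrow(hypopneas))
    for (k in seq_len(nrow(hypopneas))) {
      evk <- hypopneas[k, , drop = FALSE]
      t1 <- evk$onset_s + evk$duration_s
      inside <- which(cycles$onset_s < t1 &
                      cycles$end_s > evk$onset_s)
      sn <- pa <- fl <- logical(length(inside))
      for (j in seq_along(inside)) {
        cy <- cycles[inside[j], , drop = FALSE]
        sn[j] <- detect_snore(rec$derived$audio, cy, flow, rate,
                              config$snore_power_ratio)
        pa[j] <- detect_paradox(thorax, abdomen, cy, rate)
        if (!is.null(ifl_model)) {
          span <- cycle_insp_span(flow, cy, rate)
          if (!is.null(span) && span[2] - span[1] >= 7) {
            bl_amp <- amp_bl[max(1L, round(cy$onset_s * rate))]
            ft <- extract_ifl_features(pmax(flow[span[1]:span[2]], 0), bl_amp)
            fl[j] <- classify_ifl(ft, ifl_model)
          }
        }
      }
      out[[k]] <- classify_hypopnea(evk, sn, pa, fl)
    }
    hypopneas <- do.call(rbind, out)
  }

  events <- rbind(apneas, hypopneas)
  if (nrow(events)) {
    o <- order(events$onset_s)
    events <- events[o, , drop = FALSE]
    rownames(events) <- NULL
    for (k in seq_len(nrow(events))) {
      t1 <- events$onset_s[k] + events$duration_s[k]
      hit <- cycles$onset_s < t1 & cycles$end_s > events$onset_s[k]
      cycles$label[hit] <- events$kind[k]
    }
  }
  list(events = events, cycles = cycles, attempts = attempts)
}

# excursion series of an auxiliary channel (confirmation or RIP band);
# falls back to a rolling amplitude proxy when too few extrema exist
channel_excursion <- function(x, rate = 20) {
  if (is.null(x)) return(NULL)
  pv <- detect_peaks_valleys(x, rate)
  if (length(pv$peaks) >= 2 && length(pv$valleys) >= 2)
    return(compute_excursion(x, pv$peaks, pv$valleys, rate)$excursion)
  m <- stats::runmed(x, 1 + 2 * round(2 * rate))
  abs(x - m)
}

#' Apnea-hypopnea summary indices
#'
#' Events per hour of analysed (stable) recording time: AHI (all events),
#' AI (apneas), HI (hypopneas).
#'
#' @param events events data.frame.
#' @param hours analysed time in hours (e.g. total stable time).
#' @return list with `ahi`, `ai`, `hi`, `n_events`, `hours`.
#' @export
ahi_summary <- function(events, hours) {
  stopifnot(hours > 0)
  is_ap <- events$kind %in% c("OA", "CA")
  is_hy <- events$kind %in% c("OH", "CH")
  list(ahi = (sum(is_ap) + sum(is_hy)) / hours,
       ai = sum(is_ap) / hours, hi = sum(is_hy) / hours,
       n_events = nrow(events), hours = hours)
}

#' Export events
#'
#' CSV (one row per event) or a JSON annotation track including the AHI
#' summary.
#'
#' @param events events data.frame.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param hours analysed hours for the JSON summary.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("csv", "json"),
                         hours = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(events, path, row.names = FALSE)
  } else {
    payload <- list(events = events)
    if (!is.null(hours)) payload$summary <- ahi_summary(events, hours)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
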