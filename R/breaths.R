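# Breath identification: AMPD extrema over 3-minute moving windows, rescue
# of missed cycles, peak/valley envelopes and their excursion, detection of
# highly reduced excursion segments, and breath onsets (flow zero-crossings
# outside reduced segments, reference-RIP valleys inside them).

#' Detect inspiratory peaks and expiratory valleys
#'
#' AMPD is applied to 3-minute moving windows (hop half a window); valleys
#' come from AMPD on the negated signal. Window results are stitched with
#' duplicate suppression (extrema within `dedup_s` of an accepted one are
#' dropped) and reconciled so peaks and valleys strictly alternate: of two
#' consecutive same-type extrema the more extreme one is kept.
#'
#' @param flow preprocessed airflow series.
#' @param rate sampling rate, Hz.
#' @param window_s window length, s (default 180; holds roughly 45 cycles
#'   at Ttot = 4 s and 72 at Ttot = 2.5 s).
#' @param hop_s window hop, s.
#' @param max_scale_s largest AMPD scale, s (longest plausible half-period).
#' @param dedup_s duplicate-suppression radius, s.
#' @return list with integer index vectors `peaks` and `valleys`.
#' @export
detect_peaks_valleys <- function(flow, rate = 20, window_s = 180, hop_s = 90,
                                 max_scale_s = 10, dedup_s = 0.25) {
  n <- length(flow)
  if (n == 0) return(list(peaks = integer(0), valleys = integer(0)))
  win <- round(window_s * rate)
  hop <- round(hop_s * rate)
  max_scale <- round(max_scale_s * rate)
  starts <- if (n <= win) 1L else unique(c(seq(1L, n - win, by = hop), n - win + 1L))

  collect <- function(sgn) {
    acc <- integer(0)
    for (st in starts) {
      w <- flow[st:min(st + win - 1L, n)]
      acc <- c(acc, ampd(sgn * w, max_scale = max_scale) + st - 1L)
    }
    acc <- sort(unique(acc))
    dedup_indices(acc, round(dedup_s * rate))
  }
  peaks <- collect(1)
  valleys <- collect(-1)
  reconcile_alternation(flow, peaks, valleys)
}

dedup_indices <- function(idx, radius) {
  if (length(idx) < 2) return(idx)
  keep <- c(TRUE, diff(idx) > radius)
  idx[keep]
}

# enforce strict peak/valley alternation, keeping the more extreme of
# consecutive same-type extrema
reconcile_alternation <- function(flow, peaks, valleys) {
  if (!length(peaks) || !length(valleys))
    return(list(peaks = peaks, valleys = valleys))
  ev <- rbind(data.frame(i = peaks, type = 1L), data.frame(i = valleys, type = -1L))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  last <- 1L
  for (j in seq_len(nrow(ev))[-1]) {
    if (ev$type[j] == ev$type[last]) {
      better_j <- (ev$type[j] == 1L && flow[ev$i[j]] > flow[ev$i[last]]) ||
                  (ev$type[j] == -1L && flow[ev$i[j]] < flow[ev$i[last]])
      if (better_j) { keep[last] <- FALSE; last <- j } else keep[j] <- FALSE
    } else last <- j
  }
  ev <- ev[keep, ]
  list(peaks = ev$i[ev$type == 1L], valleys = ev$i[ev$type == -1L])
}

#' Rescue missed breathing cycles
#'
#' Gaps between consecutive detected peaks longer than
#' `gap_factor * mean_ttot` are scanned for oscillations around zero whose
#' peak-to-valley excursion exceeds `amp_frac * mean_amp`; qualifying
#' oscillations are inserted as peak/valley pairs.
#'
#' @param flow airflow series.
#' @param peaks,valleys extrema indices from [detect_peaks_valleys()].
#' @param rate sampling rate, Hz.
#' @param mean_ttot_s,mean_amp recent unobstructed cycle statistics
#'   (defaults: medians from the detected extrema).
#' @param amp_frac amplitude threshold as a fraction of `mean_amp`.
#' @param gap_factor gap length triggering a scan, in units of `mean_ttot_s`.
#' @return updated list with `peaks` and `valleys`.
#' @export
rescue_missed_cycles <- function(flow, peaks, valleys, rate = 20,
                                 mean_ttot_s = NULL, mean_amp = NULL,
                                 amp_frac = 0.2, gap_factor = 1.5) {
  if (length(peaks) < 3) return(list(peaks = peaks, valleys = valleys))
  if (is.null(mean_ttot_s)) mean_ttot_s <- median(diff(peaks)) / rate
  if (is.null(mean_amp)) {
    env_hi <- median(flow[peaks]); env_lo <- median(flow[valleys])
    mean_amp <- env_hi - env_lo
  }
  thr <- amp_frac * mean_amp
  new_p <- integer(0); new_v <- integer(0)
  gap_len <- gap_factor * mean_ttot_s * rate
  for (g in which(diff(peaks) > gap_len)) {
    a <- peaks[g]; b <- peaks[g + 1L]
    seg <- flow[a:b]
    sgn <- sign(seg); sgn[sgn == 0] <- 1
    cross <- which(diff(sgn) != 0)
    if (length(cross) < 2) next
    bounds <- c(1L, cross, length(seg))
    for (j in seq_len(length(bounds) - 1L)) {
      lo <- bounds[j] + 1L; hi <- bounds[j + 1L]
      if (hi - lo < 0.2 * mean_ttot_s * rate) next
      lobe <- seg[lo:hi]
      if (max(lobe) >= thr / 2 && all(lobe >= 0)) {
        cand <- a + lo - 2L + which.max(lobe)
        if (min(abs(cand - c(peaks, new_p))) > 0.25 * rate &&
            max(lobe) - min(seg) >= thr)
          new_p <- c(new_p, cand)
      } else if (min(lobe) <= -thr / 2 && all(lobe <= 0)) {
        cand <- a + lo - 2L + which.min(lobe)
        if (!length(valleys) || min(abs(cand - c(valleys, new_v))) > 0.25 * rate)
          if (max(seg) - min(lobe) >= thr) new_v <- c(new_v, cand)
      }
    }
  }
  reconcile_alternation(flow, sort(c(peaks, new_p)), sort(c(valleys, new_v)))
}

#' Upper/lower envelopes and excursion of the airflow
#'
#' Envelopes are shape-preserving piecewise-cubic (PCHIP) interpolants
#' through the peak (respectively valley) samples, constant-extrapolated
#' beyond the first and last extremum. The excursion is their difference,
#' clipped at zero.
#'
#' @param flow airflow series.
#' @param peaks,valleys extrema indices.
#' @param rate sampling rate, Hz.
#' @return object of class `excursion_track`: `upper_env`, `lower_env`,
#'   `excursion` (series), `peaks`, `valleys`, `rate`.
#' @export
compute_excursion <- function(flow, peaks, valleys, rate = 20) {
  if (length(peaks) < 2 || length(valleys) < 2)
    stop("compute_excursion: need at least two peaks and two valleys")
  n <- length(flow)
  env <- function(idx) {
    x <- seq_len(n)
    xi <- pmin(pmax(x, idx[1]), idx[length(idx)])
    pracma::pchip(idx, flow[idx], xi)
  }
  upper <- env(peaks)
  lower <- env(valleys)
  structure(list(upper_env = upper, lower_env = lower,
                 excursion = pmax(upper - lower, 0),
                 peaks = peaks, valleys = valleys, rate = rate),
            class = "excursion_track")
}

# causal rolling mean over the preceding `window_s` seconds (the sample
# itself excluded); the first sample falls back to its own value
rolling_pre_baseline <- function(x, rate, window_s = 120) {
  n <- length(x)
  w <- round(window_s * rate)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - w, 1L)
  cnt <- i - lo
  out <- (cs[i] - cs[lo]) / pmax(cnt, 1L)
  out[cnt == 0] <- x[cnt == 0]
  out
}

# maximal runs where `x` stays at or below frac * (pre-run baseline).
# Two passes: candidate runs against a causal rolling baseline, then each
# run re-evaluated against the frozen mean of the `baseline_s` window
# preceding its start, and expanded/merged.
low_excursion_runs <- function(x, rate, frac, baseline_s = 120,
                               min_dur_s = 0, max_dur_s = Inf,
                               strict_min = FALSE) {
  n <- length(x)
  bl <- rolling_pre_baseline(x, rate, baseline_s)
  mask <- x <= frac * bl
  if (!any(mask)) return(empty_runs())
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  w <- round(baseline_s * rate)
  out <- data.frame(start = integer(0), end = integer(0), baseline = numeric(0))
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]; e <- runs$end[k]
    pre <- x[max(1L, s - w):max(1L, s - 1L)]
    b <- if (length(pre)) mean(pre) else bl[s]
    while (s > 1L && x[s - 1L] <= frac * b) s <- s - 1L
    while (e < n && x[e + 1L] <= frac * b) e <- e + 1L
    if (nrow(out) && s <= out$end[nrow(out)] + 1L) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], e)
    } else out <- rbind(out, data.frame(start = s, end = e, baseline = b))
  }
  dur <- (out$end - out$start + 1L) / rate
  keep <- if (strict_min) dur > min_dur_s else dur >= min_dur_s
  keep <- keep & dur <= max_dur_s
  out <- out[keep, , drop = FALSE]
  data.frame(start_s = (out$start - 1) / rate,
             end_s = out$end / rate,
             baseline = out$baseline)
}

empty_runs <- function()
  data.frame(start_s = numeric(0), end_s = numeric(0), baseline = numeric(0))

#' Find highly reduced excursion segments
#'
#' Maximal intervals where the airflow excursion falls to at most
#' `1 - drop` (default 35%) of the 2-minute pre-event baseline, lasting
#' longer than `min_dur_s` (4 s; long enough to contain a single apneic
#' cycle plus the delay from the preceding breath's valley).
#'
#' @param exc an `excursion_track` (or bare excursion series).
#' @param rate sampling rate, Hz.
#' @param drop minimum relative reduction (default 0.65).
#' @param min_dur_s minimum duration, s (strict).
#' @param baseline_s pre-event baseline window, s.
#' @return data.frame `start_s`, `end_s`, `baseline`.
#' @export
find_reduced_excursion_segments <- function(exc, rate = 20, drop = 0.65,
                                            min_dur_s = 4, baseline_s = 120) {
  x <- if (inherits(exc, "excursion_track")) exc$excursion else as.numeric(exc)
  low_excursion_runs(x, rate, frac = 1 - drop, baseline_s = baseline_s,
                     min_dur_s = min_dur_s, strict_min = TRUE)
}

#' Choose the reference RIP channel for a reduced-excursion segment
#'
#' The reference is the RIP band with the larger relative amplitude
#' modulation during the segment, each normalized by its own modulation
#' over the `baseline_s` window preceding the segment. Ties go to the
#' thorax. If both bands are essentially flat relative to baseline the
#' segment is flagged central-type (no detectable attempts).
#'
#' @param rip_thorax,rip_abdomen 20 Hz RIP series.
#' @param segment list or row with `start_s`, `end_s`.
#' @param rate sampling rate, Hz.
#' @param baseline_s pre-segment baseline window, s.
#' @param flat_frac both-ratios-below which the segment is flagged flat.
#' @return list with `channel` ("rip_thorax"/"rip_abdomen"), `ratio_thorax`,
#'   `ratio_abdomen`, `flat` (logical).
#' @export
select_reference_rip <- function(rip_thorax, rip_abdomen, segment, rate = 20,
                                 baseline_s = 120, flat_frac = 0.05) {
  i0 <- max(1L, round(segment$start_s * rate) + 1L)
  i1 <- min(length(rip_thorax), round(segment$end_s * rate))
  p0 <- max(1L, i0 - round(baseline_s * rate))
  modulation <- function(x) if (length(x) < 2) 0 else mean(abs(x - mean(x)))
  ratio <- function(ch) {
    seg <- modulation(ch[i0:i1])
    pre <- modulation(ch[p0:max(p0, i0 - 1L)])
    if (pre <= .Machine$double.eps) return(0)
    seg / pre
  }
  rt <- ratio(rip_thorax); ra <- ratio(rip_abdomen)
  list(channel = if (rt >= ra) "rip_thorax" else "rip_abdomen",
       ratio_thorax = rt, ratio_abdomen = ra,
       flat = (rt < flat_frac && ra < flat_frac))
}

#' Detect breath onsets and assemble breathing cycles
#'
#' Outside reduced-excursion segments each onset is the expiratory-to-
#' inspiratory zero-crossing of the airflow between a valley and the
#' following peak (falling back to the point of maximum slope when no
#' crossing exists). Inside reduced segments onsets are taken from the
#' valleys of the reference RIP band; segments where both bands are flat
#' (central-type) contribute no onsets. Cycles are built onset-to-onset.
#'
#' @param flow airflow series.
#' @param exc an `excursion_track` for `flow`.
#' @param rip_thorax,rip_abdomen 20 Hz RIP series.
#' @param reduced data.frame of reduced segments
#'   ([find_reduced_excursion_segments()]).
#' @param rate sampling rate, Hz.
#' @param stable optional `stable_periods`; cycles are restricted to (and
#'   never span) stable intervals.
#' @return data.frame of class `breath_cycles`: `onset_s`, `end_s`,
#'   `ttot_s`, `insp_peak_s`, `exp_valley_s`, `amplitude`, `onset_source`,
#'   `label`.
#' @export
detect_breath_onsets <- function(flow, exc, rip_thorax = NULL,
                                 rip_abdomen = NULL, reduced = empty_runs(),
                                 rate = 20, stable = NULL) {
  n <- length(flow)
  if (n == 0) return(empty_cycles())
  peaks <- exc$peaks; valleys <- exc$valleys
  in_reduced <- function(t)
    nrow(reduced) > 0 && any(t >= reduced$start_s & t < reduced$end_s)

  onsets <- numeric(0); src <- character(0)
  # flow-based onsets: valley -> next peak
  for (v in valleys) {
    p <- peaks[peaks > v]
    if (!length(p)) next
    p <- p[1]
    tv <- (v - 1) / rate
    if (in_reduced(tv) && in_reduced((p - 1) / rate)) next
    seg <- flow[v:p]
    sgn <- sign(seg); sgn[sgn == 0] <- 1
    cr <- which(sgn[-length(sgn)] < 0 & sgn[-1] >= 0)
    idx <- if (length(cr)) v + cr[length(cr)] else v + which.max(diff(seg)) - 1L
    onsets <- c(onsets, (idx - 1) / rate)
    src <- c(src, "flow")
  }
  # RIP-based onsets inside reduced segments
  if (nrow(reduced) && !is.null(rip_thorax) && !is.null(rip_abdomen)) {
    for (k in seq_len(nrow(reduced))) {
      seg <- reduced[k, ]
      ref <- select_reference_rip(rip_thorax, rip_abdomen, seg, rate)
      if (ref$flat) next
      ch <- if (ref$channel == "rip_thorax") rip_thorax else rip_abdomen
      i0 <- max(1L, round(seg$start_s * rate) + 1L)
      i1 <- min(length(ch), round(seg$end_s * rate))
      if (i1 - i0 < rate) next
      vv <- ampd(-ch[i0:i1], max_scale = round(10 * rate)) + i0 - 1L
      if (length(vv)) {
        onsets <- c(onsets, (vv - 1) / rate)
        src <- c(src, rep(ref$channel, length(vv)))
      }
    }
  }
  if (!length(onsets)) return(empty_cycles())
  o <- order(onsets)
  onsets <- onsets[o]; src <- src[o]
  keep <- c(TRUE, diff(onsets) > 0.3)   # drop near-duplicates after merge
  onsets <- onsets[keep]; src <- src[keep]

  build <- function(ons, srcs) {
    if (length(ons) < 2) return(empty_cycles())
    m <- length(ons) - 1L
    df <- data.frame(onset_s = ons[-length(ons)], end_s = ons[-1],
                     onset_source = srcs[-length(srcs)],
                     stringsAsFactors = FALSE)
    df$ttot_s <- df$end_s - df$onset_s
    df$insp_peak_s <- NA_real_; df$exp_valley_s <- NA_real_
    df$amplitude <- NA_real_
    for (i in seq_len(m)) {
      a <- round(df$onset_s[i] * rate) + 1L
      b <- min(n, round(df$end_s[i] * rate))
      if (b <= a) { df$amplitude[i] <- 0; next }
      w <- flow[a:b]
      df$insp_peak_s[i] <- (a + which.max(w) - 2) / rate
      df$exp_valley_s[i] <- (a + which.min(w) - 2) / rate
      df$amplitude[i] <- max(w) - min(w)
    }
    df
  }

  if (is.null(stable)) {
    cycles <- build(onsets, src)
  } else {
    parts <- list()
    for (k in seq_len(nrow(stable$intervals))) {
      s <- stable$intervals$start_s[k]; e <- stable$intervals$end_s[k]
      sel <- onsets >= s & onsets < e
      parts[[k]] <- build(onsets[sel], src[sel])
    }
    cycles <- do.call(rbind, parts)
    if (is.null(cycles)) cycles <- empty_cycles()
  }
  cycles$label <- "normal"
  rownames(cycles) <- NULL
  class(cycles) <- c("breath_cycles", "data.frame")
  cycles
}

empty_cycles <- function() {
  df <- data.frame(onset_s = numeric(0), end_s = numeric(0),
                   onset_source = character(0), ttot_s = numeric(0),
                   insp_peak_s = numeric(0), exp_valley_s = numeric(0),
                   amplitude = numeric(0), label = character(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("breath_cycles", "data.frame")
  df
}

#' Export breathing cycles as CSV
#'
#' @param cycles a `breath_cycles` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycles_csv <- function(cycles, path) {
  utils::write.csv(as.data.frame(cycles)[, c("onset_s", "ttot_s", "amplitude",
                                             "onset_source", "label")],
                   path, row.names = FALSE)
  invisible(path)
}
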