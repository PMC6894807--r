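# Bench command synthesis: the central-drive airflow estimate (vcc), the
# per-cycle volume equilibration the piston hardware requires, the
# muscular-effort pressure from the single-compartment lung equation
#   dPmus = -Vcc / C - R * vcc
# and the Starling chamber pressure reproducing each obstructive cycle's
# source amplitude.

#' Single-compartment lung model
#'
#' @param compliance_ml_cmh2o lung compliance, mL/cmH2O (default 80).
#' @param resistance_cmh2o_l_s airway resistance, cmH2O/(L/s) (default
#'   7.25; the upper airway is represented by the Starling resistor, not
#'   here).
#' @param rate command rate, Hz.
#' @return object of class `lung_model` (compliance converted to L/cmH2O
#'   internally).
#' @export
lung_model <- function(compliance_ml_cmh2o = 80, resistance_cmh2o_l_s = 7.25,
                       rate = 20) {
  stopifnot(compliance_ml_cmh2o > 0, resistance_cmh2o_l_s >= 0)
  structure(list(C = compliance_ml_cmh2o / 1000, R = resistance_cmh2o_l_s,
                 rate = rate),
            class = "lung_model")
}

#' Starling resistor model
#'
#' Waterfall surrogate of the collapsible tube: flow is unrestricted while
#' the effective chamber pressure is at or below the downstream (ambient)
#' pressure; above it, the admissible peak flow is
#' `max(0, pus - pch) / rus`. Attenuation is therefore non-increasing in
#' the chamber pressure and reaches full occlusion at `pch = pus`.
#'
#' @param pus_cmh2o upstream source pressure, cmH2O (default 4, the
#'   minimal pressure delivered by APAP devices).
#' @param rus_cmh2o_l_s upstream resistance, cmH2O/(L/s).
#' @param pch_min_cmh2o fully open chamber pressure.
#' @param regulator_tau_s time constant of the chamber-pressure regulator.
#' @param transition_artifact emulate the brief flow spike of the
#'   collapsing tube at obstruction onset.
#' @return object of class `starling_model`.
#' @export
starling_model <- function(pus_cmh2o = 4, rus_cmh2o_l_s = 2,
                           pch_min_cmh2o = 0, regulator_tau_s = 0.3,
                           transition_artifact = FALSE) {
  stopifnot(pus_cmh2o > 0, rus_cmh2o_l_s > 0)
  structure(list(pus = pus_cmh2o, rus = rus_cmh2o_l_s,
                 pch_min = pch_min_cmh2o, tau = regulator_tau_s,
                 artifact = transition_artifact, calibration = NULL),
            class = "starling_model")
}

# rolling per-cycle amplitude baseline, frozen at the entry of each
# obstructive run so the whole event uses its pre-event value
cycle_amp_baseline <- function(cycles, window_s = 120) {
  n <- nrow(cycles)
  bl <- numeric(n)
  for (i in seq_len(n)) {
    sel <- cycles$onset_s >= cycles$onset_s[i] - window_s &
           cycles$onset_s < cycles$onset_s[i]
    bl[i] <- if (any(sel)) mean(cycles$amplitude[sel]) else cycles$amplitude[i]
  }
  # freeze the baseline across each obstructive run at its entry value, so
  # a whole event is reconstructed against its pre-event amplitude
  obstructive <- cycles$label %in% c("OA", "OH")
  if (any(obstructive)) {
    r <- rle(obstructive)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) bl[starts[k]:ends[k]] <- bl[starts[k]]
  }
  bl
}

#' Estimate the central-drive airflow
#'
#' For cycles in normal breathing or central events the drive airflow
#' `vcc` is the source airflow itself. For cycles inside obstructive
#' events the drive is reconstructed as a sinusoid: a half-sine
#' inspiration with peak equal to the 2-minute pre-event amplitude
#' baseline over the cycle's inspiratory time, and a volume-balancing
#' half-sine expiration over the remainder. Inspiratory time comes from
#' the airflow phase span for obstructive hypopneas and defaults to
#' `ti_frac * Ttot` for obstructive apneas (whose timing derives from the
#' reference RIP onsets).
#'
#' @param flow source airflow series.
#' @param cycles labelled `breath_cycles`.
#' @param rate sampling rate, Hz.
#' @param ti_frac default inspiratory fraction when not measurable.
#' @param baseline_s amplitude baseline window, s.
#' @return list with `vcc` (series, zero outside cycles), and `cycles`
#'   augmented with `trigger_i` (sample index), `ti_s`, `te_s`, `vcc_amp`,
#'   `target_amp` (amplitudes, refined to peak-to-valley measures by
#'   [build_commands()]) and `reconstructed` (whether the sinusoidal
#'   branch was used).
#' @export
estimate_vcc <- function(flow, cycles, rate = 20, ti_frac = 0.4,
                         baseline_s = 120) {
  n <- length(flow)
  vcc <- numeric(n)
  m <- nrow(cycles)
  if (m == 0) return(list(vcc = vcc, cycles = cycles))
  bl <- cycle_amp_baseline(cycles, baseline_s)

  cycles$trigger_i <- pmax(1L, round(cycles$onset_s * rate) + 1L)
  cycles$ti_s <- NA_real_
  cycles$te_s <- NA_real_
  cycles$vcc_amp <- NA_real_
  cycles$target_amp <- NA_real_
  cycles$reconstructed <- FALSE

  for (i in seq_len(m)) {
    a <- cycles$trigger_i[i]
    b <- min(n, round(cycles$end_s[i] * rate))
    if (b <= a) next
    src <- flow[a:b]
    # transition cycles at event edges carry an obstructive label but are
    # not actually reduced; reconstructing them would inject a spurious
    # full-amplitude breath, so they are copied like normal cycles
    obstructive <- cycles$label[i] %in% c("OA", "OH") &&
      (max(src) - min(src)) < bl[i]
    cycles$reconstructed[i] <- obstructive
    cycles$target_amp[i] <- max(src, 0)
    if (!obstructive) {
      vcc[a:b] <- src
      cycles$vcc_amp[i] <- max(src, 0)
      span <- cycle_insp_span(flow, cycles[i, ], rate)
      ti <- if (!is.null(span)) (span[2] - span[1] + 1L) / rate else
        ti_frac * cycles$ttot_s[i]
      cycles$ti_s[i] <- ti
      cycles$te_s[i] <- cycles$ttot_s[i] - ti
      next
    }
    # obstructive: sinusoidal reconstruction at the pre-event baseline
    ttot <- (b - a + 1L) / rate
    if (cycles$label[i] == "OH") {
      span <- cycle_insp_span(flow, cycles[i, ], rate)
      ti <- if (!is.null(span)) (span[2] - span[1] + 1L) / rate else
        ti_frac * ttot
    } else ti <- ti_frac * ttot
    ti <- min(max(ti, 2 / rate), ttot - 2 / rate)
    te <- ttot - ti
    # excursion baseline -> inspiratory peak of the reconstructed drive
    a_base <- bl[i] * te / (ti + te)
    tau <- (seq.int(a, b) - a) / rate
    insp <- tau < ti
    w <- numeric(length(tau))
    w[insp] <- a_base * sin(pi * tau[insp] / ti)
    w[!insp] <- -a_base * (ti / te) * sin(pi * (tau[!insp] - ti) / te)
    vcc[a:b] <- w
    cycles$ti_s[i] <- ti
    cycles$te_s[i] <- te
    cycles$vcc_amp[i] <- a_base
  }
  list(vcc = vcc, cycles = cycles)
}

#' Equilibrate inspiratory and expiratory volumes of one cycle
#'
#' The bench piston must return to its start position every cycle, so the
#' inspiratory and expiratory volumes must match. The lesser-volume phase
#' is scaled by a single factor (extremum positions unchanged) until the
#' volumes agree within `tol_l`.
#'
#' @param cycle_vcc drive airflow of one cycle (numeric vector).
#' @param rate sampling rate, Hz.
#' @param tol_l volume tolerance, L.
#' @return the balanced cycle; attribute `flagged` is TRUE when a phase is
#'   absent and the cycle is returned unchanged.
#' @export
equilibrate_volumes <- function(cycle_vcc, rate = 20, tol_l = 1e-6) {
  x <- as.numeric(cycle_vcc)
  dt <- 1 / rate
  pos <- pmax(x, 0); neg <- pmin(x, 0)
  vi <- sum(pos) * dt
  ve <- -sum(neg) * dt
  if (vi <= tol_l || ve <= tol_l) {
    attr(x, "flagged") <- TRUE
    return(x)
  }
  if (abs(vi - ve) <= tol_l) {
    attr(x, "flagged") <- FALSE
    return(x)
  }
  if (vi > ve) neg <- neg * (vi / ve) else pos <- pos * (ve / vi)
  out <- pos + neg
  attr(out, "flagged") <- FALSE
  out
}

#' Muscular-effort pressure from the drive airflow
#'
#' Integrates the drive airflow to the instantaneous lung volume
#' (trapezoidal rule, reset to zero at each cycle trigger) and applies the
#' single-compartment relation `pmus = -V/C - R * vcc` (cmH2O; flow in
#' L/s, volume in L).
#'
#' @param vcc drive airflow series, L/s.
#' @param lung a [lung_model()].
#' @param triggers sample indices of cycle starts (volume resets); default
#'   a single cycle starting at the first sample.
#' @return pressure series, cmH2O, with attribute `volume` (L).
#' @export
compute_pmus <- function(vcc, lung, triggers = 1L) {
  stopifnot(inherits(lung, "lung_model"))
  n <- length(vcc)
  dt <- 1 / lung$rate
  v <- numeric(n)
  is_trig <- logical(n)
  is_trig[triggers[triggers >= 1 & triggers <= n]] <- TRUE
  for (i in seq_len(n)) {
    if (is_trig[i] || i == 1L) v[i] <- 0
    else v[i] <- v[i - 1L] + dt * (vcc[i] + vcc[i - 1L]) / 2
  }
  pmus <- -v / lung$C - lung$R * vcc
  attr(pmus, "volume") <- v
  pmus
}

#' Calibrate the Starling attenuation law
#'
#' Sweeps the chamber pressure over a grid, drives the resistor with
#' reference half-sine cycles at several amplitudes (steady chamber
#' pressure, no regulator lag), and records the output/input amplitude
#' ratio separately for inspiration and expiration. The resulting
#' per-phase tables are monotone in the chamber pressure and invertible on
#' [0, 1].
#'
#' @param model a [starling_model()].
#' @param amplitudes reference amplitudes, L/s.
#' @param pch_grid chamber-pressure grid, cmH2O.
#' @param rate waveform rate, Hz.
#' @return the model with a `calibration` element: list of `pch_grid`,
#'   `amplitudes`, `insp`, `exp` (ratio matrices, amplitudes x pch).
#' @export
calibrate_starling <- function(model, amplitudes = seq(0.1, 1, by = 0.15),
                               pch_grid = NULL, rate = 20) {
  stopifnot(inherits(model, "starling_model"))
  if (is.null(pch_grid))
    pch_grid <- seq(model$pch_min, model$pus * 1.1, length.out = 45)
  ttot <- 4; ti <- 1.6
  t <- seq(0, ttot - 1 / rate, by = 1 / rate)
  ri <- matrix(NA_real_, length(amplitudes), length(pch_grid))
  re <- ri; rpv <- ri
  for (ai in seq_along(amplitudes)) {
    a <- amplitudes[ai]
    wave <- ifelse(t < ti, a * sin(pi * t / ti),
                   -a * (ti / (ttot - ti)) * sin(pi * (t - ti) / (ttot - ti)))
    pv_in <- max(wave) - min(wave)
    for (pi_ in seq_along(pch_grid)) {
      tr <- simulate_starling(wave, pch_grid[pi_], model,
                              triggers = 1L, regulator_tau = 0, rate = rate)
      ri[ai, pi_] <- max(tr$vbench) / max(wave)
      re[ai, pi_] <- min(tr$vbench) / min(wave)
      rpv[ai, pi_] <- (max(tr$vbench) - min(tr$vbench)) / pv_in
    }
    if (any(diff(ri[ai, ]) > 1e-9) || any(diff(re[ai, ]) > 1e-9))
      stop("calibrate_starling: attenuation not monotone in pch")
  }
  model$calibration <- list(pch_grid = pch_grid, amplitudes = amplitudes,
                            insp = ri, exp = re, pv = rpv)
  model
}

#' Chamber pressure for a target amplitude ratio
#'
#' Inverts the calibrated attenuation law: for an obstructive cycle the
#' chamber pressure is the one at which a drive of amplitude `vcc_amp` is
#' attenuated to `target_amp`. Non-obstructive and central cycles use the
#' fully open minimum.
#'
#' @param obstructive logical: is the cycle obstructive.
#' @param vcc_amp drive amplitude, L/s (peak-to-valley for the default
#'   table, inspiratory peak or expiratory valley for the per-phase ones).
#' @param target_amp desired bench amplitude, L/s (same measure).
#' @param model a calibrated [starling_model()].
#' @param phase calibration table: `"pv"` (peak-to-valley, the amplitude
#'   measure of the cycle agreement analysis), `"insp"` or `"exp"`.
#' @return chamber pressure, cmH2O.
#' @export
compute_pch <- function(obstructive, vcc_amp, target_amp, model,
                        phase = c("pv", "insp", "exp")) {
  phase <- match.arg(phase)
  if (!obstructive) return(model$pch_min)
  if (is.null(model$calibration))
    stop("compute_pch: model not calibrated; see calibrate_starling()")
  ratio <- target_amp / vcc_amp
  if (!is.finite(ratio) || ratio > 1) {
    warning("compute_pch: amplitude ratio above 1; clamping to fully open")
    return(model$pch_min)
  }
  ratio <- max(ratio, 0)
  cal <- model$calibration
  tab <- switch(phase, pv = cal$pv, insp = cal$insp, exp = cal$exp)
  # nearest amplitude rows, inverse interpolation in each, then blend
  # table rows are indexed by the reference wave's inspiratory peak; its
  # peak-to-valley is (1 + Ti/Te) = 5/3 of that peak
  amp_ref <- if (phase == "pv") vcc_amp * 0.6 else vcc_amp
  ai <- findInterval(amp_ref, cal$amplitudes, all.inside = TRUE)
  rows <- unique(c(ai, min(ai + 1L, length(cal$amplitudes))))
  inv <- vapply(rows, function(r) {
    y <- tab[r, ]                       # non-increasing in pch
    if (ratio >= y[1])                  # boundary of the fully open plateau
      return(cal$pch_grid[max(which(y >= ratio))])
    j <- which(y <= ratio)[1]
    if (is.na(j)) return(cal$pch_grid[length(y)])
    y1 <- y[j - 1L]; y2 <- y[j]
    if (y1 <= y2) return(cal$pch_grid[j])
    cal$pch_grid[j - 1L] +
      (y1 - ratio) / (y1 - y2) * (cal$pch_grid[j] - cal$pch_grid[j - 1L])
  }, numeric(1))
  if (length(rows) == 2 && cal$amplitudes[rows[2]] > cal$amplitudes[rows[1]]) {
    w <- (amp_ref - cal$amplitudes[rows[1]]) /
         (cal$amplitudes[rows[2]] - cal$amplitudes[rows[1]])
    w <- min(max(w, 0), 1)
    inv[1] * (1 - w) + inv[2] * w
  } else inv[1]
}

#' Build the full bench command set
#'
#' Runs [estimate_vcc()], equilibrates every cycle, computes the
#' muscular-effort pressure with per-cycle volume resets, and assigns the
#' chamber pressure per cycle (calibrating the Starling model if needed).
#'
#' @param flow source airflow series.
#' @param cycles labelled `breath_cycles`.
#' @param lung a [lung_model()].
#' @param starling a [starling_model()] (calibrated or not).
#' @param rate sampling rate, Hz.
#' @param ti_frac default inspiratory fraction.
#' @return object of class `bench_command_set`: `t` (s), `vcc`, `pmus`
#'   (series), `cycles` (per-cycle table with `trigger_s`, `pch_cmh2o`,
#'   `ti_s`, `te_s`, `vcc_amp`, `target_amp`), `triggers` (sample
#'   indices), `lung`, `starling`.
#' @export
build_commands <- function(flow, cycles, lung = lung_model(),
                           starling = starling_model(), rate = 20,
                           ti_frac = 0.4) {
  if (is.null(starling$calibration)) starling <- calibrate_starling(starling)
  est <- estimate_vcc(flow, cycles, rate, ti_frac)
  vcc <- est$vcc
  cyc <- est$cycles
  n <- length(flow)
  m <- nrow(cyc)
  pch <- numeric(m)
  for (i in seq_len(m)) {
    a <- cyc$trigger_i[i]
    b <- min(n, round(cyc$end_s[i] * rate))
    if (b > a) vcc[a:b] <- equilibrate_volumes(vcc[a:b], rate)
    obstructive <- isTRUE(cyc$reconstructed[i])
    amp <- max(vcc[a:b]) - min(vcc[a:b])       # peak-to-valley drive
    target <- if (i <= nrow(cycles)) cycles$amplitude[i] else NA_real_
    cyc$vcc_amp[i] <- amp
    cyc$target_amp[i] <- target
    pch[i] <- if (!is.finite(amp) || amp <= 0) starling$pus else
      compute_pch(obstructive, amp, target, starling)
  }
  cyc$pch_cmh2o <- pch
  cyc$trigger_s <- (cyc$trigger_i - 1) / rate
  pmus <- compute_pmus(vcc, lung, triggers = cyc$trigger_i)
  structure(list(t = (seq_len(n) - 1) / rate, vcc = vcc,
                 pmus = as.numeric(pmus), cycles = cyc,
                 triggers = cyc$trigger_i, lung = lung,
                 starling = starling),
            class = "bench_command_set")
}

#' @export
print.bench_command_set <- function(x, ...) {
  cat("<bench_command_set>", nrow(x$cycles), "cycle(s),",
      length(x$vcc), "samples @", x$lung$rate, "Hz\n")
  invisible(x)
}

#' Export a bench command set
#'
#' Two files mirroring the hardware's digital inputs: a per-cycle CSV
#' (trigger time, chamber pressure, phase durations, amplitudes) and a
#' waveform CSV (time, muscular-effort pressure, drive airflow).
#'
#' @param commands a `bench_command_set`.
#' @param cycle_path,waveform_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_commands_csv <- function(commands, cycle_path, waveform_path) {
  utils::write.csv(commands$cycles[, c("trigger_s", "pch_cmh2o", "ti_s",
                                       "te_s", "vcc_amp", "target_amp")],
                   cycle_path, row.names = FALSE)
  utils::write.csv(data.frame(t = commands$t, pmus = commands$pmus,
                              vcc = commands$vcc),
                   waveform_path, row.names = FALSE)
  invisible(c(cycle_path, waveform_path))
}
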