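# Virtual bench: the active lung (single compartment, driven by the
# muscular-effort pressure) in series with the Starling resistor surrogate
# and its first-order chamber-pressure regulator.

#' Simulate the active lung
#'
#' Solves `R * vdot + V/C = -pmus` for the airflow at the command rate,
#' with the lung volume reset to zero at each cycle trigger. The
#' integration uses the implicit trapezoidal scheme, the exact discrete
#' inverse of the volume integration in [compute_pmus()], so a command
#' round trip reproduces the drive airflow to machine precision.
#'
#' @param pmus muscular-effort pressure series, cmH2O.
#' @param lung a [lung_model()].
#' @param triggers sample indices of cycle starts.
#' @return airflow series, L/s.
#' @export
simulate_lung <- function(pmus, lung, triggers = 1L) {
  stopifnot(inherits(lung, "lung_model"))
  n <- length(pmus)
  dt <- 1 / lung$rate
  flow <- numeric(n)
  vol <- numeric(n)
  is_trig <- logical(n)
  is_trig[triggers[triggers >= 1 & triggers <= n]] <- TRUE
  h <- dt / (2 * lung$C)
  for (i in seq_len(n)) {
    if (is_trig[i] || i == 1L) {
      flow[i] <- -pmus[i] / lung$R
      vol[i] <- 0
    } else {
      flow[i] <- (-pmus[i] - vol[i - 1L] / lung$C - h * flow[i - 1L]) /
        (lung$R + h)
      vol[i] <- vol[i - 1L] + dt * (flow[i] + flow[i - 1L]) / 2
    }
  }
  attr(flow, "volume") <- vol
  flow
}

#' Simulate the Starling resistor
#'
#' The commanded chamber pressure (one value per cycle, stepped at the
#' cycle trigger) passes through a first-order pressure regulator with
#' time constant `regulator_tau`; the instantaneous flow is clipped to the
#' waterfall admissible flow `max(0, pus - pch_eff) / rus` for the current
#' effective chamber pressure. With the chamber fully open the tube is
#' transparent to any physiological flow.
#'
#' @param flow_in upstream airflow series, L/s.
#' @param pch commanded chamber pressure: scalar or one value per trigger,
#'   cmH2O.
#' @param model a [starling_model()].
#' @param triggers sample indices of cycle starts.
#' @param regulator_tau regulator time constant, s (default from the
#'   model; 0 = instantaneous).
#' @param rate sampling rate, Hz.
#' @return object of class `bench_trace`: data.frame `t`, `vbench`,
#'   `pch_applied`.
#' @export
simulate_starling <- function(flow_in, pch, model, triggers = 1L,
                              regulator_tau = model$tau, rate = 20) {
  stopifnot(inherits(model, "starling_model"))
  n <- length(flow_in)
  triggers <- triggers[triggers >= 1 & triggers <= n]
  if (length(pch) == 1L) pch <- rep(pch, length(triggers))
  stopifnot(length(pch) == length(triggers))

  # piecewise-constant target stepping at each trigger
  target <- numeric(n)
  if (n > 0) {
    idx <- findInterval(seq_len(n), triggers)
    idx[idx < 1L] <- 1L
    target <- pch[idx]
  }
  dt <- 1 / rate
  if (regulator_tau <= 0) {
    eff <- target
  } else {
    eff <- numeric(n)
    a <- dt / regulator_tau
    prev <- target[1]
    for (i in seq_len(n)) {
      prev <- prev + a * (target[i] - prev)
      eff[i] <- prev
    }
  }
  limit <- pmax(0, model$pus - pmax(eff, 0)) / model$rus
  vbench <- pmin(pmax(flow_in, -limit), limit)
  if (isTRUE(model$artifact) && length(triggers) > 1) {
    # collapsing-tube transition spike, proportional to the pch step
    dpch <- c(pch[1], diff(pch))
    for (k in which(dpch > 0)) {
      i <- triggers[k]
      vbench[i] <- vbench[i] + 0.05 * dpch[k]
    }
  }
  structure(data.frame(t = (seq_len(n) - 1) / rate, vbench = vbench,
                       pch_applied = eff),
            class = c("bench_trace", "data.frame"))
}

#' Replay a command set through the virtual bench
#'
#' Drives the active lung with the muscular-effort pressure (volume reset
#' at every trigger) and passes the resulting flow through the Starling
#' resistor with the per-cycle chamber pressures.
#'
#' @param commands a `bench_command_set` from [build_commands()].
#' @param lung optional [lung_model()] override.
#' @param model optional [starling_model()] override.
#' @param regulator_tau regulator time constant, s.
#' @return a `bench_trace` with attribute `lung_flow` (pre-resistor flow).
#' @export
run_bench <- function(commands, lung = commands$lung,
                      model = commands$starling,
                      regulator_tau = model$tau) {
  stopifnot(inherits(commands, "bench_command_set"))
  trig <- commands$triggers
  if (length(trig) == 0)
    return(structure(data.frame(t = numeric(0), vbench = numeric(0),
                                pch_applied = numeric(0)),
                     class = c("bench_trace", "data.frame")))
  if (any(diff(trig) <= 0))
    stop("run_bench: overlapping or unordered cycles")
  flow <- simulate_lung(commands$pmus, lung, trig)
  tr <- simulate_starling(as.numeric(flow), commands$cycles$pch_cmh2o,
                          model, trig, regulator_tau, lung$rate)
  attr(tr, "lung_flow") <- as.numeric(flow)
  tr
}

#' Export a bench trace as CSV
#'
#' @param trace a `bench_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bench_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
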