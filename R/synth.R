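# Ground-truthed synthetic polygraph nights. Breathing is built cycle by
# cycle from an asymmetric template (half-sine inspiration, gamma-shaped
# expiratory decay, volume balanced), with log-normal amplitude and normal
# period jitter. Scripted events scale the nasal airflow and the
# thoracoabdominal drive independently, so obstructive apneas keep their
# effort attempts while central ones lose them. All channels are emitted at
# the native rates of a type-3 home polygraph.

#' Build a synthetic-night scenario
#'
#' @param duration_s recording length, s.
#' @param base_ttot_s mean and sd of the total cycle time, s.
#' @param base_amplitude mean airflow amplitude (arbitrary flow units) and
#'   its log-normal jitter sd as a fraction.
#' @param events data.frame with columns `type` (one of `"OA"`, `"CA"`,
#'   `"OH"`, `"CH"`, `"movement"`), `onset_s`, `duration_s`, `depth`
#'   (fractional airflow reduction, 0-1; ignored for movement). Events must
#'   not overlap.
#' @param snore_on_obstruction add inspiratory audio bursts to obstructive
#'   hypopnea cycles.
#' @param paradox_on_obstruction invert the abdominal band during
#'   obstructive hypopnea cycles (thoracoabdominal paradox).
#' @param flatten_on_obstruction clip the inspiratory template of
#'   obstructive hypopnea cycles (inspiratory flow limitation shape).
#' @param ti_frac inspiratory fraction of the cycle.
#' @param seed integer seed; the generated record is a deterministic
#'   function of the scenario.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(duration_s = 600,
                               base_ttot_s = c(mean = 4, sd = 0.3),
                               base_amplitude = c(mean = 0.5, sd_frac = 0.1),
                               events = NULL,
                               snore_on_obstruction = TRUE,
                               paradox_on_obstruction = TRUE,
                               flatten_on_obstruction = FALSE,
                               ti_frac = 0.4,
                               seed = 1L) {
  if (is.null(events))
    events <- data.frame(type = character(0), onset_s = numeric(0),
                         duration_s = numeric(0), depth = numeric(0))
  events <- events[order(events$onset_s), , drop = FALSE]
  if (nrow(events) > 1 &&
      any(events$onset_s[-1] < (events$onset_s + events$duration_s)[-nrow(events)]))
    stop("synthetic_scenario: scripted events overlap")
  if (any(events$depth < 0 | events$depth > 1, na.rm = TRUE))
    stop("synthetic_scenario: depth must be in [0, 1]")
  structure(list(duration_s = duration_s, base_ttot_s = base_ttot_s,
                 base_amplitude = base_amplitude, events = events,
                 snore_on_obstruction = snore_on_obstruction,
                 paradox_on_obstruction = paradox_on_obstruction,
                 flatten_on_obstruction = flatten_on_obstruction,
                 ti_frac = ti_frac, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Scripted sleep-disordered-breathing night
#'
#' Convenience scenario: a two-hour night with all four event kinds plus
#' movement bursts, spread over the recording with jittered spacing. The
#' default counts give an overall event rate near 22 per hour, a moderate
#' to severe clinical picture.
#'
#' @param duration_s night length, s.
#' @param n_oa,n_ca,n_oh,n_ch event counts per kind.
#' @param n_movement movement bursts.
#' @param seed integer seed.
#' @param ... passed to [synthetic_scenario()].
#' @return a `synthetic_scenario`.
#' @export
scenario_sdb_night <- function(duration_s = 7200, n_oa = 12, n_ca = 10,
                               n_oh = 12, n_ch = 10, n_movement = 2,
                               seed = 1L, ...) {
  set.seed(seed + 1000L)
  types <- sample(c(rep("OA", n_oa), rep("CA", n_ca),
                    rep("OH", n_oh), rep("CH", n_ch)))
  n <- length(types)
  slots <- seq(300, duration_s - 300, length.out = n + n_movement)
  slot_ev <- sort(sample(seq_along(slots), n))
  onsets <- slots[slot_ev] + runif(n, -15, 15)
  dur <- ifelse(types %in% c("OA", "CA"), runif(n, 15, 30), runif(n, 18, 35))
  depth <- ifelse(types == "OA", 0.95,
           ifelse(types == "CA", 0.97, runif(n, 0.45, 0.6)))
  ev <- data.frame(type = types, onset_s = onsets, duration_s = dur,
                   depth = depth, stringsAsFactors = FALSE)
  mv_slots <- setdiff(seq_along(slots), slot_ev)
  if (n_movement > 0 && length(mv_slots)) {
    mv <- data.frame(type = "movement",
                     onset_s = slots[mv_slots[seq_len(n_movement)]],
                     duration_s = runif(n_movement, 45, 80), depth = 0)
    ev <- rbind(ev, mv)
  }
  ev <- ev[order(ev$onset_s), ]
  synthetic_scenario(duration_s = duration_s, events = ev, seed = seed, ...)
}

# expiratory template: g(u) = u * exp(1 - u), u = tau' / tp, tp = Te / 4;
# running integral of g is tp * e * G(u), G(u) = 1 - (1 + u) exp(-u)
synth_G <- function(u) 1 - (1 + u) * exp(-u)

# cycle table: one row per breath with template parameters and event labels
synth_cycle_table <- function(sc) {
  tt_mean <- sc$base_ttot_s[["mean"]]; tt_sd <- sc$base_ttot_s[["sd"]]
  a_mean <- sc$base_amplitude[["mean"]]; a_sd <- sc$base_amplitude[["sd_frac"]]
  n_max <- ceiling(sc$duration_s / max(tt_mean - 3 * tt_sd, 1)) + 2
  ttot <- pmin(pmax(rnorm(n_max, tt_mean, tt_sd), 0.6 * tt_mean), 1.6 * tt_mean)
  amp <- a_mean * exp(rnorm(n_max, -a_sd^2 / 2, a_sd))
  onset <- cumsum(c(0, ttot))[seq_len(n_max)]
  keep <- onset < sc$duration_s
  cyc <- data.frame(onset_s = onset[keep], ttot_s = ttot[keep],
                    amp = amp[keep])
  cyc$ti_s <- sc$ti_frac * cyc$ttot_s
  cyc$label <- "normal"
  cyc$flow_scale <- 1
  cyc$drive_scale <- 1
  cyc$snore <- FALSE
  cyc$paradox <- FALSE
  cyc$flatten <- FALSE

  ev <- sc$events
  breathing <- ev$type %in% c("OA", "CA", "OH", "CH")
  truth_ev <- ev[breathing, , drop = FALSE]
  truth_ev$start_s <- rep(NA_real_, nrow(truth_ev))
  truth_ev$end_s <- rep(NA_real_, nrow(truth_ev))
  for (k in seq_len(nrow(ev))) {
    if (!breathing[k]) next
    sel <- cyc$onset_s >= ev$onset_s[k] &
           cyc$onset_s < ev$onset_s[k] + ev$duration_s[k]
    if (!any(sel)) next
    cyc$label[sel] <- ev$type[k]
    cyc$flow_scale[sel] <- 1 - ev$depth[k]
    cyc$drive_scale[sel] <- switch(ev$type[k],
      OA = 0.8, CA = 1 - ev$depth[k],
      OH = 0.75, CH = 1 - ev$depth[k])
    if (ev$type[k] == "OH") {
      cyc$snore[sel] <- sc$snore_on_obstruction
      cyc$paradox[sel] <- sc$paradox_on_obstruction
      cyc$flatten[sel] <- sc$flatten_on_obstruction
    }
    kk <- which(rownames(truth_ev) == rownames(ev)[k])
    truth_ev$start_s[kk] <- min(cyc$onset_s[sel])
    truth_ev$end_s[kk] <- max(cyc$onset_s[sel] + cyc$ttot_s[sel])
  }
  truth_ev <- truth_ev[!is.na(truth_ev$start_s), , drop = FALSE]
  rownames(truth_ev) <- NULL
  list(cycles = cyc,
       events = truth_ev[, c("type", "start_s", "end_s", "depth")],
       movement = ev[ev$type == "movement", c("onset_s", "duration_s"),
                     drop = FALSE])
}

# evaluate airflow (scale_col selects nasal vs drive scaling) on a time grid
synth_flow_at <- function(t, cyc, scale_col = "flow_scale") {
  i <- findInterval(t, cyc$onset_s)
  i[i < 1] <- 1L
  tau <- t - cyc$onset_s[i]
  ti <- cyc$ti_s[i]
  te <- cyc$ttot_s[i] - ti
  a <- cyc$amp[i] * cyc[[scale_col]][i]
  insp <- tau < ti
  out <- numeric(length(t))
  # inspiration: half sine, optionally plateau-clipped
  xi <- a[insp] * sin(pi * tau[insp] / ti[insp])
  fl <- if (scale_col == "flow_scale") cyc$flatten[i][insp] else FALSE
  xi <- ifelse(fl, pmin(xi, 0.75 * a[insp]) * 1.12, xi)
  out[insp] <- xi
  # expiration: gamma-shaped decay, volume balanced against inspiration
  tp <- te / 4
  vt <- 2 * a * ti / pi
  ae <- vt / (exp(1) * tp * synth_G(4))
  u <- (tau[!insp] - ti[!insp]) / tp[!insp]
  out[!insp] <- -ae[!insp] * u * exp(1 - u)
  out
}

# running lung-volume analogue of the (drive) template
synth_volume_at <- function(t, cyc) {
  i <- findInterval(t, cyc$onset_s)
  i[i < 1] <- 1L
  tau <- t - cyc$onset_s[i]
  ti <- cyc$ti_s[i]
  te <- cyc$ttot_s[i] - ti
  a <- cyc$amp[i] * cyc$drive_scale[i]
  vt <- 2 * a * ti / pi
  tp <- te / 4
  ae <- vt / (exp(1) * tp * synth_G(4))
  insp <- tau < ti
  out <- numeric(length(t))
  out[insp] <- a[insp] * ti[insp] / pi * (1 - cos(pi * tau[insp] / ti[insp]))
  u <- (tau[!insp] - ti[!insp]) / tp[!insp]
  out[!insp] <- vt[!insp] -
    ae[!insp] * tp[!insp] * exp(1) * synth_G(pmin(u, 4))
  out
}

#' Generate a synthetic polygraph night
#'
#' Produces a `polygraph_record` with all channels at native rates (nasal
#' pressure 200 Hz, RIP bands and RIP flow 25 Hz, audio 100 Hz,
#' accelerometer norm 20 Hz, SpO2 3 Hz) plus a ground-truth annotation
#' list. Nasal pressure is the signed square of the scripted airflow (the
#' inverse of the square-root estimate), RIP bands follow the ventilatory
#' drive volume (antiphase abdomen during scripted paradox), audio gains
#' inspiratory bursts on snoring cycles, and the accelerometer floor gains
#' high-energy bursts during scripted movement.
#'
#' @param sc a [synthetic_scenario()].
#' @return list with `record` (a `polygraph_record`), and `truth`: list of
#'   `cycles` (per-breath table with onset, Ttot, amplitude, label),
#'   `events` (cycle-aligned scripted events with `type`, `start_s`,
#'   `end_s`, `depth`), `movement`, and the `scenario`.
#' @export
generate_polygraph <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  if (sc$duration_s <= 0) {
    rec <- structure(list(duration_s = 0, channels = list(),
                          channel_map = default_channel_map(), rate_hz = 20),
                     class = "polygraph_record")
    return(list(record = rec,
                truth = list(cycles = empty_cycles(),
                             events = data.frame(), movement = data.frame(),
                             scenario = sc)))
  }
  set.seed(sc$seed)
  tab <- synth_cycle_table(sc)
  cyc <- tab$cycles
  dur <- floor(sc$duration_s)

  grid <- function(rate) seq(0, by = 1 / rate, length.out = dur * rate)

  # nasal pressure @200 Hz: signed square of airflow
  t200 <- grid(200)
  flow200 <- synth_flow_at(t200, cyc, "flow_scale")
  nasal <- sign(flow200) * flow200^2 + rnorm(length(t200), 0, 2e-4)

  # RIP bands @25 Hz from the drive volume
  t25 <- grid(25)
  vol <- synth_volume_at(t25, cyc)
  i25 <- findInterval(t25, cyc$onset_s); i25[i25 < 1] <- 1L
  vt25 <- 2 * cyc$amp[i25] * cyc$drive_scale[i25] * cyc$ti_s[i25] / pi
  drift <- 0.15 * sin(2 * pi * t25 / 300)
  thorax <- 5 + 0.6 * vol + drift + rnorm(length(t25), 0, 0.004)
  ab_mod <- ifelse(cyc$paradox[i25], vt25 - vol, vol)
  abdomen <- 4 + 0.4 * ab_mod + drift + rnorm(length(t25), 0, 0.004)

  # RIP-derived flow @25 Hz follows the obstructed airflow
  ripflow <- 0.9 * synth_flow_at(t25, cyc, "flow_scale") +
    rnorm(length(t25), 0, 0.004)

  # audio power @100 Hz with inspiratory snore bursts
  t100 <- grid(100)
  i100 <- findInterval(t100, cyc$onset_s); i100[i100 < 1] <- 1L
  tau100 <- t100 - cyc$onset_s[i100]
  audio <- abs(rnorm(length(t100), 0.5, 0.05))
  sn <- cyc$snore[i100] & tau100 < cyc$ti_s[i100]
  audio[sn] <- audio[sn] +
    4 * sin(pi * tau100[sn] / cyc$ti_s[i100][sn])^2

  # accelerometer norm @20 Hz with movement bursts
  t20 <- grid(20)
  accel <- abs(1 + rnorm(length(t20), 0, 0.01))
  for (k in seq_len(nrow(tab$movement))) {
    mv <- t20 >= tab$movement$onset_s[k] &
          t20 < tab$movement$onset_s[k] + tab$movement$duration_s[k]
    accel[mv] <- abs(accel[mv] + rnorm(sum(mv), 0, 1.2))
  }

  spo2 <- 96 + rnorm(dur * 3, 0, 0.2)

  cm <- default_channel_map()
  rec <- structure(list(
    duration_s = dur,
    channels = list(
      accel = list(data = accel, rate = 20),
      nasal_pressure = list(data = nasal, rate = 200),
      rip_thorax = list(data = thorax, rate = 25),
      rip_abdomen = list(data = abdomen, rate = 25),
      rip_flow = list(data = ripflow, rate = 25),
      audio = list(data = audio, rate = 100),
      spo2 = list(data = spo2, rate = 3)
    ),
    channel_map = cm,
    rate_hz = 20
  ), class = "polygraph_record")

  list(record = rec,
       truth = list(cycles = cyc, events = tab$events,
                    movement = tab$movement, scenario = sc))
}

#' Write a synthetic night to EDF plus a ground-truth JSON
#'
#' @param gen result of [generate_polygraph()].
#' @param edf_path output EDF path.
#' @param truth_path output JSON path (default: `edf_path` with
#'   `.truth.json`).
#' @return `edf_path`, invisibly.
#' @export
write_synthetic_edf <- function(gen, edf_path,
                                truth_path = paste0(edf_path, ".truth.json")) {
  rec <- gen$record
  cm <- rec$channel_map
  channels <- list()
  for (role in names(rec$channels))
    channels[[cm[[role]]]] <- rec$channels[[role]]
  write_edf(edf_path, channels)
  jsonlite::write_json(list(cycles = gen$truth$cycles,
                            events = gen$truth$events,
                            movement = gen$truth$movement),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(edf_path)
}
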