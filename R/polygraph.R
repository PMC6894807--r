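# Polygraph input: EDF loading, harmonization of all channels onto the
# common 20 Hz timebase, Savitzky-Golay smoothing, and derivation of the
# estimated nasal airflow from nasal pressure.

#' @importFrom stats approx median sd cor coef lm predict quantile rnorm runif
NULL

#' Load a polygraph recording from EDF
#'
#' Reads an EDF file and attaches channels under canonical roles
#' (accelerometer, nasal pressure, RIP thorax/abdomen/flow, audio, and
#' optionally SpO2 and naso-buccal thermistance). When the accelerometer is
#' provided as three separate axes they are collapsed to the Euclidean
#' norm.
#'
#' @param path EDF file path.
#' @param channel_map named list mapping canonical roles to channel labels;
#'   see [default_channel_map()].
#' @return a `polygraph_record`: native-rate channels plus metadata. Run
#'   [preprocess_polygraph()] to derive the 20 Hz series and the estimated
#'   nasal airflow.
#' @export
load_polygraph <- function(path, channel_map = default_channel_map()) {
  edf <- read_edf(path)
  labels <- names(edf$channels)
  pick <- function(role) {
    lbl <- channel_map[[role]]
    if (is.null(lbl) || !lbl %in% labels) return(NULL)
    edf$channels[[lbl]]
  }

  channels <- list()
  axes <- lapply(c("accel_x", "accel_y", "accel_z"), pick)
  if (!any(vapply(axes, is.null, logical(1)))) {
    rates <- vapply(axes, function(a) a$rate, numeric(1))
    if (length(unique(rates)) != 1)
      stop("load_polygraph: accelerometer axes have differing rates")
    channels$accel <- list(
      data = sqrt(axes[[1]]$data^2 + axes[[2]]$data^2 + axes[[3]]$data^2),
      rate = rates[1])
  } else {
    channels$accel <- pick("accel")
    if (!is.null(channels$accel))
      channels$accel$data <- abs(channels$accel$data)
  }

  for (role in c("nasal_pressure", "rip_thorax", "rip_abdomen", "rip_flow",
                 "audio", "spo2", "thermistance"))
    channels[[role]] <- pick(role)

  mandatory <- c("accel", "nasal_pressure", "rip_thorax", "rip_abdomen",
                 "rip_flow", "audio")
  missing <- mandatory[vapply(channels[mandatory], is.null, logical(1))]
  if (length(missing))
    stop("load_polygraph: missing mandatory channel role(s): ",
         paste(missing, collapse = ", "))
  channels <- channels[!vapply(channels, is.null, logical(1))]

  structure(list(
    duration_s = edf$duration_s,
    channels = channels,
    channel_map = channel_map,
    rate_hz = 20
  ), class = "polygraph_record")
}

#' @export
print.polygraph_record <- function(x, ...) {
  cat("<polygraph_record>", format(x$duration_s), "s\n")
  for (nm in names(x$channels))
    cat(sprintf("  %-15s @ %g Hz, n = %d\n", nm, x$channels[[nm]]$rate,
                length(x$channels[[nm]]$data)))
  if (!is.null(x$vsource))
    cat("  vsource derived @ 20 Hz, n =", length(x$vsource), "\n")
  invisible(x)
}

#' Resample a series to the common 20 Hz timebase
#'
#' Downsampling applies a zero-phase low-pass (4th-order Butterworth at
#' 9 Hz, forward-backward) before interpolating onto the 20 Hz grid, so
#' breath onsets are not phase shifted. Rates below 20 Hz are upsampled by
#' sample-and-hold with a warning, since such channels (e.g. SpO2 at 3 Hz)
#' are carried for inspection only.
#'
#' @param x numeric series at `native_rate`.
#' @param native_rate sampling rate of `x`, Hz.
#' @param target_rate output rate, Hz (default 20).
#' @return numeric series at `target_rate`, length `floor(duration * target_rate)`.
#' @export
resample_to_20hz <- function(x, native_rate, target_rate = 20) {
  stopifnot(native_rate > 0)
  n_out <- floor(length(x) / native_rate * target_rate)
  if (native_rate == target_rate) return(x[seq_len(n_out)])
  if (native_rate < target_rate) {
    warning("resample_to_20hz: upsampling ", native_rate,
            " Hz channel by sample-and-hold")
    t_out <- (seq_len(n_out) - 1) / target_rate
    idx <- pmin(floor(t_out * native_rate) + 1, length(x))
    return(x[idx])
  }
  # anti-alias below the 10 Hz target Nyquist, zero phase; odd-reflection
  # padding suppresses filtfilt edge transients
  cutoff_hz <- 0.9 * target_rate / 2
  bf <- signal::butter(4, cutoff_hz / (native_rate / 2), type = "low")
  np <- min(length(x) - 1, ceiling(2 * native_rate))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  xf <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  xf <- xf[(np + 1):(np + length(x))]
  t_in <- (seq_along(x) - 1) / native_rate
  t_out <- (seq_len(n_out) - 1) / target_rate
  approx(t_in, xf, xout = t_out, rule = 2)$y
}

#' Savitzky-Golay smoothing over one-second windows
#'
#' Third-degree polynomial fit over successive 1 s windows (21 samples at
#' 20 Hz; the window is forced odd). Cubic and lower-order trends pass
#' unchanged; length is preserved. Series shorter than the window are
#' returned unchanged with a warning.
#'
#' @param x numeric series.
#' @param rate sampling rate, Hz.
#' @param order polynomial order (default 3).
#' @return smoothed series, same length as `x`.
#' @export
savgol_smooth <- function(x, rate = 20, order = 3) {
  n_win <- rate + 1 - (rate %% 2)          # 1 s rounded up to odd
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (length(x) < n_win) {
    warning("savgol_smooth: series shorter than smoothing window; unchanged")
    return(x)
  }
  signal::sgolayfilt(x, p = order, n = n_win)
}

#' Estimate nasal airflow from nasal pressure
#'
#' Signed square-root transform: `sign(p) * sqrt(|p|)`. The square root
#' linearizes the quadratic pressure-flow relation of a nasal cannula; the
#' sign is kept so inspiratory/expiratory polarity survives. Consequently a
#' pressure-amplitude reduction of 90% corresponds to a flow reduction of
#' 1 - sqrt(0.1) ~ 68.4%.
#'
#' @param p zero-centred nasal pressure series.
#' @return airflow series (arbitrary flow units), odd in `p`.
#' @export
nasal_pressure_to_flow <- function(p) sign(p) * sqrt(abs(p))

#' Preprocess a polygraph recording
#'
#' Brings nasal pressure, RIP and audio channels onto the 20 Hz timebase,
#' smooths the respiratory channels with the Savitzky-Golay filter, and
#' derives the estimated nasal airflow `vsource`. Sub-20 Hz channels (SpO2)
#' are carried as metadata only.
#'
#' @param rec a `polygraph_record` from [load_polygraph()] (or the
#'   synthetic generator).
#' @return the record with a `derived` list of 20 Hz series
#'   (`accel_norm`, `nasal_pressure`, `rip_thorax`, `rip_abdomen`,
#'   `rip_flow`, `audio`, optional `thermistance`) and `vsource`.
#' @export
preprocess_polygraph <- function(rec) {
  stopifnot(inherits(rec, "polygraph_record"))
  rate <- rec$rate_hz
  to20 <- function(role) {
    ch <- rec$channels[[role]]
    if (is.null(ch)) return(NULL)
    resample_to_20hz(ch$data, ch$rate, rate)
  }
  derived <- list()
  derived$accel_norm <- abs(to20("accel"))
  derived$nasal_pressure <- savgol_smooth(to20("nasal_pressure"), rate)
  for (role in c("rip_thorax", "rip_abdomen", "rip_flow"))
    derived[[role]] <- savgol_smooth(to20(role), rate)
  derived$audio <- to20("audio")
  if (!is.null(rec$channels$thermistance))
    derived$thermistance <- savgol_smooth(to20("thermistance"), rate)

  n <- min(lengths(derived))
  derived <- lapply(derived, function(d) d[seq_len(n)])
  rec$derived <- derived
  rec$vsource <- nasal_pressure_to_flow(derived$nasal_pressure)
  stopifnot(all(is.finite(rec$vsource)))
  rec
}

#' Export the preprocessed 20 Hz channels as CSV
#'
#' One column per canonical channel on the 20 Hz grid, for inspection.
#'
#' @param rec preprocessed `polygraph_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_polygraph_csv <- function(rec, path) {
  if (is.null(rec$derived))
    stop("write_polygraph_csv: run preprocess_polygraph() first")
  df <- data.frame(t_s = (seq_along(rec$vsource) - 1) / rec$rate_hz,
                   vsource = rec$vsource)
  for (nm in names(rec$derived)) df[[nm]] <- rec$derived[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
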