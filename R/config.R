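# Pipeline configuration: every tunable threshold of the processing chain in
# one nested list, serializable to YAML/JSON without loss.

#' Default pipeline configuration
#'
#' Returns the full set of processing constants. Units are seconds for
#' durations and window lengths, fractions (0-1) for relative thresholds.
#' Key entries:
#'
#' * `stability$slope_ratio` (5.8): slope-jump ratio of the adaptive
#'   accelerometer-energy threshold.
#' * `breaths$reduced_drop` (0.65): airflow-excursion reduction marking a
#'   highly reduced segment, vs the 2-min pre-event baseline;
#'   `breaths$reduced_min_dur_s` (4 s) its minimum duration.
#' * `events$apnea_flow_frac` (sqrt(0.10) ~ 0.316): apnea threshold on the
#'   flow scale. Apnea scoring is defined on nasal pressure (drop >= 90%);
#'   since flow is the square root of pressure the equivalent excursion
#'   bound is sqrt(0.10) of baseline.
#' * `events$hypopnea_drop` (0.30): minimum excursion reduction for a
#'   hypopnea; `events$confirm_drop_apnea` (0.20) and
#'   `events$confirm_drop_hypopnea` (0.10): required drop in the
#'   confirmation channel (thermistance, else RIP flow).
#' * `events$min_dur_s` (10) / `events$max_dur_s` (180): scored event
#'   duration bounds.
#' * `lung`: compliance 80 mL/cmH2O, resistance 7.25 cmH2O/(L/s).
#' * `starling`: upstream pressure 4 cmH2O, upstream resistance, regulator
#'   time constant.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    rate_hz = 20,
    channel_map = default_channel_map(),
    stability = list(
      frame_len_samples = 100L,
      hop_samples = 50L,
      n_resampled = 1080L,
      slope_window = 6L,
      slope_hop = 3L,
      slope_ratio = 5.8,
      rest_fraction = 0.25,
      max_gap_s = 120
    ),
    breaths = list(
      ampd_window_s = 180,
      ampd_hop_s = 90,
      ampd_max_scale_s = 10,
      dedup_s = 0.25,
      rescue_amp_frac = 0.2,
      rescue_gap_factor = 1.5,
      reduced_drop = 0.65,
      reduced_min_dur_s = 4,
      baseline_s = 120
    ),
    events = list(
      apnea_flow_frac = sqrt(0.10),
      hypopnea_drop = 0.30,
      confirm_drop_apnea = 0.20,
      confirm_drop_hypopnea = 0.10,
      confirm_baseline_s = 60,
      attempt_sig_frac = 0.10,
      attempt_baseline_s = 60,
      min_dur_s = 10,
      max_dur_s = 180,
      snore_power_ratio = 2,
      ifl = list(enabled = TRUE, seed = 42L, n_per_class = 400L)
    ),
    commands = list(
      ti_frac_default = 0.4,
      equilibrate_tol_l = 1e-6
    ),
    lung = list(compliance_ml_cmh2o = 80, resistance_cmh2o_l_s = 7.25),
    starling = list(pus_cmh2o = 4, rus_cmh2o_l_s = 2, pch_min_cmh2o = 0,
                    regulator_tau_s = 0.3, transition_artifact = FALSE),
    evaluation = list(match_window_s = 1.5, overlap_frac = 0.5,
                      min_cycle_samples = 40L),
    seed = 1L
  )
}

#' Default channel-role mapping
#'
#' Maps canonical roles to recording channel labels. Defaults follow the
#' labels of a typical type-3 home polygraph and match the synthetic
#' generator's output. `accel` may name a
#' precomputed norm; alternatively `accel_x`/`accel_y`/`accel_z` name the
#' three axes, collapsed to a Euclidean norm on load.
#'
#' @return named list role -> channel label.
#' @export
default_channel_map <- function() {
  list(
    accel = "Activity",
    nasal_pressure = "Nasal Pressure",
    rip_thorax = "Thorax",
    rip_abdomen = "Abdomen",
    rip_flow = "RIP Flow",
    audio = "Audio Volume",
    spo2 = "SpO2",
    thermistance = "Thermistance"
  )
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the configuration list. Unspecified entries fall
#' back to [default_config()] values.
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return `read_config`: configuration list; `write_config`: `path`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modify_defaults(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

modify_defaults <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_defaults(base[[nm]], user[[nm]])
    else
      base[[nm]] <- user[[nm]]
  }
  base
}
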