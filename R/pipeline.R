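# End-to-end pipeline: preprocess -> stable periods -> breaths -> events
# -> bench commands, plus the command-style wrappers used by the
# inst/cli/polybench front-end.

#' Run the full polygraph-to-bench pipeline
#'
#' Chains preprocessing, movement segmentation, breath detection, event
#' scoring and command synthesis on one recording.
#'
#' @param rec a `polygraph_record` (raw; preprocessed automatically).
#' @param config pipeline configuration ([default_config()]).
#' @param ifl_model optional `ifl_model`; when `NULL` and
#'   `config$events$ifl$enabled` is TRUE, the default synthetic-corpus
#'   classifier is trained (seeded, deterministic).
#' @return object of class `polybench_result`: list with `record`
#'   (preprocessed), `stable`, `excursion`, `reduced`, `cycles`, `events`,
#'   `commands`, `summary`.
#' @export
process_polygraph <- function(rec, config = default_config(),
                              ifl_model = NULL) {
  rate <- config$rate_hz
  if (is.null(rec$derived)) rec <- preprocess_polygraph(rec)

  fe <- frame_energy(rec$derived$accel_norm, rate,
                     config$stability$frame_len_samples,
                     config$stability$hop_samples)
  thr <- adaptive_energy_threshold(fe,
    slope_ratio = config$stability$slope_ratio,
    rest_fraction = config$stability$rest_fraction,
    n_resampled = config$stability$n_resampled,
    slope_window = config$stability$slope_window,
    slope_hop = config$stability$slope_hop)
  stable <- segment_stable_periods(fe, thr, config$stability$max_gap_s)

  flow <- rec$vsource
  pv <- detect_peaks_valleys(flow, rate,
                             window_s = config$breaths$ampd_window_s,
                             hop_s = config$breaths$ampd_hop_s,
                             max_scale_s = config$breaths$ampd_max_scale_s,
                             dedup_s = config$breaths$dedup_s)
  pv <- rescue_missed_cycles(flow, pv$peaks, pv$valleys, rate,
                             amp_frac = config$breaths$rescue_amp_frac,
                             gap_factor = config$breaths$rescue_gap_factor)
  exc <- compute_excursion(flow, pv$peaks, pv$valleys, rate)
  reduced <- find_reduced_excursion_segments(exc, rate,
                                             drop = config$breaths$reduced_drop,
                                             min_dur_s = config$breaths$reduced_min_dur_s,
                                             baseline_s = config$breaths$baseline_s)
  cycles <- detect_breath_onsets(flow, exc, rec$derived$rip_thorax,
                                 rec$derived$rip_abdomen, reduced, rate,
                                 stable = stable)

  if (is.null(ifl_model) && isTRUE(config$events$ifl$enabled))
    ifl_model <- default_ifl_model(config$events$ifl$n_per_class,
                                   config$events$ifl$seed)
  scored <- detect_events(rec, cycles, exc, config$events, ifl_model, rate)

  lung <- lung_model(config$lung$compliance_ml_cmh2o,
                     config$lung$resistance_cmh2o_l_s, rate)
  starling <- calibrate_starling(
    starling_model(config$starling$pus_cmh2o, config$starling$rus_cmh2o_l_s,
                   config$starling$pch_min_cmh2o,
                   config$starling$regulator_tau_s,
                   config$starling$transition_artifact))
  commands <- build_commands(flow, scored$cycles, lung, starling, rate,
                             config$commands$ti_frac_default)

  hours <- sum(stable$intervals$end_s - stable$intervals$start_s) / 3600
  summary <- if (hours > 0) ahi_summary(scored$events, hours) else NULL

  structure(list(record = rec, stable = stable, excursion = exc,
                 reduced = reduced, cycles = scored$cycles,
                 events = scored$events, attempts = scored$attempts,
                 commands = commands, summary = summary, config = config),
            class = "polybench_result")
}

#' @export
print.polybench_result <- function(x, ...) {
  cat("<polybench_result>\n")
  cat("  stable time:",
      round(sum(x$stable$intervals$end_s - x$stable$intervals$start_s)), "s in",
      nrow(x$stable$intervals), "interval(s)\n")
  cat("  cycles:", nrow(x$cycles), " events:", nrow(x$events), "\n")
  if (!is.null(x$summary))
    cat(sprintf("  AHI %.1f (AI %.1f, HI %.1f) over %.2f h\n",
                x$summary$ahi, x$summary$ai, x$summary$hi, x$summary$hours))
  invisible(x)
}

#' Process an EDF recording to events and bench commands
#'
#' Command-style wrapper: reads the EDF, runs [process_polygraph()], and
#' writes events (CSV + JSON), cycles CSV, stable periods, the two command
#' files and a summary JSON into `outdir`.
#'
#' @param edf_path input EDF.
#' @param config configuration list or path to a YAML config.
#' @param outdir output directory (created if needed).
#' @return the `polybench_result`, invisibly.
#' @export
cmd_process <- function(edf_path, config = default_config(), outdir = ".") {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rec <- load_polygraph(edf_path, config$channel_map)
  res <- process_polygraph(rec, config)
  write_events(res$events, file.path(outdir, "events.csv"), "csv")
  hours <- if (is.null(res$summary)) NULL else res$summary$hours
  write_events(res$events, file.path(outdir, "events.json"), "json",
               hours = hours)
  write_cycles_csv(res$cycles, file.path(outdir, "cycles.csv"))
  write_stable_periods(res$stable, file.path(outdir, "stable_periods.bed"))
  write_commands_csv(res$commands, file.path(outdir, "commands_cycles.csv"),
                     file.path(outdir, "commands_waveform.csv"))
  invisible(res)
}

#' Replay command files through the virtual bench
#'
#' @param commands a `bench_command_set` (or a `polybench_result`).
#' @param config configuration list or YAML path.
#' @param outdir output directory.
#' @return the `bench_trace`, invisibly.
#' @export
cmd_bench <- function(commands, config = default_config(), outdir = ".") {
  if (is.character(config)) config <- read_config(config)
  if (inherits(commands, "polybench_result")) commands <- commands$commands
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  trace <- run_bench(commands)
  write_bench_csv(trace, file.path(outdir, "bench_trace.csv"))
  invisible(trace)
}

#' Evaluate a bench trace against its source recording
#'
#' @param result a `polybench_result` for the source recording, or a bare
#'   airflow series (then both sides are analysed identically via
#'   [evaluate_traces()]).
#' @param trace a `bench_trace` (or bench airflow vector).
#' @param config configuration list or YAML path.
#' @param outdir output directory for the report JSON.
#' @return the `evaluation_report`, invisibly.
#' @export
cmd_evaluate <- function(result, trace, config = default_config(),
                         outdir = ".") {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vb <- if (is.data.frame(trace)) trace$vbench else as.numeric(trace)
  report <- if (inherits(result, "polybench_result")) {
    evaluate_bench(result$record$vsource, result$cycles, result$events,
                   vb, config$rate_hz, config$evaluation, config$events)
  } else {
    evaluate_traces(as.numeric(result), vb, config$rate_hz,
                    config$evaluation, config$events)
  }
  write_report_json(report, file.path(outdir, "evaluation.json"))
  invisible(report)
}

#' Generate a synthetic night and write it to disk
#'
#' @param scenario a `synthetic_scenario`.
#' @param outdir output directory (EDF + ground-truth JSON).
#' @return the generated list (`record`, `truth`), invisibly.
#' @export
cmd_synth <- function(scenario, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_polygraph(scenario)
  write_synthetic_edf(gen, file.path(outdir, "synthetic_night.edf"),
                      file.path(outdir, "synthetic_night.truth.json"))
  invisible(gen)
}
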