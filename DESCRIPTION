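Package: polybench
Title: Replay of Sleep Polygraph Breathing Profiles on a Virtual Respiratory Bench
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms night-long multichannel sleep-polygraph recordings
    (nasal pressure, respiratory inductance plethysmography, audio,
    accelerometry) into per-breath commands for a respiratory test bench:
    a muscular-effort pressure waveform driving a single-compartment
    active lung and a chamber pressure regulating a Starling resistor
    that mimics upper-airway collapse. Movement-free periods are
    segmented with an adaptive accelerometer-energy threshold, breath
    onsets are located with automatic multiscale peak detection, and
    apneas and hypopneas are scored and typed obstructive or central
    following AASM-style rules. A software surrogate of the bench
    replays the commands, and agreement between the source and replayed
    airflow is quantified with per-cycle amplitude and period bias,
    Bland-Altman limits, waveform correlation and apnea detection
    sensitivity and positive predictive value. A seeded synthetic-night
    generator with scripted events provides ground-truthed recordings
    in European Data Format for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
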