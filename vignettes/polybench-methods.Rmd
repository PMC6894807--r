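---
title: "Methods: from polygraph signals to bench commands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from polygraph signals to bench commands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `polybench`, and what the synthetic validation does and
does not demonstrate.

## Signal model and preprocessing

All analysis runs on a common 20 Hz timebase. Channels above 20 Hz are
low-passed with a 4th-order Butterworth at 9 Hz applied forward-backward
(zero phase, so breath onsets are not shifted) and interpolated onto the
20 Hz grid; channels below 20 Hz (SpO2 at 3 Hz) are carried by
sample-and-hold for inspection only — no processing step consumes them.
Respiratory channels are then smoothed with a Savitzky–Golay filter of
polynomial order 3 over 1 s windows (21 samples; the window is forced
odd). An order-3 filter passes cubic trends exactly, so breath morphology
up to the third derivative is untouched while sensor noise is attenuated.

Nasal airflow is estimated as the *signed* square root of nasal pressure,
`sign(p)·√|p|`. The square root linearizes the quadratic pressure–flow
characteristic of a nasal cannula; the sign convention (not stated in the
classical scoring rules, which operate on excursions) preserves
inspiratory/expiratory polarity and is required for the zero-crossing
onset definition. A useful corollary: a 90% nasal-pressure reduction — the
classical apnea criterion — maps to a `1 − √0.1 ≈ 68.4%` airflow
reduction. The events module therefore uses `√0.10 ≈ 31.6%` of baseline as
the apnea bound on the flow scale, while the coarser 65% reduction rule
(chosen near the 66.7% bound) drives the breath-module segmentation only.

## Movement segmentation

Body movement corrupts every channel at once, so movement-free ("stable")
periods are found on the accelerometer norm alone: short-time energy
`E_k = Σ_{i=1..100}|S_k(i)|²` over 5 s frames with 50% overlap. The
threshold adapts to the night: energies are sorted, resampled to exactly
1080 points (nearest-rank selection; linear interpolation upward for
recordings under ~1.5 h, which is logged), slopes are fit by least squares
over every 6 consecutive points with hop 3 (359 slopes), and the scan
starts at slope index 90 — the assumption being that at least 25% of the
recording is at rest. The first slope exceeding 5.8× the running mean of
all previous slopes marks the change point, and the threshold is the
median of that window's six energies. The ratio 5.8 is an empirical
constant of the method; it is exposed in the configuration but not
re-derived. The procedure is scale-equivariant (sums, medians, slopes and
slope ratios all scale linearly), which the tests exploit.

Two idealizations matter. If no slope ever qualifies, the whole night is
declared stable (with a warning) — correct for a quiet recording. And
frames that straddle a rest/movement boundary form a continuum in the
sorted array, so the change point can land a few order statistics inside
the rest tail; the property tests therefore require ≥99% (not 100%) of
pure-rest frames below threshold. Misclassified single frames are
operationally irrelevant because movement gaps shorter than 2 minutes are
absorbed into the surrounding stable interval anyway.

## Breath identification

Extrema come from automatic multiscale peak detection (AMPD): a local-
maxima scalogram over window scales `k = 1..L`, the scale with the most
maxima selecting λ, and peaks being samples that are maxima at *every*
scale up to λ. We use the deterministic form of the scalogram (membership
counts rather than randomized entries; the selected scale and surviving
columns are identical), detrend each window linearly first, and cap the
scale at 10 s — half the longest plausible breath. Windows are 3 minutes
(about 45 cycles at Ttot = 4 s, 72 at 2.5 s — enough periodicity for the
scalogram, small enough for the O(n²) cost), hop 90 s, and stitched with
a 0.25 s duplicate-suppression radius. Because the scalogram cannot
certify extrema within λ samples of a window edge, each detrended window
is padded by odd reflection before scanning; without this the first and
last breath of the night are systematically lost. A rescue pass then
scans long inter-peak gaps (>1.5× the recent median Ttot) for
zero-crossing oscillations with excursion above 0.2× the recent median
amplitude — both thresholds exist in the method's description without
stated values; the defaults here are configuration entries.

Envelopes interpolate peaks and valleys with shape-preserving piecewise
cubics (PCHIP; ordinary splines overshoot at apnea edges), constant
beyond the terminal extrema, and the excursion is their difference
clipped at zero. Breath onsets are the expiratory→inspiratory zero
crossings of the flow between a valley and the following peak, falling
back to the maximum-slope point if a DC offset prevents a crossing.
Inside reduced-excursion segments (≥65% drop vs the rolling 2-minute
pre-segment baseline, >4 s) the flow is uninformative, so onsets come
from the valleys of the reference RIP band — the band whose
segment-modulation, normalized by its own pre-segment baseline, is larger
(ties to thorax). If both bands are flat relative to baseline the segment
is central-type and contributes no onsets: the surrounding cycle then
spans it, which is exactly what the command stage needs for a central
apnea.

## Event scoring

Apneas: flow excursion ≤ 31.6% of the 2-minute pre-event baseline for
10–180 s. The 10 s minimum follows the clinical scoring convention for
scored events (the 4 s rule above is segmentation, not scoring); the
3-minute cap guards against sensor displacement and mouth breathing, as
does the required >20% excursion drop in a confirmation channel
(naso-buccal thermistance when recorded, else RIP flow) against its 1-min
pre/post baselines. Baselines are computed in two passes: candidate runs
against a causal rolling mean, then each run re-evaluated against the
frozen mean of the window preceding its start — otherwise the event
itself drags its own baseline down.

Apnea typing counts breath attempts: reference-RIP peaks inside the
event, each significant iff the RIP excursion at the peak time reaches
10% of the 1-minute pre+post RIP excursion baseline. Any significant
attempt ⇒ obstructive (mixed events are labelled OA, with per-attempt
flags kept for the command stage); none ⇒ central. Attempts within 2 s of
either event boundary are ignored: the detected boundary cuts through
transition breaths whose excursion still carries pre/post-event
amplitude, and counting them misclassifies central events.

Hypopneas: excursion reduction ≥30% (but above the apnea bound) for
10–180 s with a ≥10% confirmation drop; apneas take precedence on
overlapping intervals. Typing requires one of three obstruction markers
on the event's cycles: snoring (mean inspiratory audio power > 2× the
expiratory mean — the factor is a configuration default, none being
stated in the source method), thoracoabdominal paradox (the thorax peak
closer in time to the abdomen valley than to the abdomen peak), or a
flow-limited inspiratory shape. Flow limitation uses seven features —
peak count, peak amplitude normalized by the 2-minute baseline, scooping
index (1 − mean of the middle 50% of inspiration over peak), kurtosis,
deviation from the best-fit half-sine (RMS, normalized by peak),
flattening index (fraction of inspiration within 15% of peak), skewness —
fed to a 7–14–14–1 sigmoid network. No scored clinical corpus is
available, so the default classifier trains on a synthetic shape corpus
(rounded vs plateau-clipped-and-scooped inspirations, amplitudes spanning
normal breaths to deep hypopneas in both classes so the normalized peak
is not a class shortcut), by BFGS on L2-regularized cross-entropy with
analytic gradients, seed 42, deterministic. Because the classifier sees
one noisy inspiration at a time, flow-limitation evidence alone must
appear on at least two cycles of an event; snore and paradox remain
single-cycle evidence.

## Commands and the virtual bench

Units are L/s, L, cmH2O throughout; the lung compliance is converted from
80 mL/cmH2O at the model boundary. For normal and central cycles the
drive airflow `V̇cc` is the recorded airflow itself. For obstructive
cycles it is rebuilt as a sinusoid at the pre-event 2-minute amplitude
baseline (frozen at event entry): a half-sine inspiration over the
cycle's inspiratory time and a volume-balancing half-sine expiration.
Inspiratory time is measured from the airflow phase span for obstructive
hypopneas and defaults to 0.4×Ttot for obstructive apneas, whose timing
derives from RIP onsets. A cycle carrying an obstructive label whose own
amplitude already reaches the baseline (a transition breath at an event
edge) is copied, not reconstructed — reconstructing it would inject a
spurious full-amplitude breath into the replay.

Each cycle is then volume-equilibrated (the bench piston must return to
its start position): the lesser-volume phase is scaled by a single factor
until inspiratory and expiratory volumes agree within 10⁻⁶ L. The
muscular-effort pressure is `ΔPmus = −Vcc/C − R·V̇cc` with the volume as
the running trapezoidal integral of `V̇cc`, reset to zero at every cycle
trigger — whether the volume integrates across cycles is not specified by
the hardware description; resetting prevents drift accumulation over a
night. The virtual lung inverts the same relation with the implicit
trapezoidal scheme, the exact discrete inverse of that integration (and
A-stable at RC = 0.58 s, 20 Hz), so the command/replay pair is discretely
consistent and the round trip is exact to machine precision; the 2%
round-trip tolerance in the tests is then pure headroom for future
integrator changes.

The Starling resistor's attenuation law is not published for the physical
tube, so the surrogate is a waterfall law: flow passes unrestricted while
the effective chamber pressure is at or below ambient; above it the
admissible flow magnitude is `(P_us − P_ch)/R_us`, with upstream pressure
4 cmH2O (the minimal APAP delivery pressure) and upstream resistance
2 cmH2O/(L/s) — full occlusion therefore at 4 cmH2O. Calibration proceeds
as on the physical bench: sweep the chamber pressure, drive reference
cycles at several amplitudes with the regulator bypassed, and tabulate
output/input amplitude ratios (per phase, and peak-to-valley). The
per-cycle chamber pressure for an obstructive cycle inverts the
peak-to-valley table — the same amplitude measure the evaluation uses —
so for reconstructed cycles (which *are* the calibration reference
shape) the inversion is exact. The commanded pressure steps at each
cycle trigger and passes through a first-order regulator
(τ = 0.3 s, configurable; the physical regulator dynamics are
uncharacterized), so the first occluded cycle of an event carries a
settling transient, as the hardware's would. The collapsing-tube flow
spike at obstruction onset can be emulated (amplitude proportional to the
pressure step) but is off by default.

## Evaluation

Source and bench cycles are paired greedily by nearest onset within
±1.5 s (no pairing rule being stated for the cycle-by-cycle comparison).
The bench produces airflow only, so its cycles and apneas are re-detected
flow-only, without the confirmation-channel rule. Cycle agreement uses
the *relative* amplitude — peak-to-valley amplitude over the trace's own
rolling 2-minute mean across normal-breathing cycles; restricting the
baseline pool to normal cycles keeps the normalizer from dipping right
after every event, and is applied identically on both sides. Amplitude
and Ttot biases (bench − source) are reported with mean, SD,
2.5/50/97.5 percentiles, the central-95% statistics, a regression of
bench on source, and Bland–Altman limits (mean ± 1.96 SD). Waveform
similarity is the per-pair Pearson r on cycles resampled to the shorter
length (the source method does not state raw vs resampled; equal-length
resampling is the choice here), excluding cycles under 40 samples, split
into obstructed (OA/OH) and unobstructed groups. Apneas match on ≥50%
overlap of the shorter event (again no stated rule); sensitivity, PPV,
onset differences and duration agreement follow, and no specificity is
computed — normal breathing dominates the night, so it would be
uninformative. Cycle-level agreement covers normal and hypopnea breathing
only; apneic cycles are compared at the event level. Self-comparison of a
trace through the symmetric path (`evaluate_traces()`) returns exact
identities, which the tests assert.

## The synthetic night

The generator scripts breathing cycle by cycle: half-sine inspiration
(Ti/Ttot = 0.4), gamma-shaped expiratory decay, volume balanced; Ttot
jitter normal with SD 0.3 s around 4 s, amplitude jitter log-normal with
SD 10% — mid-range adult resting values. Nasal pressure is the signed
square of the airflow at 200 Hz (the exact inverse of the flow estimate),
RIP bands integrate the *drive* airflow at 25 Hz (so obstructive apneas
keep 80% of their effort excursion while central events lose it with the
airflow), RIP flow follows the obstructed airflow, audio carries
inspiratory bursts on snoring cycles at 100 Hz, and the accelerometer
norm sits at 1 g with movement bursts. Event depths are airflow-scale
reductions: 0.95/0.97 for obstructive/central apneas, 0.45–0.6 for
hypopneas — inside the detection bands with physiological margin. The
default two-hour study night (`scenario_sdb_night()`) scripts 44 events
of all four kinds plus two movement bursts, an overall rate near 22/h —
a moderate-to-severe clinical picture.

What passing on this generator shows: every rule of the chain fires on
waveforms with the right geometry, rates, jitter, cross-channel timing
and artifact structure, end to end from an EDF file. What it does not
show: robustness to real-world sensor pathology (cannula drift and
partial displacement, RIP belt slippage, cardiogenic oscillations,
sighs, REM irregularity), to event morphologies outside the template
family, or to scorer-level ambiguity in clinical recordings. The
agreement numbers on synthetic nights are accordingly tighter than those
achievable against physical hardware, where regulator and tube
uncertainty dominate; they validate the software chain, not the bench
electronics.

## Problem sizes and runtime choices

The test suite works on a 10-minute clean night, a 15-minute scripted
night, and one two-hour study night (reused across tests), which keeps
the full suite around a minute while still exercising ≥40 events of all
kinds. The lung round trip uses 100 cycles; the acceptance script uses
the single 3-minute window the cycle-count question is about. AMPD's
scale cap (10 s) bounds its quadratic cost; the IFL network trains in
under a second with analytic gradients.

## Known limitations

* Scoring uses no oximetry: desaturation-linked hypopnea criteria and
  respiratory-effort-related arousals are out of scope, so indices are
  comparable to flow+effort scoring only.
* Flow-limited cycles outside obstructive events are replayed with an
  open resistor (their shape comes through the drive pressure); the two
  alternative replay policies for such cycles are exposed as a
  configuration hook but not implemented.
* The Starling surrogate is memoryless beyond the regulator lag; tube
  hysteresis and the collapse artifact are at best coarsely emulated.
* Short apneas near the 10 s scoring minimum can be lost when re-detected
  on the replayed trace (boundary shrinkage through the envelope), which
  depresses bench-side sensitivity exactly as on physical hardware.
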