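test_that("AMPD finds every cycle of a periodic signal and nothing in a
           constant one", {
  t <- (0:3599) / 20
  pv <- detect_peaks_valleys(sin(2 * pi * t / 4))
  expect_equal(length(pv$peaks), 45, tolerance = 0)
  expect_equal(length(pv$valleys), 45)
  pv <- detect_peaks_valleys(sin(2 * pi * t / 2.5))
  expect_equal(length(pv$peaks), 72)
  expect_length(ampd(rep(1, 500)), 0)
  expect_length(detect_peaks_valleys(numeric(0))$peaks, 0)

  # peaks and valleys strictly alternate
  pv <- detect_peaks_valleys(sin(2 * pi * t / 4) + 0.05 * sin(2 * pi * t))
  ev <- sort(c(pv$peaks, pv$valleys))
  types <- ev %in% pv$peaks
  expect_true(all(diff(types) != 0))
})

test_that("missed-cycle rescue restores a deleted peak but ignores flat
           and sub-threshold gaps", {
  t <- (0:1199) / 20
  f <- sin(2 * pi * t / 4)
  pv <- detect_peaks_valleys(f)
  # delete the 6th peak: analytic location t = 21 s
  del <- pv$peaks[6]
  p2 <- rescue_missed_cycles(f, pv$peaks[-6], pv$valleys)
  expect_true(any(abs(p2$peaks - del) <= 2))

  # flat gap: a 12 s hole of zeros
  f2 <- f
  f2[t >= 20 & t < 32] <- 0
  pv2 <- detect_peaks_valleys(f2)
  pv2$peaks <- pv2$peaks[t[pv2$peaks] < 19 | t[pv2$peaks] > 33]
  n_before <- length(pv2$peaks)
  r2 <- rescue_missed_cycles(f2, pv2$peaks, pv2$valleys)
  expect_equal(sum(t[r2$peaks] > 20 & t[r2$peaks] < 32), 0)

  # sub-threshold ripple (5% of amplitude) is not rescued
  f3 <- f
  f3[t >= 20 & t < 32] <- 0.05 * sin(2 * pi * t[t >= 20 & t < 32] / 4)
  r3 <- rescue_missed_cycles(f3, pv2$peaks, pv2$valleys)
  expect_equal(sum(t[r3$peaks] > 20.5 & t[r3$peaks] < 31.5), 0)
})

test_that("envelope excursion tracks twice the instantaneous amplitude", {
  t <- (0:3599) / 20
  f <- sin(2 * pi * t / 4)
  pv <- detect_peaks_valleys(f)
  exc <- compute_excursion(f, pv$peaks, pv$valleys)
  core <- seq(200, 3400)
  expect_lt(max(abs(exc$excursion[core] - 2)), 0.1)      # within 5%
  expect_true(all(exc$excursion >= 0))

  # amplitude-modulated sine: excursion follows 2x the modulation
  am <- (1 + 0.5 * sin(2 * pi * t / 60))
  f2 <- am * sin(2 * pi * t / 4)
  pv2 <- detect_peaks_valleys(f2)
  exc2 <- compute_excursion(f2, pv2$peaks, pv2$valleys)
  expect_lt(max(abs(exc2$excursion[core] / (2 * am[core]) - 1)), 0.1)

  expect_error(compute_excursion(rep(0, 100), integer(0), integer(0)),
               "at least two")
})

test_that("reduced-excursion segments obey the 65% drop and 4 s duration
           rules", {
  rate <- 20
  exc <- rep(1, 20 * 400)
  exc[(200 * rate):(210 * rate)] <- 0.30      # 10 s at 30% of baseline
  segs <- find_reduced_excursion_segments(exc, rate)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_s, 200, tolerance = 1)
  expect_equal(segs$end_s, 210.05, tolerance = 1)

  exc2 <- rep(1, 20 * 400)
  exc2[(200 * rate):(203 * rate)] <- 0.30     # only 3 s: duration rule
  expect_equal(nrow(find_reduced_excursion_segments(exc2, rate)), 0)
  expect_equal(nrow(find_reduced_excursion_segments(rep(1, 8000), rate)), 0)
})

test_that("the reference RIP channel is the one with higher relative
           modulation; ties go to the thorax", {
  rate <- 20
  t <- (0:(300 * rate - 1)) / rate
  base <- sin(2 * pi * t / 4)
  seg <- list(start_s = 200, end_s = 220)
  damp <- function(x, frac) {
    x[t >= 200 & t < 220] <- frac * x[t >= 200 & t < 220]
    x
  }
  r <- select_reference_rip(damp(base, 0.5), damp(base, 0.1), seg)
  expect_equal(r$channel, "rip_thorax")
  r <- select_reference_rip(damp(base, 0.05), damp(base, 0.8), seg)
  expect_equal(r$channel, "rip_abdomen")
  r <- select_reference_rip(damp(base, 0.4), damp(base, 0.4), seg)
  expect_equal(r$channel, "rip_thorax")   # tie rule
  r <- select_reference_rip(damp(base, 0.001), damp(base, 0.001), seg)
  expect_true(r$flat)
})

test_that("breath onsets sit at the expiratory-to-inspiratory zero
           crossing of a clean periodic flow", {
  t <- (0:3599) / 20
  f <- sin(2 * pi * t / 4)
  pv <- detect_peaks_valleys(f)
  exc <- compute_excursion(f, pv$peaks, pv$valleys)
  cycles <- detect_breath_onsets(f, exc)
  # ascending zero crossings at t = 0, 4, 8, ... (within one sample)
  md <- cycles$onset_s %% 4
  expect_true(all(pmin(md, 4 - md) <= 0.06))
  expect_equal(median(cycles$ttot_s), 4, tolerance = 0.05)
  expect_length(detect_breath_onsets(numeric(0), NULL)$onset_s, 0)
})

test_that("on the clean synthetic night onsets agree with ground truth
           and amplitudes equal the brute-force cycle range", {
  gen <- fixture_clean()
  rec <- gen$record
  pv <- detect_peaks_valleys(rec$vsource)
  pv <- rescue_missed_cycles(rec$vsource, pv$peaks, pv$valleys)
  exc <- compute_excursion(rec$vsource, pv$peaks, pv$valleys)
  cycles <- detect_breath_onsets(rec$vsource, exc,
                                 rec$derived$rip_thorax,
                                 rec$derived$rip_abdomen)
  err <- vapply(cycles$onset_s,
                function(o) min(abs(o - gen$truth$cycles$onset_s)),
                numeric(1))
  expect_gte(mean(err <= 0.15), 0.95)

  # oracle equivalence: amplitude = max - min of flow within the cycle
  idx <- sample(nrow(cycles), 25)
  for (i in idx) {
    a <- round(cycles$onset_s[i] * 20) + 1
    b <- round(cycles$end_s[i] * 20)
    expect_equal(cycles$amplitude[i],
                 max(rec$vsource[a:b]) - min(rec$vsource[a:b]))
  }

  # cycles tile the analysed span
  expect_equal(sum(cycles$ttot_s),
               max(cycles$end_s) - min(cycles$onset_s), tolerance = 1e-9)
})

test_that("during a scripted obstructive apnea, onsets come from the
           reference RIP valleys at the attempt rate", {
  fx <- fixture_short()
  red <- fx$res$reduced
  oa <- fx$gen$truth$events[fx$gen$truth$events$type == "OA", ]
  in_oa <- fx$res$cycles$onset_s >= oa$start_s + 2 &
           fx$res$cycles$onset_s <= oa$end_s - 2
  expect_gt(sum(in_oa), 2)
  expect_true(all(fx$res$cycles$onset_source[in_oa] %in%
                  c("rip_thorax", "rip_abdomen")))
  # attempt spacing matches the scripted cycle period
  expect_equal(median(fx$res$cycles$ttot_s[in_oa]), 4, tolerance = 0.8)
})
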