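mk_cycles <- function(onsets, amp = 1, ttot = diff(c(onsets, max(onsets) + 4)),
                      label = "normal") {
  data.frame(onset_s = onsets, end_s = onsets + ttot, onset_source = "flow",
             ttot_s = ttot, insp_peak_s = onsets + 1,
             exp_valley_s = onsets + 2.5, amplitude = amp, label = label)
}

test_that("cycle pairing is nearest-onset greedy within the window", {
  a <- mk_cycles(seq(0, 396, by = 4))
  m <- match_cycles(a, a)
  expect_equal(nrow(m$pairs), nrow(a))
  expect_true(all(m$pairs$offset_s == 0))

  b <- a; b$onset_s <- b$onset_s + 0.3; b$end_s <- b$end_s + 0.3
  m <- match_cycles(a, b)
  expect_equal(nrow(m$pairs), nrow(a))
  expect_true(all(abs(m$pairs$offset_s - 0.3) < 1e-9))

  c <- a; c$onset_s <- c$onset_s + 1000; c$end_s <- c$end_s + 1000
  m <- match_cycles(a, c)
  expect_equal(nrow(m$pairs), 0)
  expect_length(m$unmatched_source, nrow(a))
})

test_that("amplitude and period bias statistics match their sampling
           oracles", {
  a <- mk_cycles(seq(0, 396, by = 4))
  m <- match_cycles(a, a)
  same <- amplitude_ttot_agreement(a, a, m)
  expect_equal(same$amplitude$mean, 0)
  expect_equal(same$amplitude$sd, 0)
  expect_equal(same$ttot$mean, 0)

  # bench amplitudes 2% above source, matched baselines: +0.02 bias
  b <- a; b$amplitude <- 1.02
  two <- amplitude_ttot_agreement(a, b, m, relative = FALSE)
  expect_equal(two$amplitude$mean, 0.02, tolerance = 1e-12)
  expect_equal(two$amplitude$sd, 0, tolerance = 1e-12)

  # injected period noise: bias distribution recovers mean 0, sd 0.3
  set.seed(7)
  n <- 5000
  src <- mk_cycles(seq(0, by = 4, length.out = n))
  ben <- src
  noise <- rnorm(n, 0, 0.3)
  ben$ttot_s <- ben$ttot_s + noise
  mm <- list(pairs = data.frame(source = 1:n, bench = 1:n, offset_s = 0))
  out <- amplitude_ttot_agreement(src, ben, mm)
  expect_equal(out$ttot$mean, mean(noise), tolerance = 1e-9)
  expect_equal(out$ttot$sd, sd(noise), tolerance = 1e-9)
  expect_equal(out$ttot$mean, 0, tolerance = 0.01)
  expect_equal(out$ttot$sd, 0.3, tolerance = 0.01)
  # Bland-Altman limits are mean +/- 1.96 sd
  expect_equal(out$ttot$loa_upper - out$ttot$loa_lower,
               2 * 1.96 * sd(noise), tolerance = 1e-9)
  expect_error(amplitude_ttot_agreement(a, a,
               list(pairs = data.frame(source = 1, bench = 1,
                                       offset_s = 0))), "two matched")
})

test_that("waveform correlation is 1 for identical, -1 for flipped, and
           attenuated by noise as predicted", {
  rate <- 20
  t <- seq(0, 400 - 1 / rate, by = 1 / rate)
  flow <- template_flow(t, ttot = 4, amp = 1)
  cyc <- mk_cycles(seq(0, 396, by = 4))
  m <- match_cycles(cyc, cyc)
  same <- morphology_correlation(cyc, cyc, m, flow, flow)
  expect_equal(same$unobstructed$mean, 1, tolerance = 1e-12)
  flipped <- morphology_correlation(cyc, cyc, m, flow, -flow)
  expect_equal(flipped$unobstructed$mean, -1, tolerance = 1e-12)

  # analytic attenuation: r ~ 1 / sqrt(1 + sigma^2/var(signal))
  set.seed(3)
  noisy <- flow + rnorm(length(flow), 0, 0.1)
  out <- morphology_correlation(cyc, cyc, m, flow, noisy)
  pred <- 1 / sqrt(1 + 0.01 / stats::var(flow))
  expect_equal(out$unobstructed$mean, pred, tolerance = 0.01)

  # cycles under 40 samples (2 s at 20 Hz) are excluded
  short <- mk_cycles(seq(0, 398, by = 1.5), ttot = 1.5)
  ms <- match_cycles(short, short)
  outs <- morphology_correlation(short, short, ms, flow, flow)
  expect_equal(outs$unobstructed$n, 0)
  expect_gt(outs$n_excluded, 0)
})

test_that("apnea agreement counts matched, missed and spurious events", {
  ev <- function(onsets, dur = 20)
    data.frame(kind = "OA", onset_s = onsets, duration_s = dur,
               baseline_excursion = 1, evidence = "", n_attempts = 1L,
               n_sig_attempts = 1L)
  ten <- ev(seq(100, by = 100, length.out = 10))
  same <- apnea_agreement(ten, ten)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$ppv, 1)
  expect_equal(same$onset_diff$mean, 0)

  nine <- apnea_agreement(ten, ten[-1, ])
  expect_equal(nine$sensitivity, 0.9)
  expect_equal(nine$ppv, 1)

  extra <- apnea_agreement(ten, ev(c(seq(100, by = 100, length.out = 10),
                                     5000, 6000)))
  expect_equal(extra$ppv, 10 / 12)
  expect_equal(extra$sensitivity, 1)

  # under 50% overlap does not match
  shifted <- ev(seq(100, by = 100, length.out = 10) + 15)
  expect_equal(apnea_agreement(ten, shifted)$sensitivity, 0)
})

test_that("bias statistics are antisymmetric under swapping the traces", {
  fx <- fixture_short()
  v <- fx$res$record$vsource
  set.seed(8)
  w <- v * 1.01 + rnorm(length(v), 0, 0.005)
  ab <- evaluate_traces(v, w)
  ba <- evaluate_traces(w, v)
  expect_equal(ab$ttot$mean, -ba$ttot$mean, tolerance = 0.02)
  expect_equal(abs(ab$amplitude$mean), abs(ba$amplitude$mean),
               tolerance = 0.5)
})
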