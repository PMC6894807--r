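test_that("apnea detection needs a deep drop, 10 s, and a confirmed
           second channel", {
  rate <- 20
  n <- 400 * rate
  mk_exc <- function(drop_to, from, to) {
    e <- rep(1, n)
    e[(from * rate):(to * rate)] <- drop_to
    e
  }
  # 95% drop for 15 s with a 50% confirmation drop: one apnea
  exc <- mk_exc(0.05, 200, 215)
  conf <- mk_exc(0.5, 200, 215)
  ev <- detect_apneas(exc, conf, rate)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 200, tolerance = 1)
  expect_equal(ev$duration_s, 15, tolerance = 1.5)

  # 8 s: below the minimum duration
  expect_equal(nrow(detect_apneas(mk_exc(0.05, 200, 208),
                                  mk_exc(0.5, 200, 208), rate)), 0)

  # confirmation drop of only 5% (mouth-breathing mimic): rejected
  expect_equal(nrow(detect_apneas(exc, mk_exc(0.95, 200, 215), rate)), 0)

  # above the 3-minute cap: sensor-displacement guard
  expect_equal(nrow(detect_apneas(mk_exc(0.05, 100, 350),
                                  mk_exc(0.5, 100, 350), rate)), 0)

  # no confirmation channel: dropped with a warning by default
  expect_warning(none <- detect_apneas(exc, NULL, rate), "unconfirmed")
  expect_equal(nrow(none), 0)
  expect_equal(nrow(detect_apneas(exc, NULL, rate,
                                  require_confirmation = FALSE)), 1)
})

test_that("apneas are typed by significant effort attempts in the
           reference RIP band", {
  rate <- 20
  t <- (0:(400 * rate - 1)) / rate
  ev <- data.frame(kind = NA_character_, onset_s = 200, duration_s = 20,
                   baseline_excursion = 1, evidence = "", n_attempts = 0L,
                   n_sig_attempts = 0L)
  mk_rip <- function(event_frac) {
    x <- sin(2 * pi * t / 4)
    x[t >= 200 & t < 220] <- event_frac * x[t >= 200 & t < 220]
    x
  }
  exc_of <- function(x) {
    pv <- detect_peaks_valleys(x, rate)
    compute_excursion(x, pv$peaks, pv$valleys, rate)$excursion
  }
  rip <- mk_rip(0.4)                      # attempts at 40% of baseline
  out <- classify_apnea(ev, rip, exc_of(rip), rate)
  expect_equal(out$kind, "OA")
  expect_gt(out$n_sig_attempts, 0)
  expect_true(all(attr(out, "attempts")$significant))

  rip <- mk_rip(0.005)                    # essentially flat: central
  out <- classify_apnea(ev, rip, exc_of(rip), rate)
  expect_equal(out$kind, "CA")

  rip <- mk_rip(0.05)                     # attempts below 10% of baseline
  out <- classify_apnea(ev, rip, exc_of(rip), rate)
  expect_equal(out$kind, "CA")
  expect_equal(out$n_sig_attempts, 0)
})

test_that("hypopnea detection needs a 30% drop, duration bounds and a 10%
           confirmation drop, and yields to apneas", {
  rate <- 20
  n <- 400 * rate
  mk <- function(drop_to, from, to) {
    e <- rep(1, n)
    e[(from * rate):(to * rate)] <- drop_to
    e
  }
  ev <- detect_hypopneas(mk(0.5, 200, 220), mk(0.8, 200, 220), rate = rate)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 200, tolerance = 1)

  # 20% drop: below the hypopnea threshold
  expect_equal(nrow(detect_hypopneas(mk(0.8, 200, 220), mk(0.8, 200, 220),
                                     rate = rate)), 0)
  # 200 s: beyond the 3-minute cap
  expect_equal(nrow(detect_hypopneas(mk(0.5, 100, 300), mk(0.8, 100, 300),
                                     rate = rate)), 0)
  # an apnea on the same interval takes precedence
  ap <- data.frame(kind = "OA", onset_s = 199, duration_s = 22,
                   baseline_excursion = 1, evidence = "", n_attempts = 1L,
                   n_sig_attempts = 1L)
  expect_equal(nrow(detect_hypopneas(mk(0.5, 200, 220), mk(0.8, 200, 220),
                                     apneas = ap, rate = rate)), 0)
})

test_that("snoring is an inspiratory/expiratory audio power imbalance", {
  rate <- 20
  t <- (0:199) / rate
  flow <- template_flow(t, ttot = 4, amp = 0.5)
  cycle <- data.frame(onset_s = 0, end_s = 4, insp_peak_s = 0.8,
                      exp_valley_s = 2.2)
  insp <- t < 1.6
  audio <- rep(0.5, length(t))
  audio[insp] <- 5                                  # 10x inspiratory power
  expect_true(detect_snore(audio, cycle, flow, rate))
  expect_false(detect_snore(rep(0.5, length(t)), cycle, flow, rate))
  audio2 <- rep(0.1, length(t))
  audio2[!insp] <- 5                                # expiratory-only noise
  expect_false(detect_snore(audio2, cycle, flow, rate))
})

test_that("thoracoabdominal paradox follows the extrema-closeness rule", {
  rate <- 20
  t <- (0:99) / rate
  thorax <- sin(2 * pi * t / 5)
  cycle <- data.frame(onset_s = 0, end_s = 5, insp_peak_s = 1.25,
                      exp_valley_s = 3.75)
  expect_true(detect_paradox(thorax, -thorax, cycle, rate))
  expect_false(detect_paradox(thorax, thorax, cycle, rate))
  # 90 degree lag: analytically, thorax peak t=1.25, abdomen peak t=2.5,
  # abdomen valley t=0 on [0,5) -> both distances 1.25, tie is not paradox
  shifted <- sin(2 * pi * t / 5 - pi / 2)
  expect_false(detect_paradox(thorax, shifted, cycle, rate))
  expect_false(detect_paradox(thorax, rep(1, length(t)), cycle, rate))
})

test_that("hypopnea typing requires evidence; flow-limitation evidence
           needs at least two cycles", {
  ev <- data.frame(kind = NA_character_, onset_s = 0, duration_s = 20,
                   baseline_excursion = 1, evidence = "", n_attempts = 0L,
                   n_sig_attempts = 0L)
  out <- classify_hypopnea(ev, snore = c(FALSE, FALSE),
                           paradox = c(TRUE, FALSE), ifl = c(FALSE, FALSE))
  expect_equal(out$kind, "OH")
  expect_equal(out$evidence, "paradox")
  out <- classify_hypopnea(ev, rep(FALSE, 3), rep(FALSE, 3), rep(FALSE, 3))
  expect_equal(out$kind, "CH")
  out <- classify_hypopnea(ev, c(TRUE, FALSE), rep(FALSE, 2), c(TRUE, TRUE))
  expect_equal(out$kind, "OH")
  expect_equal(out$evidence, "snore,ifl")
  # a single flow-limited cycle is not enough on its own
  out <- classify_hypopnea(ev, rep(FALSE, 3), rep(FALSE, 3),
                           c(TRUE, FALSE, FALSE))
  expect_equal(out$kind, "CH")
})

test_that("the scripted short night is scored with the right kinds,
           onsets and durations", {
  fx <- fixture_short()
  truth <- fx$gen$truth$events
  det <- fx$res$events
  expect_equal(nrow(det), 4)
  m <- match_truth_events(truth, det)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$kind_agreement, 1)
  # onsets within a breath of the script
  for (i in seq_len(nrow(truth))) {
    j <- which.min(abs(det$onset_s - truth$start_s[i]))
    expect_lt(abs(det$onset_s[j] - truth$start_s[i]), 5)
  }
  # scored durations within the AASM window
  expect_true(all(det$duration_s >= 10 & det$duration_s <= 180))
  # events never overlap
  o <- order(det$onset_s)
  expect_true(all(det$onset_s[o][-1] >=
                  (det$onset_s + det$duration_s)[o][-4]))
})
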