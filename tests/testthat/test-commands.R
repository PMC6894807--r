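test_that("drive estimation copies unobstructed cycles and reconstructs
           obstructive ones as baseline-amplitude sinusoids", {
  rate <- 20
  t <- (0:(200 * rate - 1)) / rate
  flow <- template_flow(t, ttot = 4, amp = 0.5)
  onsets <- seq(0, 196, by = 4)
  cycles <- data.frame(onset_s = onsets, end_s = onsets + 4,
                       onset_source = "flow", ttot_s = 4,
                       insp_peak_s = onsets + 0.8,
                       exp_valley_s = onsets + 2.2,
                       amplitude = NA_real_, label = "normal")
  for (i in seq_len(nrow(cycles))) {
    a <- round(cycles$onset_s[i] * rate) + 1
    b <- round(cycles$end_s[i] * rate)
    cycles$amplitude[i] <- max(flow[a:b]) - min(flow[a:b])
  }
  # obstruct cycles 41-45 (t in [160, 180)): near-zero flow, label OA
  oa <- 41:45
  obs <- t >= 160 & t < 180
  flow2 <- flow
  flow2[obs] <- 0.03 * flow[obs]
  cycles$label[oa] <- "OA"
  cycles$amplitude[oa] <- cycles$amplitude[oa] * 0.03

  est <- estimate_vcc(flow2, cycles, rate)
  # normal cycle: identity branch
  a <- round(cycles$onset_s[3] * rate) + 1; b <- round(cycles$end_s[3] * rate)
  expect_equal(est$vcc[a:b], flow2[a:b])
  # obstructive cycle: half-sine at the pre-event baseline amplitude
  i <- 43
  a <- round(cycles$onset_s[i] * rate) + 1; b <- round(cycles$end_s[i] * rate)
  w <- est$vcc[a:b]
  base <- mean(cycles$amplitude[1:40])
  ti <- est$cycles$ti_s[i]; te <- est$cycles$te_s[i]
  expect_equal(max(w), base * te / (ti + te), tolerance = 0.05)
  # analytic half-sine shape over the inspiratory time
  tau <- (seq(a, b) - a) / rate
  ref <- ifelse(tau < ti, max(w) * sin(pi * tau / ti),
                -max(w) * ti / te * sin(pi * (tau - ti) / te))
  expect_lt(sqrt(mean((w - ref)^2)) / max(w), 0.05)

  # central cycles copy the (near-zero) source
  cycles$label[oa] <- "CA"
  est2 <- estimate_vcc(flow2, cycles, rate)
  expect_equal(est2$vcc[a:b], flow2[a:b])
  expect_lt(max(abs(est2$vcc[a:b])), 0.03)
})

test_that("volume equilibration balances the phases by scaling the
           lesser one", {
  rate <- 20
  t <- (0:79) / rate
  sym <- sin(2 * pi * t / 4)
  expect_equal(equilibrate_volumes(sym, rate), sym, tolerance = 1e-12,
               ignore_attr = TRUE)

  # inspiration 0.6 L, expiration 0.5 L -> expiration scaled by 1.2
  insp <- c(rep(0.6, 20), rep(0, 0))
  expi <- rep(-0.5, 20)
  x <- c(insp, expi)                       # 1 s each at 20 Hz
  out <- equilibrate_volumes(x, rate)
  expect_equal(out[21:40], expi * 1.2, tolerance = 1e-9)
  expect_equal(sum(out) / rate, 0, tolerance = 1e-9)

  z <- equilibrate_volumes(rep(0, 40), rate)
  expect_true(attr(z, "flagged"))
  expect_equal(as.numeric(z), rep(0, 40))

  # property: balanced volumes on arbitrary cycles
  set.seed(31)
  for (k in 1:20) {
    x <- template_flow((0:79) / rate, ttot = 4, amp = runif(1, 0.2, 1)) +
      rnorm(80, 0, 0.02)
    out <- equilibrate_volumes(x, rate)
    expect_lt(abs(sum(out) / rate), 1e-6)
  }
})

test_that("the muscular-effort pressure follows the lung equation with
           per-cycle volume resets", {
  lung <- lung_model()
  expect_equal(as.numeric(compute_pmus(rep(0, 100), lung)), rep(0, 100))

  # hand-evaluated point: V = 0.25 L, vdot = 0.5 L/s
  # pmus = -0.25/0.08 - 7.25 * 0.5 = -6.75 cmH2O
  expect_equal(-0.25 / 0.08 - 7.25 * 0.5, -6.75)

  # brute-force trapezoid oracle on a half-sine
  rate <- 20
  t <- (0:199) / rate
  vcc <- ifelse(t < 4, sin(pi * t / 4), 0)
  pmus <- compute_pmus(vcc, lung)
  v <- 0
  for (i in 2:length(vcc)) {
    v <- v + (vcc[i] + vcc[i - 1]) / 2 / rate
    expect_equal(pmus[i], -v / lung$C - lung$R * vcc[i], tolerance = 1e-9)
  }

  # volume resets at each trigger
  p2 <- compute_pmus(rep(0.5, 100), lung, triggers = c(1, 51))
  vol <- attr(p2, "volume")
  expect_equal(vol[51], 0)
})

test_that("the Starling calibration is monotone and its inverse recovers
           target amplitude ratios through forward simulation", {
  st <- calibrate_starling(starling_model())
  cal <- st$calibration
  expect_true(all(abs(cal$insp[, 1] - 1) < 1e-9))      # pch = 0: open
  expect_true(all(cal$insp[, ncol(cal$insp)] < 1e-9))  # pch >> pus: closed
  for (r in seq_len(nrow(cal$insp)))
    expect_true(all(diff(cal$insp[r, ]) <= 1e-12))

  rate <- 20
  tau <- seq(0, 4 - 1 / rate, by = 1 / rate)
  wave <- ifelse(tau < 1.6, 0.5 * sin(pi * tau / 1.6),
                 -0.5 * (1.6 / 2.4) * sin(pi * (tau - 1.6) / 2.4))
  pv_in <- max(wave) - min(wave)
  for (ratio in c(1, 0.6, 0.3, 0)) {
    p <- compute_pch(TRUE, pv_in, ratio * pv_in, st)
    tr <- simulate_starling(wave, p, st, 1L, regulator_tau = 0)
    achieved <- (max(tr$vbench) - min(tr$vbench)) / pv_in
    expect_equal(achieved, ratio, tolerance = 0.05)
  }
  # full occlusion demands at least the closing pressure
  expect_gte(compute_pch(TRUE, pv_in, 0, st), st$pus - 1e-6)
  # non-obstructive cycles stay fully open
  expect_equal(compute_pch(FALSE, 1, 1, st), st$pch_min)
  expect_warning(open <- compute_pch(TRUE, 0.5, 0.7, st), "clamping")
  expect_equal(open, st$pch_min)
  expect_error(compute_pch(TRUE, 1, 0.5, starling_model()),
               "not calibrated")
})
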