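test_that("the virtual lung inverts the command equation and relaxes with
           the RC time constant", {
  lung <- lung_model()
  expect_equal(as.numeric(simulate_lung(rep(0, 100), lung)), rep(0, 100))

  # command/replay round trip on a 100-cycle drive
  rate <- 20
  t <- seq(0, 400 - 1 / rate, by = 1 / rate)
  vcc <- template_flow(t, ttot = 4, amp = 0.5)
  trig <- round(seq(0, 396, by = 4) * rate) + 1
  back <- simulate_lung(compute_pmus(vcc, lung, trig), lung, trig)
  expect_lt(sqrt(mean((back - vcc)^2)) / sqrt(mean(vcc^2)), 0.02)

  # step: flow decays toward zero as volume fills, tau = R*C = 0.58 s
  fl <- as.numeric(simulate_lung(rep(-1, 200), lung))
  expect_equal(fl[1], 1 / lung$R, tolerance = 1e-9)
  t63 <- (which(fl <= fl[1] * exp(-1))[1] - 1) / 20
  expect_equal(t63, lung$R * lung$C, tolerance = 0.15)
})

test_that("the Starling surrogate is transparent when open, occludes when
           pch exceeds pus, and attenuates monotonically", {
  st <- starling_model()
  rate <- 20
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  flow <- template_flow(t, ttot = 4, amp = 0.5)
  trig <- round(seq(0, 36, by = 4) * rate) + 1

  open <- simulate_starling(flow, rep(0, 10), st, trig, regulator_tau = 0)
  expect_equal(open$vbench, flow)

  # one fully occluded cycle
  pch <- rep(0, 10); pch[5] <- 10
  occ <- simulate_starling(flow, pch, st, trig, regulator_tau = 0)
  cyc5 <- seq(trig[5], trig[6] - 1)
  expect_lt(max(abs(occ$vbench[cyc5])), 1e-9)
  expect_equal(occ$vbench[-cyc5], flow[-cyc5])

  # amplitude non-increasing in pch
  amps <- vapply(seq(0, 5, by = 0.5), function(p) {
    tr <- simulate_starling(flow, rep(p, 10), st, trig, regulator_tau = 0)
    max(tr$vbench) - min(tr$vbench)
  }, numeric(1))
  expect_true(all(diff(amps) <= 1e-12))

  # regulator causality: effective pch rises only after the trigger
  lag <- simulate_starling(flow, pch, st, trig, regulator_tau = 0.3)
  expect_lt(max(lag$pch_applied[seq_len(trig[5] - 1)]), 1e-6)
  expect_gt(lag$pch_applied[trig[5] + 10], 5)
})

test_that("replaying a command set conserves cycles and reproduces
           scripted obstructive apneas as deep amplitude reductions", {
  fx <- fixture_short()
  res <- fx$res
  trace <- run_bench(res$commands)
  expect_equal(nrow(trace), length(res$commands$vcc))
  expect_true(all(is.finite(trace$vbench)))

  # bench cycle count close to the command cycle count
  bench <- analyse_flow_trace(trace$vbench)
  expect_lt(abs(nrow(bench$cycles) - nrow(res$cycles)) /
            nrow(res$cycles), 0.15)

  # scripted OA: >= 90% amplitude reduction on the bench once the chamber
  # regulator has settled (the first occluded cycle carries the settling
  # transient, as the physical regulator would)
  oa <- fx$gen$truth$events[fx$gen$truth$events$type == "OA", ]
  rate <- 20
  i_ev <- seq(round((oa$start_s + 6) * rate), round((oa$end_s - 2) * rate))
  i_pre <- seq(round((oa$start_s - 60) * rate), round(oa$start_s * rate))
  amp_ev <- max(trace$vbench[i_ev]) - min(trace$vbench[i_ev])
  amp_pre <- max(trace$vbench[i_pre]) - min(trace$vbench[i_pre])
  expect_lt(amp_ev / amp_pre, 0.10)

  # empty command set -> empty trace
  empty <- structure(list(t = numeric(0), vcc = numeric(0),
                          pmus = numeric(0),
                          cycles = data.frame(pch_cmh2o = numeric(0)),
                          triggers = integer(0), lung = lung_model(),
                          starling = res$commands$starling),
                     class = "bench_command_set")
  expect_equal(nrow(run_bench(empty)), 0)

  # unordered cycles are rejected
  bad <- res$commands
  bad$triggers <- rev(bad$triggers)
  expect_error(run_bench(bad), "unordered")
})
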