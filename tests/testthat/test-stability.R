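test_that("frame energy matches the definition: 100-sample frames, 50%
           overlap, sum of squares", {
  fe <- frame_energy(rep(1, 1000))
  expect_true(all(fe$energies == 100))
  expect_length(fe$energies, 19)          # trailing partial frame dropped
  expect_true(all(frame_energy(rep(0, 500))$energies == 0))

  set.seed(21)
  x <- rnorm(730)
  fe <- frame_energy(x)
  # brute-force oracle: explicit per-frame loop
  starts <- seq(1, length(x) - 99, by = 50)
  oracle <- vapply(starts, function(s) sum(x[s:(s + 99)]^2), numeric(1))
  expect_equal(fe$energies, oracle)

  expect_warning(fe0 <- frame_energy(rnorm(50)), "shorter")
  expect_length(fe0$energies, 0)
})

test_that("the adaptive threshold machinery has the stated shape:
           1080 resampled energies, 359 slopes, scan start at 90", {
  set.seed(22)
  for (n in c(1080, 2879, 5000)) {
    d <- attr(suppressWarnings(adaptive_energy_threshold(runif(n, 0, 2))),
              "details")
    expect_length(d$sorted_resampled, 1080)
    expect_length(d$slopes, 359)
    expect_identical(d$scan_start, 90)
  }
})

test_that("the threshold separates a rest plateau from a movement ramp and
           is order-invariant and scale-equivariant", {
  set.seed(2)
  e <- sample(c(runif(950, 0.9, 1.1), seq(1.2, 1000, length.out = 130)))
  thr <- as.numeric(adaptive_energy_threshold(e))
  expect_gte(thr, 0.9)
  expect_lte(thr, 2.0)
  expect_true(all(e[e > 2] >= thr))       # all ramp frames unstable

  expect_equal(as.numeric(adaptive_energy_threshold(rev(sort(e)))), thr)
  expect_equal(as.numeric(adaptive_energy_threshold(7 * e)), 7 * thr)

  expect_error(adaptive_energy_threshold(runif(5)), "at least")
  # no slope jump anywhere: whole night is declared stable
  e_flat <- runif(2000, 1, 1.001)
  expect_warning(flat <- adaptive_energy_threshold(e_flat),
                 "whole night stable")
  expect_equal(as.numeric(flat), max(e_flat))
})

test_that("stable frames merge into intervals; short movement gaps are
           absorbed, long ones split the night", {
  fe <- frame_energy(rep(1, 40000))
  sp <- segment_stable_periods(fe, 200)
  expect_equal(nrow(sp$intervals), 1)
  expect_lt(sp$intervals$start_s[1], 5)

  # 60 s burst: absorbed, flagged
  fe <- frame_energy(c(rep(1, 20000), rep(5, 1200), rep(1, 20000)))
  sp <- segment_stable_periods(fe, 200)
  expect_equal(nrow(sp$intervals), 1)
  expect_true(sp$intervals$has_gap[1])

  # 300 s burst: two disjoint intervals (oracle: interval arithmetic)
  fe <- frame_energy(c(rep(1, 20000), rep(5, 6000), rep(1, 20000)))
  sp <- segment_stable_periods(fe, 200)
  expect_equal(nrow(sp$intervals), 2)
  expect_equal(sp$intervals$end_s[1], 1000, tolerance = 5)
  expect_equal(sp$intervals$start_s[2], 1300, tolerance = 5)
})

test_that("on a synthetic night the ground-truth rest frames are all
           classified stable", {
  set.seed(23)
  accel <- abs(1 + rnorm(72000, 0, 0.01))           # 1 h, mostly at rest
  move <- rep(FALSE, 72000)
  for (s in c(10000, 30000, 55000))                 # three 2.5 min bursts
    move[s:(s + 3000)] <- TRUE
  accel[move] <- abs(accel[move] + rnorm(sum(move), 0, 1.2))
  fe <- frame_energy(accel)
  thr <- adaptive_energy_threshold(fe)
  starts <- round(fe$frame_times * 20 - 50)
  rest_frames <- vapply(starts, function(s)
    !any(move[max(1, s):min(72000, s + 99)]), logical(1))
  move_frames <- vapply(starts, function(s)
    all(move[max(1, s):min(72000, s + 99)]), logical(1))
  # frames straddling a rest/movement boundary blur the sorted-energy
  # jump, so the change point can land within the last few rest order
  # statistics; virtually all rest frames must still be stable, and every
  # fully-moving frame unstable
  expect_gte(mean(fe$energies[rest_frames] < as.numeric(thr)), 0.99)
  expect_true(all(fe$energies[move_frames] >= as.numeric(thr)))
})

test_that("stable periods export to BED-like text and JSON", {
  fe <- frame_energy(c(rep(1, 20000), rep(5, 6000), rep(1, 20000)))
  sp <- segment_stable_periods(fe, 200)
  bed <- withr::local_tempfile(fileext = ".bed")
  js <- withr::local_tempfile(fileext = ".json")
  write_stable_periods(sp, bed, "bed")
  write_stable_periods(sp, js, "json")
  expect_equal(nrow(read.table(bed)), 2)
  expect_length(jsonlite::read_json(js)$intervals, 2)
})
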