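# Shared fixtures, computed once per test run and memoized. All synthetic,
# generated in code; seeds fixed so every run sees identical data.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 10-minute clean night (no events): generator + preprocessing
fixture_clean <- function() memo("clean", {
  gen <- generate_polygraph(synthetic_scenario(duration_s = 600, seed = 1))
  gen$record <- preprocess_polygraph(gen$record)
  gen
})

# 15-minute night with one event of each kind, processed end to end
fixture_short <- function() memo("short", {
  ev <- data.frame(
    type = c("OA", "CA", "OH", "CH"),
    onset_s = c(300, 460, 620, 780),
    duration_s = c(20, 22, 24, 24),
    depth = c(0.95, 0.97, 0.5, 0.5))
  gen <- generate_polygraph(synthetic_scenario(duration_s = 900, events = ev,
                                               seed = 7))
  res <- process_polygraph(gen$record)
  list(gen = gen, res = res)
})

# the two-hour scripted night of the acceptance analyses, with the bench
# replay and the evaluation report
fixture_night <- function() memo("night", {
  gen <- generate_polygraph(scenario_sdb_night(seed = 1))
  res <- process_polygraph(gen$record)
  trace <- run_bench(res$commands)
  report <- evaluate_bench(res$record$vsource, res$cycles, res$events,
                           trace$vbench)
  list(gen = gen, res = res, trace = trace, report = report)
})

# overlap-based event matching against generator ground truth
match_truth_events <- function(truth, detected, overlap_frac = 0.5) {
  used <- logical(nrow(detected))
  hits <- 0L; kind_ok <- 0L
  for (i in seq_len(nrow(truth))) {
    s0 <- truth$start_s[i]; s1 <- truth$end_s[i]
    best <- 0; bj <- NA_integer_
    for (j in seq_len(nrow(detected))) {
      if (used[j]) next
      d0 <- detected$onset_s[j]; d1 <- d0 + detected$duration_s[j]
      ov <- min(s1, d1) - max(s0, d0)
      sh <- min(s1 - s0, d1 - d0)
      if (ov > 0 && ov / sh >= overlap_frac && ov > best) {
        best <- ov; bj <- j
      }
    }
    if (!is.na(bj)) {
      used[bj] <- TRUE
      hits <- hits + 1L
      if (truth$type[i] == detected$kind[bj]) kind_ok <- kind_ok + 1L
    }
  }
  list(sensitivity = hits / nrow(truth),
       ppv = hits / nrow(detected),
       kind_agreement = kind_ok / max(hits, 1L))
}

# asymmetric breath template sampled on a grid (matches the generator)
template_flow <- function(t, ttot = 4, ti = 0.4 * ttot, amp = 0.5) {
  tau <- t %% ttot
  te <- ttot - ti
  tp <- te / 4
  vt <- 2 * amp * ti / pi
  ae <- vt / (exp(1) * tp * (1 - 5 * exp(-4)))
  ifelse(tau < ti, amp * sin(pi * tau / ti),
         -ae * ((tau - ti) / tp) * exp(1 - (tau - ti) / tp))
}
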