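fake_curves <- function(pos, neg = -pos) {
  structure(list(frame = seq_along(pos) - 1L, pos = pos, neg = neg,
                 sample_rate_hz = 60),
            class = "dgei_curves")
}

test_that("candidate extrema require a strict interior peak above baseline", {
  cv <- fake_curves(c(0, 1, 3, 1, 0))
  cand <- candidate_peaks(cv, bar = 2)
  expect_equal(cand$to$frame, 2)
  expect_equal(cand$to$value, 3)
  expect_equal(cand$hs$frame, 2)  # mirrored trough on the negative curve
  # monotone curve: no interior extremum
  expect_equal(nrow(candidate_peaks(fake_curves(c(0, 1, 2, 3, 4)), 0)$to), 0)
  # below-baseline peaks are filtered
  expect_equal(nrow(candidate_peaks(fake_curves(c(0, 1, 3, 1, 0)), 5)$to), 0)
})

test_that("a plateau yields one candidate at its first frame", {
  cv <- fake_curves(c(0, 1, 4, 4, 4, 1, 0))
  cand <- candidate_peaks(cv, bar = 2)
  expect_equal(cand$to$frame, 2)
  expect_equal(nrow(cand$to), 1)
})

test_that("ripples on one excursion count once until the baseline re-arms", {
  # two local maxima without an intervening drop to the baseline: one event
  cv <- fake_curves(c(0, 5, 9, 8, 10, 7, 0, 6, 9, 0))
  cand <- candidate_peaks(cv, bar = 2)
  expect_equal(cand$to$frame, c(2, 8))
})

test_that("the validation rules gate sleep, threshold and alternation", {
  cfg <- detector_config(sleeptime0 = 60, threshold0 = 0, sleep_margin = 1)
  st <- gaitdgei:::new_detector_state(cfg)
  step <- function(st, frame, type, value) {
    gaitdgei:::detector_step(st, list(frame = frame, refined = frame,
                                      type = type, value = value))
  }
  r1 <- step(st, 100, "TO", 50)           # first event seeds the queues
  expect_true(r1$accepted)
  r2 <- step(r1$state, 105, "TO", 60)     # refractory: 5 frames after a TO
  expect_false(r2$accepted)
  expect_equal(r2$log$reason, "sleep")
  r3 <- step(r2$state, 130, "HS", 55)     # other type has its own refractory
  expect_true(r3$accepted)
  r4 <- step(r3$state, 190, "HS", 1)      # amplitude below the 60% rule
  expect_false(r4$accepted)
  expect_equal(r4$log$reason, "threshold")
  r5 <- step(r4$state, 191, "HS", 55)     # same type as last accepted event
  expect_false(r5$accepted)
  expect_equal(r5$log$reason, "alternation")
  r6 <- step(r5$state, 195, "TO", 60)
  expect_true(r6$accepted)
  expect_error(step(r6$state, 50, "TO", 60), "frame order")
})

test_that("an alternating steady stream is accepted in full", {
  cfg <- detector_config(sleeptime0 = 60, threshold0 = 0, sleep_margin = 1)
  st <- gaitdgei:::new_detector_state(cfg)
  frames <- seq(0, by = 30, length.out = 20)
  types <- rep(c("TO", "HS"), 10)
  for (i in seq_along(frames)) {
    r <- gaitdgei:::detector_step(st, list(frame = frames[i],
                                           refined = frames[i],
                                           type = types[i], value = 100))
    expect_true(r$accepted)
    st <- r$state
  }
})

test_that("a flat signal produces no events at all", {
  ev <- run_detector(gait_signal(rep(0, 400)))
  expect_equal(nrow(ev), 0)
})

test_that("clean gait is recovered in full with the default profile", {
  sc <- clean_walk(20)
  ev <- run_detector(sc$signal)
  expect_equal(sum(ev$type == "TO"), 20)
  expect_equal(sum(ev$type == "HS"), 20)
  expect_equal(sum(ev$type == "WS"), 1)
  expect_equal(sum(ev$type == "WP"), 0)
  expect_equal(frames_of(ev, "TO"), frames_of(sc$truth, "TO"))
  expect_equal(frames_of(ev, "HS"), frames_of(sc$truth, "HS"))
  expect_true(!is.unsorted(ev$frame))
  assert_detector_invariants(ev)
})

test_that("detection is deterministic across repeated runs", {
  sc <- generate_scenario(scenario_spec("tremor_pathological",
                                        n_cycles = 10, seed = 8))
  e1 <- run_detector(sc$signal)
  e2 <- run_detector(sc$signal)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(attr(e1, "state_log"), attr(e2, "state_log"))
})

test_that("walk transitions mark starts and pauses around quiet spans", {
  sp <- splice_scenarios(list(
    scenario_spec("standard_locomotion", n_cycles = 10, period_jitter = 0,
                  amplitude_jitter = 0, noise_sd = 0, seed = 1),
    scenario_spec("static_posture", n_cycles = 6, seed = 2),
    scenario_spec("standard_locomotion", n_cycles = 10, period_jitter = 0,
                  amplitude_jitter = 0, noise_sd = 0, seed = 3)))
  ev <- run_detector(sp$signal)
  expect_equal(sum(ev$type == "WP"), 1)
  expect_equal(sum(ev$type == "WS"), 2)
  wp <- ev$frame[ev$type == "WP"]
  ws <- sort(ev$frame[ev$type == "WS"])
  expect_lt(wp, ws[2])          # the pause precedes the restart
  expect_gt(wp, ws[1])
  # continuous walking: a single start, no pauses
  ev2 <- run_detector(clean_walk(15)$signal)
  expect_equal(sum(ev2$type == "WS"), 1)
  expect_equal(sum(ev2$type == "WP"), 0)
})

test_that("tremor spikes inside refractory spans never alter the output", {
  sc <- clean_walk(10, seed = 3)
  base <- run_detector(sc$signal)
  v <- sc$signal$values
  # quiet zones away from any event refinement window
  truth_fr <- sc$truth$frame[sc$truth$type %in% c("HS", "TO")]
  quiet <- which(abs(v) < 2) - 1L
  quiet <- quiet[vapply(quiet, function(f) all(abs(f - truth_fr) > 12), TRUE)]
  quiet <- quiet[quiet > 12 & quiet < length(v) - 12]
  set.seed(77)
  for (rep_i in 1:100) {
    f <- sample(quiet, 1)
    vv <- v
    idx <- (f + 1):(f + 3)
    vv[idx] <- vv[idx] + 0.25 * 30 * c(0.5, 1, 0.5)  # < 0.3x the gait peak
    ev <- run_detector(gait_signal(vv))
    expect_identical(ev$frame, base$frame)
    expect_identical(ev$type, base$type)
  }
})

test_that("halving the step period pulls the sleep time down within q events", {
  ad <- splice_scenarios(list(
    scenario_spec("standard_locomotion", n_cycles = 8, period_frames = 80,
                  period_jitter = 0, amplitude_jitter = 0, noise_sd = 0,
                  seed = 1),
    scenario_spec("standard_locomotion", n_cycles = 10, period_frames = 40,
                  period_jitter = 0, amplitude_jitter = 0, noise_sd = 0,
                  seed = 2)))
  cfg <- detector_config(sleeptime0 = 80, sleep_floor = 20, sleep_margin = 1)
  ev <- run_detector(ad$signal, config = cfg)
  log <- attr(ev, "state_log")
  to <- log[log$type == "TO", , drop = FALSE]
  switch_frame <- 8 * 80
  after <- to$sleeptime[to$cand_frame > switch_frame]
  expect_true(all(diff(after) <= 1e-9))          # monotone decrease
  expect_lt(after[min(length(after), 5)], 50)    # well below the old stride
  expect_equal(after[length(after)], 40)         # settles on the new interval
})

test_that("sleep times quoted per event satisfy the refractory replay", {
  for (seed in c(2, 9)) {
    sc <- generate_scenario(scenario_spec("standard_locomotion",
                                          n_cycles = 15, seed = seed))
    assert_detector_invariants(run_detector(sc$signal))
  }
  assert_detector_invariants(run_detector(clean_walk(12)$signal))
})
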