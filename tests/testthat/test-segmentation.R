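test_that("detected events match simulator ground truth within a frame", {
  tw <- make_trial(n_cycles = 6, seed = 21)
  ev <- detect_events(tw$trial, belt_speed = 40)
  expect_alternating(ev)
  truth <- tw$truth$events$events
  det <- ev$events
  for (ty in c("HS", "TO")) {
    tt <- truth$time[truth$type == ty]
    dd <- det$time[det$type == ty]
    expect_equal(length(dd), length(tt))
    err <- vapply(tt, function(t) min(abs(dd - t)), 0)
    expect_lt(max(err), 1.0001 / tw$trial$rate)
  }
})

test_that("standing still on a stopped belt yields no events, with a warning", {
  pos <- array(rep(forward_kinematics(fix_model, neutral_pose()),
                   each = 200), c(200, 8, 3),
               dimnames = list(NULL, MARKERS8, c("x", "y", "z")))
  still <- marker_trajectories(pos, rate = 120)
  expect_warning(ev <- detect_events(still, belt_speed = 0),
                 class = "ratgait_warning_empty_events")
  expect_equal(nrow(ev$events), 0)
})

test_that("detection requires the detector marker and an adequate rate", {
  tw <- make_trial(n_cycles = 2, seed = 22)
  x <- tw$trial
  drop <- marker_trajectories(x$positions[, setdiff(MARKERS8, "TOE"), ],
                              x$rate)
  expect_error(detect_events(drop, 40), class = "ratgait_error_missing_marker")
  slow <- marker_trajectories(x$positions[seq(1, dim(x$positions)[1], by = 4), , , drop = FALSE], rate = 30)
  expect_error(detect_events(slow, 40), class = "ratgait_error_contract")
})

test_that("segment_cycles forms complete HS-TO-HS triplets", {
  ev1 <- gait_events(c(0, 0.2, 0.35, 0.55, 0.70),
                     c("HS", "TO", "HS", "TO", "HS"))
  expect_length(segment_cycles(ev1), 2)
  ev2 <- gait_events(c(0, 0.2), c("HS", "TO"))
  expect_length(segment_cycles(ev2), 0)
  t10 <- seq(0, by = 0.18, length.out = 20)
  ev3 <- gait_events(t10, rep(c("HS", "TO"), 10))
  expect_length(segment_cycles(ev3), 9)
})

test_that("event containers enforce ordering and alternation", {
  expect_error(gait_events(c(0.2, 0.1), c("HS", "TO")),
               class = "ratgait_error_contract")
  expect_error(gait_events(c(0.1, 0.2), c("HS", "HS")),
               class = "ratgait_error_contract")
})

test_that("cycle normalization reproduces simple analytic series", {
  t <- seq(0, 1, by = 1 / 120)
  cyc <- c(0.1, 0.3, 0.8)
  const <- normalize_cycle(t, rep(7.5, length(t)), cyc)
  expect_equal(const$curve, rep(7.5, 101), tolerance = 1e-9)
  expect_equal(const$stance_fraction, (0.3 - 0.1) / 0.7, tolerance = 1e-12)

  ramp <- normalize_cycle(t, 3 + 2 * t, cyc)
  expect_equal(ramp$curve, 3 + 2 * seq(0.1, 0.8, length.out = 101),
               tolerance = 1e-6)

  expect_equal(normalize_cycle(t, sin(t), c(0, 0.2, 0.35))$stance_fraction,
               0.5714, tolerance = 1e-3)
  expect_error(normalize_cycle(t, sin(t), c(0.5, 0.9, 1.2)),
               class = "ratgait_error_coverage")
})

test_that("normalization is invariant to the input sampling rate", {
  p <- gait_waveform_params()
  tr120 <- generate_joint_curves(p, 3, seed = 1)
  p240 <- gait_waveform_params(rate = 240)
  tr240 <- generate_joint_curves(p240, 3, seed = 1)
  cyc <- segment_cycles(tr120$events)[[2]]
  for (a in ANGLES5) {
    c120 <- normalize_cycle(tr120$time, tr120$angles[, a], cyc)$curve
    c240 <- normalize_cycle(tr240$time, tr240$angles[, a], cyc)$curve
    expect_equal(c120, c240, tolerance = 1e-3)
  }
})

test_that("stance and swing fractions sum to one", {
  tw <- make_trial(n_cycles = 5, seed = 23)
  ev <- detect_events(tw$trial, 40)
  st <- spatiotemporal(ev)
  cycles <- segment_cycles(ev)
  stance <- vapply(cycles, function(c) (c[2] - c[1]) / (c[3] - c[1]), 0)
  swing <- vapply(cycles, function(c) (c[3] - c[2]) / (c[3] - c[1]), 0)
  expect_equal(stance + swing, rep(1, length(cycles)), tolerance = 1e-12)
  expect_equal(st$swing_pct, 100 * mean(swing), tolerance = 1e-9)
})

test_that("imposed stride time is recovered across belt speeds", {
  for (belt in c(20, 40, 60)) {
    p <- gait_waveform_params(belt_speed = belt)
    tw <- make_trial(n_cycles = 5, seed = 24, params = p)
    ev <- detect_events(tw$trial, belt)
    st <- spatiotemporal(ev)
    expect_lt(abs(st$stride_time - p$stride_time), 1 / tw$trial$rate)
  }
})

test_that("cut_cycles produces 101-node curves for the five angles", {
  tw <- make_trial(n_cycles = 4, seed = 25, noise = noise_model(0, 0, 0))
  ik <- solve_trial(fix_model, tw$trial)
  ev <- detect_events(tw$trial, 40)
  cycles <- cut_cycles(ik, ev)
  expect_gte(length(cycles), 3)
  for (cy in cycles) {
    expect_identical(dim(cy$curves), c(101L, 5L))
    expect_identical(colnames(cy$curves), ANGLES5)
    expect_true(cy$stance_fraction > 0 && cy$stance_fraction < 1)
  }
})
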