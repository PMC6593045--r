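test_that("waveform generation is deterministic in (params, seed)", {
  p <- gait_waveform_params()
  a <- generate_joint_curves(p, 3, seed = 5, intercycle_sd = 1)
  b <- generate_joint_curves(p, 3, seed = 5, intercycle_sd = 1)
  expect_identical(a$poses, b$poses)
  expect_identical(a$events$events, b$events$events)
  c_ <- generate_joint_curves(p, 3, seed = 6, intercycle_sd = 1)
  expect_false(identical(a$poses, c_$poses))
})

test_that("generated angle waveforms hit the calibrated ranges of motion", {
  p <- gait_waveform_params()
  tr <- generate_joint_curves(p, 5, seed = 2, intercycle_sd = 0)
  for (a in ANGLES5) {
    rom <- max(tr$angles[, a]) - min(tr$angles[, a])
    expect_equal(rom, unname(p$rom[[a]]), tolerance = 0.01)
  }
})

test_that("true events mark the requested number of cycles", {
  p <- gait_waveform_params()
  tr <- generate_joint_curves(p, 5, seed = 3)
  ev <- tr$events$events
  expect_equal(sum(ev$type == "HS"), 6)  # 6 heel strikes bound 5 cycles
  expect_length(segment_cycles(tr$events), 5)
  hs <- ev$time[ev$type == "HS"]
  expect_equal(diff(hs), rep(p$stride_time, 5), tolerance = 1e-9)
  to <- ev$time[ev$type == "TO"]
  expect_equal((to - hs[1:5]) / p$stride_time,
               rep(1 - p$swing_fraction, 5), tolerance = 1e-9)
})

test_that("the stance toe is carried at belt speed on the belt", {
  p <- gait_waveform_params()
  tr <- generate_joint_curves(p, 4, seed = 4, intercycle_sd = 1)
  trial <- simulate_trial(fix_model, tr, noise_model(0, 0, 0))
  toe <- trial$positions[, "TOE", ]
  ev <- tr$events$events
  hs1 <- ev$time[ev$type == "HS"][2]
  to1 <- ev$time[ev$type == "TO"][2]
  mid <- which(trial$time > hs1 + 0.02 & trial$time < to1 - 0.02)
  v <- diff(toe[mid, 1]) * trial$rate
  expect_equal(v, rep(-p$belt_speed * 10, length(v)), tolerance = 1e-6)
  expect_equal(toe[mid, 2], rep(0, length(mid)), tolerance = 1e-9)
  # swing lifts the toe to the configured clearance
  sw <- which(trial$time > to1 & trial$time < hs1 + p$stride_time)
  expect_equal(max(toe[sw, 2]), p$toe_clearance, tolerance = 0.1)
})

test_that("simulated markers are exact forward kinematics when noise is off", {
  p <- gait_waveform_params()
  tr <- generate_joint_curves(p, 2, seed = 5, intercycle_sd = 0)
  trial <- simulate_trial(fix_model, tr, noise_model(0, 0, 0))
  f <- c(1, 50, length(trial$time))
  for (fr in f) {
    expect_equal(trial$positions[fr, , ],
                 forward_kinematics(fix_model, tr$poses[fr, ]),
                 tolerance = 1e-12)
  }
})

test_that("marker noise has the configured scale", {
  p <- gait_waveform_params()
  tr <- generate_joint_curves(p, 10, seed = 6, intercycle_sd = 0)
  clean <- simulate_trial(fix_model, tr, noise_model(0, 0, 0))
  noisy <- simulate_trial(fix_model, tr, noise_model(0.5, 0, 0), seed = 7)
  resid <- noisy$positions - clean$positions
  expect_gt(length(resid), 3000)
  expect_lt(abs(sd(as.vector(resid)) - 0.5), 0.05)
})

test_that("the knee artifact displaces the knee anteriorly, peaking at max flexion", {
  p <- gait_waveform_params()
  tr <- generate_joint_curves(p, 3, seed = 8, intercycle_sd = 0)
  clean <- simulate_trial(fix_model, tr, noise_model(0, 0, 0))
  art <- simulate_trial(fix_model, tr, noise_model(0, 5, 0))
  shift <- art$positions[, "KNEE", 1] - clean$positions[, "KNEE", 1]
  expect_true(all(shift <= 5 + 1e-9))
  expect_true(all(shift >= 0))
  expect_equal(max(shift), 5, tolerance = 1e-9)
  expect_equal(which.max(shift), which.max(tr$poses[, "knee_flexion"]))
  # only the knee moves
  expect_equal(art$positions[, "ANKLE", ], clean$positions[, "ANKLE", ])
})

test_that("cohorts have the requested composition and determinism", {
  co <- generate_cohort(n_control = 2, n_injured = 2, seed = 11, n_cycles = 2)
  expect_length(co$rats, 4)
  expect_equal(sum(vapply(co$rats, `[[`, "", "group") == "injured"), 2)
  co2 <- generate_cohort(n_control = 2, n_injured = 2, seed = 11, n_cycles = 2)
  expect_identical(co$rats[[3]]$trial$positions, co2$rats[[3]]$trial$positions)
})

test_that("a null injury effect leaves injured parameters at baseline levels", {
  eff0 <- injury_effect(delay_pct = setNames(rep(0, 5), ANGLES5),
                        rom_scale = setNames(rep(1, 5), ANGLES5),
                        stride_time_factor = 1, swing_offset_pct = 0)
  co <- generate_cohort(2, 2, effect = eff0, seed = 12, n_cycles = 2)
  strides <- vapply(co$rats, function(r) r$params_true$stride_time, 0)
  # same distribution: all strides drawn from N(0.352, 0.034), no group shift
  expect_true(all(abs(strides - 0.352) < 4 * 0.034))
})

test_that("the default injury shortens stride time on average across seeds", {
  diffs <- vapply(1:20, function(s) {
    co <- generate_cohort(2, 2, seed = s, n_cycles = 1)
    grp <- vapply(co$rats, `[[`, "", "group")
    st <- vapply(co$rats, function(r) r$params_true$stride_time, 0)
    mean(st[grp == "injured"]) - mean(st[grp == "control"])
  }, 0)
  expect_lt(mean(diffs), 0)
})

test_that("written cohorts round-trip through TRC and carry a manifest", {
  co <- generate_cohort(1, 1, seed = 13, n_cycles = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  trc <- read_trc(file.path(dir, paste0(co$rats[[1]]$id, ".trc")))
  expect_equal(trc$positions, co$rats[[1]]$trial$positions, tolerance = 1e-6)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 13)
  expect_length(man$rats, 2)
})
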