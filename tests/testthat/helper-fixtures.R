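# Shared fixtures: all synthetic, built in code at test time.

MARKERS8 <- c("SPINE", "TAIL", "LASI", "RASI", "HIP", "KNEE", "ANKLE", "TOE")
ANGLES5 <- c("hip_flexion", "hip_adduction", "hip_rotation",
             "knee_flexion", "ankle_flexion")

fix_model <- build_default_model()

# A short deterministic walking trial plus its noisy capture.
make_trial <- function(n_cycles = 6, seed = 1, noise = noise_model(),
                       params = gait_waveform_params(), model = fix_model) {
  truth <- generate_joint_curves(params, n_cycles, seed = seed,
                                 intercycle_sd = noise$intercycle_sd,
                                 model = model)
  list(truth = truth,
       trial = simulate_trial(model, truth, noise, seed = seed + 1000L))
}

# Random (gait-plausible) pose within joint limits, sagittal ankle.
random_pose <- function() {
  q <- neutral_pose()
  q[1:3] <- stats::runif(3, -20, 20)
  q[4:6] <- stats::runif(3, -30, 30)
  q["hip_flexion"] <- stats::runif(1, -80, 80)
  q["hip_adduction"] <- stats::runif(1, -60, 60)
  q["hip_rotation"] <- stats::runif(1, -60, 60)
  q["knee_flexion"] <- stats::runif(1, 5, 150)
  q["ankle_flexion"] <- stats::runif(1, -80, 80)
  q
}

# Random trajectory set for I/O round-trips.
random_trajectories <- function(n_frames = 7, rate = 120, missing = 0) {
  pos <- array(stats::rnorm(n_frames * 8 * 3, sd = 50), c(n_frames, 8, 3),
               dimnames = list(NULL, MARKERS8, c("x", "y", "z")))
  if (missing > 0) {
    for (k in seq_len(missing)) {
      f <- sample(n_frames, 1); m <- sample(8, 1)
      pos[f, m, ] <- NA
    }
  }
  marker_trajectories(pos, rate = rate)
}

expect_alternating <- function(events) {
  tp <- events$events$type
  if (length(tp) > 1)
    expect_true(all(tp[-1] != tp[-length(tp)]))
  expect_true(all(diff(events$events$time) > 0))
}
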