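# Synthetic treadmill gait: ground-truth joint-angle waveforms, a contact
# schedule with prescribed stance/swing timing, forward-kinematic marker
# trajectories with measurement noise and a knee skin artifact, and full
# control/injured cohorts with known generating parameters.

#' Baseline gait waveform parameters
#'
#' Defines the periodic joint-angle waveforms of one animal as three Fourier
#' harmonics per angle (relative harmonic amplitudes and phases give the
#' shape; the shape is rescaled so its peak-to-peak range equals the target
#' ROM, then offset to the target mean). Defaults are calibrated to healthy
#' rat treadmill walking at 40 cm/s: stride time 0.352 s, swing 45.71% of
#' the cycle, and flexion ROMs of 39.24 (hip), 52.88 (knee) and 53.88 deg
#' (ankle); frontal/transverse hip ROMs are not tabulated for rats walking
#' on a treadmill, so modest defaults of 12 and 15 deg are used. Curve
#' shapes are qualitative (single-peak hip, double-bump knee/ankle);
#' published rat studies tabulate only the scalar summaries the defaults
#' are calibrated to.
#'
#' @param stride_time Stride duration, s (default 0.352).
#' @param swing_fraction Swing fraction of the cycle (default 0.4571).
#' @param belt_speed Treadmill belt speed, cm/s (default 40).
#' @param rate Sampling rate, Hz (default 120).
#' @param rom Named per-angle peak-to-peak range of motion, deg.
#' @param mean Named per-angle mean value, deg.
#' @param harmonics List per angle of `amp` (3 relative amplitudes) and
#'   `phase` (3 phases, radians).
#' @param toe_clearance Peak swing toe lift, mm (default 10).
#' @return Object of class `gait_waveform_params`.
#' @export
gait_waveform_params <- function(stride_time = 0.352,
                                 swing_fraction = 0.4571,
                                 belt_speed = 40, rate = 120,
                                 rom = c(hip_flexion = 39.24,
                                         hip_adduction = 12,
                                         hip_rotation = 15,
                                         knee_flexion = 52.88,
                                         ankle_flexion = 53.88),
                                 mean = c(hip_flexion = 40,
                                          hip_adduction = 5,
                                          hip_rotation = 0,
                                          knee_flexion = 66,
                                          ankle_flexion = 10),
                                 harmonics = default_harmonics(),
                                 toe_clearance = 10) {
  if (stride_time <= 0 || rate <= 0)
    rg_stop("stride_time and rate must be > 0", "ratgait_error_contract")
  if (swing_fraction <= 0 || swing_fraction >= 1)
    rg_stop("swing_fraction must lie in (0, 1)", "ratgait_error_contract")
  if (!all(RG_ANGLES %in% names(rom)) || !all(RG_ANGLES %in% names(mean)))
    rg_stop("rom and mean must name all five angles", "ratgait_error_contract")
  structure(list(stride_time = stride_time, swing_fraction = swing_fraction,
                 belt_speed = belt_speed, rate = rate,
                 rom = rom[RG_ANGLES], mean = mean[RG_ANGLES],
                 harmonics = harmonics, toe_clearance = toe_clearance),
            class = "gait_waveform_params")
}

#' @rdname gait_waveform_params
#' @export
default_harmonics <- function() {
  list(
    hip_flexion = list(amp = c(1, 0.25, 0.08), phase = c(0.4, 2.0, 1.0)),
    hip_adduction = list(amp = c(1, 0.30, 0.10), phase = c(1.2, 0.5, 2.2)),
    hip_rotation = list(amp = c(1, 0.35, 0.10), phase = c(2.1, 1.1, 0.3)),
    knee_flexion = list(amp = c(1, 0.55, 0.12), phase = c(1.0, 2.6, 0.7)),
    ankle_flexion = list(amp = c(1, 0.45, 0.15), phase = c(1.7, 0.2, 1.5))
  )
}

# Periodic unit-shape waveform on cycle fraction s in [0, 1); rescaled by
# the caller to the target ROM.
waveform_shape <- function(h, s) {
  w <- 0
  for (k in 1:3) w <- w + h$amp[k] * cos(2 * pi * k * s + h$phase[k])
  w
}

# Peak-to-peak of the shape on a fine grid (analytic extrema are not worth
# the trouble for 3 harmonics).
shape_ptp <- function(h) {
  s <- seq(0, 1, length.out = 2001)[-2001]
  w <- waveform_shape(h, s)
  max(w) - min(w)
}

#' Injury effect applied to baseline waveforms
#'
#' A volumetric-muscle-loss-like transformation of the baseline gait: each
#' angle waveform is circularly delayed by a percentage of the cycle and its
#' ROM scaled; stride time shrinks and the swing fraction drops. Default
#' delays (3, 2, 3, 5, 4% for hip flexion, hip adduction, hip rotation, knee
#' flexion, ankle flexion), the stride-time factor (0.314/0.352) and the
#' swing offset (41.82 - 45.71 points) reproduce the week-8 deficits of a
#' 20%-mass tibialis anterior VML injury; ROM scale defaults are qualitative
#' reductions.
#'
#' @param delay_pct Named per-angle circular delay, % of cycle, in
#'   `[0, 50]`.
#' @param rom_scale Named per-angle ROM scale factor (> 0).
#' @param stride_time_factor Multiplier on stride time.
#' @param swing_offset_pct Additive change of the swing percentage, points.
#' @return Object of class `injury_effect`.
#' @export
injury_effect <- function(delay_pct = c(hip_flexion = 3, hip_adduction = 2,
                                        hip_rotation = 3, knee_flexion = 5,
                                        ankle_flexion = 4),
                          rom_scale = c(hip_flexion = 0.9, hip_adduction = 0.9,
                                        hip_rotation = 0.9, knee_flexion = 0.85,
                                        ankle_flexion = 0.85),
                          stride_time_factor = 0.314 / 0.352,
                          swing_offset_pct = 41.82 - 45.71) {
  if (any(delay_pct < 0 | delay_pct > 50))
    rg_stop("delays must lie in [0, 50] percent", "ratgait_error_contract")
  if (any(rom_scale <= 0))
    rg_stop("ROM scale factors must be > 0", "ratgait_error_contract")
  structure(list(delay_pct = delay_pct[RG_ANGLES],
                 rom_scale = rom_scale[RG_ANGLES],
                 stride_time_factor = stride_time_factor,
                 swing_offset_pct = swing_offset_pct),
            class = "injury_effect")
}

#' Measurement noise model for simulated motion capture
#'
#' @param marker_sd Isotropic marker noise sd, mm (default 0.5).
#' @param knee_artifact Peak anterior knee skin-artifact displacement, mm,
#'   applied in proportion to instantaneous knee flexion (default 3).
#' @param intercycle_sd Between-cycle waveform variability sd, deg
#'   (default 1).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(marker_sd = 0.5, knee_artifact = 3,
                        intercycle_sd = 1) {
  if (marker_sd < 0 || knee_artifact < 0 || intercycle_sd < 0)
    rg_stop("noise parameters must be nonnegative", "ratgait_error_contract")
  structure(list(marker_sd = marker_sd, knee_artifact = knee_artifact,
                 intercycle_sd = intercycle_sd),
            class = "noise_model")
}

# Swing toe-path profile p(u), u in [0,1]: fraction of the backward stance
# travel recovered by the swing. C1-continuous with the belt at both ends
# (p'(0) = p'(1) = -T_swing/T_stance) and steep edge curvature (|p''| = K)
# so the toe leaves/re-enters the belt-speed band within ~1 ms, keeping
# detector bias well under a frame.
swing_profile <- function(u, c0, K = 60) {
  # quintic with p(0)=0, p'(0)=-c0, p''(0)=K, p(1)=1, p'(1)=-c0, p''(1)=-K
  a1 <- -c0
  a2 <- K / 2
  A <- rbind(c(1, 1, 1), c(3, 4, 5), c(6, 12, 20))
  rhs <- c(1 - a1 - a2, -c0 - a1 - 2 * a2, -K - 2 * a2)
  coef <- solve(A, rhs)
  a1 * u + a2 * u^2 + coef[1] * u^3 + coef[2] * u^4 + coef[3] * u^5
}

# Prescribed lab-frame toe path over one cycle: stance (s < stance_frac)
# carries the toe backward at belt speed on the belt (y = 0); swing returns
# it with a smooth lift. x is centered so the path is periodic.
toe_path <- function(s, stance_frac, stride_len_mm, clearance) {
  x <- numeric(length(s))
  y <- numeric(length(s))
  st <- s < stance_frac
  x[st] <- stride_len_mm * (0.5 - s[st] / stance_frac)
  u <- (s[!st] - stance_frac) / (1 - stance_frac)
  c0 <- (1 - stance_frac) / stance_frac
  x[!st] <- -stride_len_mm / 2 + stride_len_mm * swing_profile(u, c0)
  y[!st] <- clearance * sin(pi * u)^2
  list(x = x, y = y)
}

#' Generate ground-truth joint curves and events for one trial
#'
#' Builds the 13-coordinate pose series of one treadmill walking trial:
#' periodic Fourier waveforms for the five reported joint angles (with
#' optional smooth per-cycle perturbations), non-sagittal ankle coordinates
#' held at zero, and pelvis translations chosen so that the lab-frame toe
#' trajectory follows the prescribed contact schedule exactly - carried
#' backward at belt speed and flat on the belt during stance, lifted and
#' swung forward during swing. The pelvis therefore bobs periodically with
#' zero mean velocity, as on a treadmill. True heel-strike/toe-off times
#' follow directly from the schedule. The trial is padded by `pad` seconds
#' of continued walking at each end so that every true event is interior.
#'
#' @param params A [gait_waveform_params()].
#' @param n_cycles Number of complete gait cycles (>= 1).
#' @param seed Seed for the per-cycle perturbations.
#' @param intercycle_sd Between-cycle waveform variability, deg (default 0:
#'   deterministic waveforms).
#' @param model A `rat_model` used to place the toe (default
#'   [build_default_model()]); pass the scaled per-animal model when
#'   simulating a cohort.
#' @param pad Padding of continued walking at each trial end, s.
#' @return List of class `gait_truth`: `time`, `poses` (frames x 13),
#'   `angles` (frames x 5), `events` (a [gait_events()] with the true
#'   HS/TO times), `params`, `seed`.
#' @export
generate_joint_curves <- function(params, n_cycles, seed = 1L,
                                  intercycle_sd = 0,
                                  model = build_default_model(),
                                  pad = 0.15) {
  if (n_cycles < 1)
    rg_stop("n_cycles must be >= 1", "ratgait_error_contract")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  stride <- params$stride_time
  rate <- params$rate
  stance_frac <- 1 - params$swing_fraction
  total <- n_cycles * stride + 2 * pad
  time <- seq(0, total, by = 1 / rate)
  tt <- time - pad                      # 0 at the first true heel strike
  cyc <- floor(tt / stride)
  s <- tt / stride - cyc                # cycle fraction in [0, 1)
  cyc_range <- min(cyc):max(cyc)
  pert <- list()
  for (a in RG_ANGLES)
    pert[[a]] <- list(
      amp = stats::rnorm(length(cyc_range), 0, intercycle_sd),
      phase = stats::runif(length(cyc_range), 0, 2 * pi)
    )
  angles <- matrix(0, length(time), 5, dimnames = list(NULL, RG_ANGLES))
  for (a in RG_ANGLES) {
    h <- params$harmonics[[a]]
    shape <- waveform_shape(h, s)
    base <- params$mean[[a]] + shape * (params$rom[[a]] / shape_ptp(h))
    ci <- match(cyc, cyc_range)
    # perturbation windowed by sin^2(pi s): zero value and slope at the
    # cycle boundaries, so trials stay C1 across cycles
    p <- pert[[a]]$amp[ci] * sin(pi * s)^2 *
      cos(2 * pi * s + pert[[a]]$phase[ci])
    angles[, a] <- base + p
  }
  belt_mm <- params$belt_speed * 10
  stride_len <- belt_mm * stance_frac * stride
  tp <- toe_path(s, stance_frac, stride_len, params$toe_clearance)
  # pelvis translation absorbs the difference between the prescribed toe
  # path and the toe position implied by the joint angles
  poses <- matrix(0, length(time), 13, dimnames = list(NULL, RG_COORDS))
  poses[, RG_ANGLES] <- angles
  toe_limb <- t(vapply(seq_along(time), function(f) {
    q <- poses[f, ]
    forward_kinematics(model, q)["TOE", 1:2]
  }, numeric(2)))
  poses[, "pelvis_tx"] <- tp$x - toe_limb[, 1]
  poses[, "pelvis_ty"] <- tp$y - toe_limb[, 2]
  hs <- pad + (0:n_cycles) * stride
  to <- pad + (0:(n_cycles - 1)) * stride + stance_frac * stride
  ev <- rbind(data.frame(time = hs, type = "HS"),
              data.frame(time = to, type = "TO"))
  ev <- ev[order(ev$time), ]
  structure(list(time = time, poses = poses, angles = angles,
                 events = gait_events(ev$time, ev$type,
                                      belt_speed = params$belt_speed),
                 params = params, seed = seed),
            class = "gait_truth")
}

#' Simulate a motion-capture trial from a pose series
#'
#' Forward kinematics of the model at every frame, plus isotropic Gaussian
#' marker noise and an anterior knee skin artifact proportional to
#' instantaneous knee flexion (`amplitude * knee_flexion / max(knee_flexion)`,
#' reaching the full amplitude at peak flexion) - the dominant soft-tissue
#' error in rodent motion capture.
#'
#' @param model A (scaled) `rat_model`.
#' @param truth A `gait_truth` from [generate_joint_curves()], or any list
#'   with `time` and `poses`.
#' @param noise A [noise_model()].
#' @param seed Seed for the marker noise.
#' @return A [marker_trajectories()] object at the pose-series rate.
#' @export
simulate_trial <- function(model, truth, noise = noise_model(), seed = 1L) {
  poses <- truth$poses
  if (is.null(poses) || nrow(poses) == 0)
    rg_stop("empty pose series", "ratgait_error_empty")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n <- nrow(poses)
  pos <- array(NA_real_, c(n, 8, 3),
               dimnames = list(NULL, RG_MARKERS, c("x", "y", "z")))
  for (f in seq_len(n)) pos[f, , ] <- forward_kinematics(model, poses[f, ])
  kf <- poses[, "knee_flexion"]
  if (noise$knee_artifact > 0 && max(kf) > 0)
    pos[, "KNEE", 1] <- pos[, "KNEE", 1] + noise$knee_artifact * kf / max(kf)
  if (noise$marker_sd > 0)
    pos <- pos + array(stats::rnorm(length(pos), 0, noise$marker_sd), dim(pos))
  rate <- if (!is.null(truth$params)) truth$params$rate else
    1 / stats::median(diff(truth$time))
  marker_trajectories(pos, rate = rate, time = truth$time)
}

apply_injury <- function(params, effect) {
  h <- params$harmonics
  for (a in RG_ANGLES) {
    # circular delay by d% of the cycle: w(s - d) shifts the phase of
    # harmonic k by -2 pi k d under the cos convention
    d <- effect$delay_pct[[a]] / 100
    h[[a]]$phase <- h[[a]]$phase - 2 * pi * (1:3) * d
  }
  gait_waveform_params(
    stride_time = params$stride_time * effect$stride_time_factor,
    swing_fraction = min(0.95, max(0.05,
      params$swing_fraction + effect$swing_offset_pct / 100)),
    belt_speed = params$belt_speed, rate = params$rate,
    rom = params$rom * effect$rom_scale,
    mean = params$mean, harmonics = h,
    toe_clearance = params$toe_clearance)
}

#' Generate a control/injured synthetic cohort
#'
#' Draws per-animal gait parameters around the baseline (normal perturbation
#' of stride time, swing percentage, per-angle ROMs and segment lengths with
#' the documented between-animal spreads), applies the injury transformation
#' to the injured animals, and simulates one marker-capture trial per animal
#' together with its ground truth. Every part of the cohort is a pure
#' function of (parameters, seed).
#'
#' @param n_control,n_injured Group sizes (defaults 4 and 4).
#' @param baseline A [gait_waveform_params()].
#' @param effect An [injury_effect()].
#' @param noise A [noise_model()].
#' @param seed Master seed.
#' @param n_cycles Gait cycles per trial (default 60, about 21 s of
#'   continuous walking at the baseline stride time - a small fraction of a
#'   typical 15-minute treadmill session, and enough strides that the
#'   Monte-Carlo error of the cycle-level estimators, notably the
#'   1%-of-cycle phase-delay resolution, is below their reporting
#'   resolution).
#' @param variability List of between-animal sds: `stride_sd` (s, default
#'   0.034), `swing_sd_pct` (points, 3.23), `rom_sd` (deg per angle,
#'   6.99/2/3/10.21/10.07), `segment_sd` (relative, 0.05).
#' @return Object of class `synthetic_cohort`: list `rats`, each with `id`,
#'   `group`, `model` (true scaled model), `static` (noiseless static
#'   marker frame), `trial` (noisy [marker_trajectories()]), `truth`
#'   (`gait_truth`), `params_true`; plus `seed` and the generating
#'   parameter objects.
#' @export
generate_cohort <- function(n_control = 4, n_injured = 4,
                            baseline = gait_waveform_params(),
                            effect = injury_effect(),
                            noise = noise_model(), seed = 17L,
                            n_cycles = 60,
                            variability = list(stride_sd = 0.034,
                                               swing_sd_pct = 3.23,
                                               rom_sd = c(hip_flexion = 6.99,
                                                          hip_adduction = 2,
                                                          hip_rotation = 3,
                                                          knee_flexion = 10.21,
                                                          ankle_flexion = 10.07),
                                               segment_sd = 0.05)) {
  if (n_control < 1 || n_injured < 1)
    rg_stop("group sizes must be >= 1", "ratgait_error_contract")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  generic <- build_default_model()
  groups <- c(rep("control", n_control), rep("injured", n_injured))
  rats <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    id <- sprintf("%s%02d", ifelse(groups[i] == "control", "C", "I"),
                  i)
    rat_seed <- sample.int(2^30, 1)
    set.seed(rat_seed)
    rom_i <- baseline$rom
    for (a in RG_ANGLES)
      rom_i[[a]] <- max(5, stats::rnorm(1, baseline$rom[[a]],
                                        variability$rom_sd[[a]]))
    p_i <- gait_waveform_params(
      stride_time = max(0.15, stats::rnorm(1, baseline$stride_time,
                                           variability$stride_sd)),
      swing_fraction = min(0.9, max(0.1,
        stats::rnorm(1, baseline$swing_fraction,
                     variability$swing_sd_pct / 100))),
      belt_speed = baseline$belt_speed, rate = baseline$rate,
      rom = rom_i, mean = baseline$mean, harmonics = baseline$harmonics,
      toe_clearance = baseline$toe_clearance)
    if (groups[i] == "injured") p_i <- apply_injury(p_i, effect)
    factors <- pmax(0.5, stats::rnorm(4, 1, variability$segment_sd))
    model_i <- scale_synthetic(generic, factors)
    static_i <- forward_kinematics(model_i, neutral_pose())
    truth_i <- generate_joint_curves(p_i, n_cycles, seed = rat_seed + 1L,
                                     intercycle_sd = noise$intercycle_sd,
                                     model = model_i)
    trial_i <- simulate_trial(model_i, truth_i, noise, seed = rat_seed + 2L)
    rats[[i]] <- list(id = id, group = groups[i], model = model_i,
                      static = static_i, trial = trial_i, truth = truth_i,
                      params_true = p_i)
  }
  structure(list(rats = rats, seed = seed, baseline = baseline,
                 effect = effect, noise = noise, n_cycles = n_cycles,
                 variability = variability),
            class = "synthetic_cohort")
}

# Scale the generic model by given per-segment factors (pelvis, femur,
# tibia, foot) without reference to a measured frame.
scale_synthetic <- function(model, factors) {
  names(factors) <- names(model$segments)
  m <- model
  for (seg in names(factors)) {
    k <- factors[[seg]]
    m$segments[[seg]]$generic_length <- m$segments[[seg]]$generic_length * k
    m$segments[[seg]]$marker_offsets <-
      lapply(m$segments[[seg]]$marker_offsets, function(o) o * k)
    child <- names(model$segments)[vapply(model$segments,
                                          function(s) identical(s$parent, seg), NA)]
    for (ch in child)
      m$segments[[ch]]$origin_in_parent <- m$segments[[ch]]$origin_in_parent * k
  }
  m
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  grp <- vapply(x$rats, `[[`, "", "group")
  cat(sprintf("Synthetic cohort: %d control + %d injured rats, %d cycles/trial, seed %d\n",
              sum(grp == "control"), sum(grp == "injured"), x$n_cycles,
              x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one TRC trial, a static TRC frame, a ground-truth angle CSV and a
#' ground-truth event CSV per rat, plus a JSON manifest recording the
#' generating parameters and seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (r in cohort$rats) {
    base <- file.path(dir, r$id)
    write_trc(r$trial, paste0(base, ".trc"))
    static <- marker_trajectories(
      array(r$static, c(1, 8, 3),
            dimnames = list(NULL, rownames(r$static), c("x", "y", "z"))),
      rate = r$trial$rate)
    write_trc(static, paste0(base, "_static.trc"))
    utils::write.csv(data.frame(time = r$truth$time, r$truth$angles,
                                check.names = FALSE),
                     paste0(base, "_angles.csv"), row.names = FALSE)
    utils::write.csv(r$truth$events$events, paste0(base, "_events.csv"),
                     row.names = FALSE)
    entries[[r$id]] <- list(group = r$group,
                            stride_time = r$params_true$stride_time,
                            swing_fraction = r$params_true$swing_fraction,
                            rom = as.list(r$params_true$rom))
  }
  manifest <- list(seed = cohort$seed, n_cycles = cohort$n_cycles,
                   belt_speed = cohort$baseline$belt_speed,
                   rate = cohort$baseline$rate,
                   noise = unclass(cohort$noise), rats = entries)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
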