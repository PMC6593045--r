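#' Default IK marker weights
#'
#' All markers weight 1 except KNEE, down-weighted to 0.1: knee skin slides
#' over the joint during locomotion, so the knee marker carries the largest
#' soft-tissue artifact and the sagittal knee angle is driven primarily by
#' the hip and ankle markers through the rigid two-link chain.
#'
#' @param knee Weight for the KNEE marker (default 0.1).
#' @return Named numeric vector of per-marker weights.
#' @export
default_ik_weights <- function(knee = 0.1) {
  w <- rep(1, 8)
  names(w) <- RG_MARKERS
  w["KNEE"] <- knee
  w
}

check_ik_weights <- function(weights) {
  if (any(weights < 0))
    rg_stop("IK weights must be nonnegative", "ratgait_error_contract")
  if (sum(weights > 0) < 3)
    rg_stop("at least 3 markers must have positive weight",
            "ratgait_error_underdetermined")
  invisible(weights)
}

#' Solve the pose of a single frame
#'
#' Weighted least-squares inverse kinematics: finds the 13 generalized
#' coordinates minimizing `sum_m w_m ||p_m_obs - FK_m(q)||^2` by damped
#' Gauss-Newton (Levenberg-style multiplicative damping, finite-difference
#' Jacobian). Joint limits are enforced by projection after each step, and
#' only objective-decreasing steps are accepted, so the weighted objective is
#' monotonically non-increasing across iterations. The solver is fully
#' deterministic.
#'
#' @param model A (scaled) `rat_model`.
#' @param observed Named 3-vectors (list or matrix with marker rownames) of
#'   observed lab positions, mm. Markers absent or non-finite are dropped.
#' @param weights Per-marker weights, see [default_ik_weights()].
#' @param init Initial pose (13 coordinates); defaults to [neutral_pose()].
#' @param max_iter Iteration cap (default 100).
#' @param grad_tol Convergence threshold on the infinity norm of the
#'   objective gradient (default 1e-8).
#' @param restart_tol Weighted RMS residual (mm) above which the solve is
#'   deemed stuck and retried, first from geometric initializations (pelvis
#'   by rigid point-cloud fit, limb by the two-link closed form) and then
#'   from a fixed grid of flexion initializations (default 1e-4 mm; all
#'   retries are deterministic). Set to `Inf` to disable restarts.
#' @return List with `pose` (13 coordinates), `residual` (weighted RMS marker
#'   distance, mm), `iterations`, `converged`.
#' @export
solve_frame <- function(model, observed, weights = default_ik_weights(),
                        init = neutral_pose(), max_iter = 100L,
                        grad_tol = 1e-8, restart_tol = 1e-4) {
  sol <- solve_frame_once(model, observed, weights, init, max_iter, grad_tol)
  if (is.finite(restart_tol) && (!sol$converged || sol$residual > restart_tol)) {
    # first retry from geometric initializations (pelvis by point-cloud fit,
    # limb by two-link closed form, one candidate per gauge azimuth): all of
    # them are evaluated and the best fit kept, because near knee extension
    # several distinct poses can fit the markers to similar small residuals
    # and only the best one pins the weakly-determined coordinates
    for (alt in analytic_inits(model, as_marker_frame(observed))) {
      cand <- solve_frame_once(model, observed, weights, alt, max_iter,
                               grad_tol)
      if (cand$residual < sol$residual) sol <- cand
      if (sol$residual <= 1e-9) break
    }
    if (sol$residual > restart_tol) {
      # fall back to a fixed flexion grid
      grid <- expand.grid(hip_flexion = c(-45, 60), knee_flexion = c(40, 120),
                          ankle_flexion = c(-30, 30))
      for (g in seq_len(nrow(grid))) {
        alt <- init
        alt[c("hip_flexion", "knee_flexion", "ankle_flexion")] <-
          unlist(grid[g, ])
        cand <- solve_frame_once(model, observed, weights, alt, max_iter,
                                 grad_tol)
        if (cand$residual < sol$residual) sol <- cand
        if (sol$residual <= restart_tol) break
      }
    }
  }
  sol
}

# Geometric initial guesses: pelvis pose from a rigid (Kabsch) fit of the
# pelvis-attached markers, knee flexion from the two-link closed form on the
# hip-ankle distance, hip flexion/adduction from aiming the femur along the
# hip-ankle chord rotated by the interior hip angle (both knee-forward and
# knee-backward branches are returned; the solver keeps the better one).
analytic_inits <- function(model, obs) {
  pelvis_markers <- intersect(names(model$segments$pelvis$marker_offsets),
                              rownames(obs))
  pelvis_markers <- pelvis_markers[
    apply(obs[pelvis_markers, , drop = FALSE], 1,
          function(r) all(is.finite(r)))]
  if (length(pelvis_markers) < 3) return(list())
  O <- vapply(pelvis_markers,
              function(m) model$segments$pelvis$marker_offsets[[m]],
              numeric(3))                       # 3 x k local
  P <- t(obs[pelvis_markers, , drop = FALSE])   # 3 x k lab
  oc <- rowMeans(O); pc <- rowMeans(P)
  H <- (O - oc) %*% t(P - pc)
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  t_p <- pc - R %*% oc
  q <- neutral_pose()
  q[1:3] <- t_p
  q["pelvis_rx"] <- asin(min(1, max(-1, R[3, 2]))) / DEG
  q["pelvis_rz"] <- atan2(-R[1, 2], R[2, 2]) / DEG
  q["pelvis_ry"] <- atan2(-R[3, 1], R[3, 3]) / DEG
  if (!"ANKLE" %in% rownames(obs) || any(!is.finite(obs["ANKLE", ])))
    return(list(q))
  f_len <- model$segments$femur$generic_length
  t_len <- model$segments$tibia$generic_length
  hipW <- as.numeric(t_p + R %*% model$segments$femur$origin_in_parent)
  a_lab <- as.numeric(obs["ANKLE", ]) - hipW
  d <- sqrt(sum(a_lab^2))
  d <- min(max(d, abs(f_len - t_len) + 1e-9), f_len + t_len - 1e-9)
  kappa <- min(max(knee_angle_two_link(f_len, t_len, d), 0.5), 159.5)
  q["knee_flexion"] <- kappa
  a_p <- as.numeric(t(R) %*% a_lab)
  u <- a_p / sqrt(sum(a_p^2))
  # femur lies on a cone of half-angle beta around the hip-ankle chord
  beta <- acos(min(1, max(-1, (f_len^2 + d^2 - t_len^2) / (2 * f_len * d))))
  c_ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- c(u[2] * c_ref[3] - u[3] * c_ref[2],
         u[3] * c_ref[1] - u[1] * c_ref[3],
         u[1] * c_ref[2] - u[2] * c_ref[1])
  w <- w / sqrt(sum(w^2))
  wxu <- c(w[2] * u[3] - w[3] * u[2],
           w[3] * u[1] - w[1] * u[3],
           w[1] * u[2] - w[2] * u[1])
  lim <- pose_limits(model)
  out <- list()
  # four azimuths around the gauge circle of femur directions on the cone;
  # the downstream foot fit selects among them
  for (phi in c(0, pi, pi / 2, 3 * pi / 2)) {
    axis2 <- cos(phi) * wxu + sin(phi) * w
    fd <- u * cos(beta) + axis2 * sin(beta)  # unit femur direction
    qi <- q
    a0 <- asin(min(1, max(-1, -fd[3]))) / DEG
    f0 <- atan2(fd[1], -fd[2]) / DEG
    qi["hip_adduction"] <- a0
    qi["hip_flexion"] <- f0
    # hip axial rotation orienting the knee-flexion plane toward the ankle
    kneeW <- hipW + f_len * as.numeric(R %*% fd)
    v_pre <- as.numeric(t(rot_zxy(f0, a0, 0)) %*% t(R) %*%
                          (as.numeric(obs["ANKLE", ]) - kneeW)) / t_len
    r0 <- atan2(v_pre[3], -v_pre[1]) / DEG
    qi["hip_rotation"] <- r0
    if ("TOE" %in% rownames(obs) && all(is.finite(obs["TOE", ]))) {
      # ankle flexion/rotation aiming the foot at the observed toe
      R_tib <- R %*% rot_zxy(f0, a0, r0) %*% rot_z(-kappa)
      v_ft <- as.numeric(t(R_tib) %*%
                           (as.numeric(obs["TOE", ]) -
                              as.numeric(obs["ANKLE", ])))
      v_ft <- v_ft / sqrt(sum(v_ft^2))
      qi["ankle_rotation"] <- asin(min(1, max(-1, -v_ft[3]))) / DEG
      qi["ankle_flexion"] <- atan2(v_ft[2], v_ft[1]) / DEG
    }
    out[[length(out) + 1L]] <- pmin(pmax(qi, lim$lower), lim$upper)
  }
  out
}

solve_frame_once <- function(model, observed, weights, init, max_iter,
                             grad_tol) {
  check_ik_weights(weights)
  obs <- as_marker_frame(observed)
  use <- intersect(names(weights)[weights > 0], rownames(obs))
  use <- use[apply(obs[use, , drop = FALSE], 1, function(r) all(is.finite(r)))]
  if (length(use) < 3)
    rg_stop("fewer than 3 weighted markers observed: pose underdetermined",
            "ratgait_error_underdetermined")
  solve_frame_core(compile_model(model), pose_limits(model),
                   t(obs[use, , drop = FALSE]), match(use, RG_MARKERS),
                   weights[use], init, max_iter, grad_tol)
}

# Damped Gauss-Newton core. target: 3 x k observed positions; idx: marker
# column indices into the compiled FK output; w: weights of those markers.
# A very weak prior pulls the 7 joint-angle coordinates toward neutral
# (weight 1e-6 mm^2/deg^2): it pins coordinates the marker set cannot
# observe (ankle inversion with the toe marker on the flexion axis) to zero
# instead of letting them wander in the objective's null space, while
# displacing observable coordinates by well under 1e-4 deg.
solve_frame_core <- function(cm, lim, target, idx, w, init, max_iter,
                             grad_tol) {
  q <- pmin(pmax(init, lim$lower), lim$upper)
  sw <- rep(sqrt(w), each = 3)
  prior_sw <- 1e-4
  resid_vec <- function(q)
    c((fk_compiled(cm, q)[, idx, drop = FALSE] - target) * sw,
      prior_sw * q[7:13])

  r <- as.vector(resid_vec(q))
  f <- sum(r * r)
  lambda <- 1e-4
  h <- 1e-6
  it <- 0L
  converged <- FALSE
  polished <- FALSE
  nq <- 13L
  J <- matrix(0, length(r), nq)
  while (it < max_iter) {
    it <- it + 1L
    for (j in seq_len(nq)) {
      qj <- q
      qj[j] <- qj[j] + h
      if (polished) {
        qm <- q
        qm[j] <- qm[j] - h
        J[, j] <- (resid_vec(qj) - resid_vec(qm)) / (2 * h)
      } else {
        J[, j] <- (resid_vec(qj) - r) / h
      }
    }
    g <- crossprod(J, r)
    if (max(abs(g)) < grad_tol) {
      converged <- TRUE
      break
    }
    A <- crossprod(J)
    dA <- diag(A)
    improved <- FALSE
    for (k in 1:30) {
      M <- A
      diag(M) <- dA * (1 + lambda)
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        q_new <- pmin(pmax(q + as.vector(delta), lim$lower), lim$upper)
        r_new <- as.vector(resid_vec(q_new))
        f_new <- sum(r_new * r_new)
        if (f_new < f) {
          step <- max(abs(q_new - q))
          q <- q_new; r <- r_new; f <- f_new
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (step < 1e-9) converged <- TRUE  # parameter-space convergence
          break
        }
      }
      lambda <- lambda * 10
    }
    if (converged) break
    if (!improved) {
      if (!polished) {
        # one polishing pass: refreshed damping and a central-difference
        # Jacobian squeeze out the last ~1e-4 deg near the minimum
        polished <- TRUE
        lambda <- 1e-4
        next
      }
      # no decreasing step found: at a (possibly constrained) stationary point
      converged <- max(abs(g)) < sqrt(grad_tol)
      break
    }
  }
  # final relaxation: coordinates whose curvature comes from the prior alone
  # are marker-unobservable at this pose; snap them to neutral when doing so
  # leaves the marker fit untouched
  nm <- length(r) - 7L
  if (it > 0L) {
    null_idx <- which(diag(crossprod(J)) <= 4 * prior_sw^2)
    null_idx <- null_idx[null_idx >= 7L]
    if (length(null_idx) && any(q[null_idx] != 0)) {
      q_try <- q
      q_try[null_idx] <- 0
      r_try <- as.vector(resid_vec(q_try))
      if (sum(r_try[seq_len(nm)]^2) <= sum(r[seq_len(nm)]^2) + 1e-12) {
        q <- q_try
        r <- r_try
      }
    }
  }
  names(q) <- RG_COORDS
  # report the weighted RMS over markers only, without the prior rows
  list(pose = q, residual = sqrt(sum(r[seq_len(nm)]^2) / sum(w)),
       iterations = it, converged = converged)
}

#' Solve inverse kinematics for a whole trial
#'
#' Runs [solve_frame()] over every frame of a trajectory set. Frame 1 starts
#' from the neutral pose; each later frame is warm-started from the previous
#' solution. Frames with fewer than 3 usable weighted markers are flagged and
#' their poses filled afterwards by per-coordinate linear interpolation of
#' neighboring solved frames, for gaps up to `max_gap` frames; longer gaps
#' are left as `NA` and remain flagged.
#'
#' @param model A (scaled) `rat_model`.
#' @param trajectories A [marker_trajectories()] object containing the
#'   8-marker set.
#' @param weights Per-marker weights, see [default_ik_weights()].
#' @param max_gap Longest run of underdetermined frames to interpolate
#'   (default 5, about 42 ms at 120 Hz).
#' @param max_iter,grad_tol Solver controls, see [solve_frame()].
#' @return Object of class `ik_result`: `time`, `rate`, `poses`
#'   (frames x 13), `residual`, `iterations`, `converged`, `interpolated`.
#' @export
solve_trial <- function(model, trajectories, weights = default_ik_weights(),
                        max_gap = 5L, max_iter = 100L, grad_tol = 1e-8) {
  x <- trajectories
  n <- length(x$time)
  if (n == 0)
    rg_stop("empty trajectory set", "ratgait_error_empty")
  chk <- validate_marker_set(x)
  if (!chk$pass)
    rg_stop(paste0("trajectories lack marker(s): ",
                   paste(chk$missing, collapse = ", ")),
            "ratgait_error_missing_marker")
  poses <- matrix(NA_real_, n, 13, dimnames = list(NULL, RG_COORDS))
  residual <- rep(NA_real_, n)
  iterations <- integer(n)
  converged <- logical(n)
  flagged <- logical(n)
  init <- neutral_pose()
  cm <- compile_model(model)
  lim <- pose_limits(model)
  w_all <- weights[RG_MARKERS]
  for (f in seq_len(n)) {
    obs <- t(x$positions[f, RG_MARKERS, , drop = TRUE])
    ok <- colSums(!is.finite(obs)) == 0 & !is.na(w_all) & w_all > 0
    if (sum(ok) < 3) {
      flagged[f] <- TRUE
      next
    }
    sol <- solve_frame_core(cm, lim, obs[, ok, drop = FALSE], which(ok),
                            w_all[ok], init, max_iter = max_iter,
                            grad_tol = grad_tol)
    if (!sol$converged || sol$residual > 10) {
      # rare hard frame: full solve with deterministic restarts
      sol <- solve_frame(model, t(obs), weights, init = init,
                         max_iter = max_iter, grad_tol = grad_tol)
    }
    poses[f, ] <- sol$pose
    residual[f] <- sol$residual
    iterations[f] <- sol$iterations
    converged[f] <- sol$converged
    init <- sol$pose
  }
  if (any(flagged)) {
    runs <- rle(flagged)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    solved_idx <- which(!flagged)
    for (k in seq_along(runs$values)) {
      if (!runs$values[k] || runs$lengths[k] > max_gap) next
      idx <- starts[k]:ends[k]
      lo <- max(solved_idx[solved_idx < starts[k]], -Inf)
      hi <- min(solved_idx[solved_idx > ends[k]], Inf)
      if (!is.finite(lo) || !is.finite(hi)) next  # boundary gap: leave NA
      a <- (idx - lo) / (hi - lo)
      poses[idx, ] <- (1 - a) %o% poses[lo, ] + a %o% poses[hi, ]
    }
  }
  structure(list(time = x$time, rate = x$rate, poses = poses,
                 residual = residual, iterations = iterations,
                 converged = converged, interpolated = flagged),
            class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  cat(sprintf("IK result: %d frames, median residual %.3f mm, %.1f%% converged\n",
              length(x$time), stats::median(x$residual, na.rm = TRUE),
              100 * mean(x$converged)))
  if (any(x$interpolated))
    cat(sprintf("  %d frame(s) underdetermined (interpolated where gap <= max_gap)\n",
                sum(x$interpolated)))
  invisible(x)
}

#' @export
as.data.frame.ik_result <- function(x, ...) {
  data.frame(time = x$time, x$poses, residual = x$residual,
             converged = x$converged, check.names = FALSE)
}

#' Write per-frame joint coordinates to CSV
#'
#' @param ik An `ik_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(ik, path) {
  utils::write.csv(as.data.frame(ik), path, row.names = FALSE)
  invisible(path)
}
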