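RG_MARKERS <- c("SPINE", "TAIL", "LASI", "RASI", "HIP", "KNEE", "ANKLE", "TOE")
RG_ANGLES <- c("hip_flexion", "hip_adduction", "hip_rotation",
               "knee_flexion", "ankle_flexion")
RG_COORDS <- c("pelvis_tx", "pelvis_ty", "pelvis_tz",
               "pelvis_rx", "pelvis_ry", "pelvis_rz",
               "hip_flexion", "hip_adduction", "hip_rotation",
               "knee_flexion",
               "ankle_flexion", "ankle_adduction", "ankle_rotation")

#' Build the default rat hindlimb model
#'
#' Constructs the generic four-segment (pelvis, femur, tibia, foot) rigid-body
#' chain with 13 generalized coordinates: 6 for the free pelvis, a 3-DOF ball
#' hip, a 1-DOF hinge knee and a 3-DOF ball ankle. Marker attachment follows
#' the 8-marker rodent set: SPINE, TAIL, LASI and RASI are rigid to the pelvis,
#' HIP sits at the hip joint center (also on the pelvis), KNEE at the knee
#' center (femur), ANKLE at the ankle center (tibia) and TOE at the distal end
#' of the foot.
#'
#' In the neutral pose (all coordinates zero) the pelvis axes are aligned with
#' the lab axes (X anterior, Y up, Z right-lateral), femur and tibia point
#' along -Y and the foot along +X. Generic segment lengths are free parameters
#' of the generic model (they are replaced by [scale_model()] for each animal):
#' pelvis inter-ASIS width 25 mm, femur 35 mm, tibia 40 mm, foot 28 mm.
#'
#' Joint limits default to +/-90 deg for the hip DOFs and ankle flexion,
#' 0-160 deg for knee flexion, and a tight +/-15 deg for the non-sagittal
#' ankle DOFs, which are retained for the 13-DOF count but are essentially
#' sagittally constrained in rat treadmill walking.
#'
#' @return An object of class `rat_model`.
#' @export
#' @examples
#' m <- build_default_model()
#' m$dof_count  # 13
build_default_model <- function() {
  half_w <- 25 / 2
  segments <- list(
    pelvis = list(
      name = "pelvis", parent = NA_character_, generic_length = 25,
      origin_in_parent = NULL,
      marker_offsets = list(
        SPINE = c(-5, 6, 0),
        TAIL = c(-32, 0, 0),
        LASI = c(0, 0, -half_w),
        RASI = c(0, 0, half_w),
        HIP = c(0, -8, half_w)
      )
    ),
    femur = list(
      name = "femur", parent = "pelvis", generic_length = 35,
      origin_in_parent = c(0, -8, half_w),  # hip joint center in pelvis frame
      marker_offsets = list(KNEE = c(0, -35, 0))
    ),
    tibia = list(
      name = "tibia", parent = "femur", generic_length = 40,
      origin_in_parent = c(0, -35, 0),      # knee center in femur frame
      marker_offsets = list(ANKLE = c(0, -40, 0))
    ),
    foot = list(
      name = "foot", parent = "tibia", generic_length = 28,
      origin_in_parent = c(0, -40, 0),      # ankle center in tibia frame
      marker_offsets = list(TOE = c(28, 0, 0))
    )
  )
  joints <- list(
    hip = list(
      name = "hip", kind = "ball",
      rotation_order = c("flexion", "adduction", "rotation"),
      limits = rbind(flexion = c(-90, 90), adduction = c(-90, 90),
                     rotation = c(-90, 90))
    ),
    knee = list(
      name = "knee", kind = "hinge",
      rotation_order = "flexion",
      limits = rbind(flexion = c(0, 160))
    ),
    ankle = list(
      name = "ankle", kind = "ball",
      rotation_order = c("flexion", "adduction", "rotation"),
      limits = rbind(flexion = c(-90, 90), adduction = c(-15, 15),
                     rotation = c(-15, 15))
    )
  )
  model <- list(segments = segments, joints = joints,
                dof_count = 6 + 3 + 1 + 3, marker_names = RG_MARKERS)
  class(model) <- "rat_model"
  validate_rat_model(model)
  model
}

validate_rat_model <- function(model) {
  if (length(model$segments) != 4)
    rg_stop("model must have exactly 4 segments", "ratgait_error_model")
  lens <- vapply(model$segments, function(s) s$generic_length, 0)
  if (any(lens <= 0))
    rg_stop("all segment generic lengths must be > 0", "ratgait_error_model")
  mk <- unlist(lapply(model$segments, function(s) names(s$marker_offsets)))
  if (anyDuplicated(mk))
    rg_stop("each marker may appear on exactly one segment", "ratgait_error_model")
  if (!setequal(mk, RG_MARKERS))
    rg_stop("model markers must be the canonical 8-marker set", "ratgait_error_model")
  ndof <- 6 + sum(vapply(model$joints, function(j) nrow(j$limits), 0L))
  if (model$dof_count != ndof)
    rg_stop("dof_count inconsistent with joint definitions", "ratgait_error_model")
  invisible(model)
}

#' @export
print.rat_model <- function(x, ...) {
  cat("Rat hindlimb rigid-body model (", x$dof_count, " DOF)\n", sep = "")
  for (s in x$segments) {
    cat(sprintf("  %-6s length %6.2f mm  markers: %s\n", s$name,
                s$generic_length, paste(names(s$marker_offsets), collapse = ", ")))
  }
  for (j in x$joints) {
    cat(sprintf("  joint %-5s %-5s [%s]\n", j$name, j$kind,
                paste(j$rotation_order, collapse = ", ")))
  }
  invisible(x)
}

#' Neutral pose
#'
#' All 13 generalized coordinates zero: pelvis at the lab origin with axes
#' aligned to the lab frame, hindlimb hanging along -Y, foot along +X.
#'
#' @return Named numeric vector of length 13 (mm for translations, degrees
#'   for rotations), in the canonical coordinate order.
#' @export
neutral_pose <- function() {
  q <- numeric(13)
  names(q) <- RG_COORDS
  q
}

# Per-coordinate bounds implied by the model's joint limits (pelvis free).
pose_limits <- function(model) {
  lo <- c(rep(-Inf, 3), rep(-180, 3),
          model$joints$hip$limits[, 1],
          model$joints$knee$limits[, 1],
          model$joints$ankle$limits[, 1])
  hi <- c(rep(Inf, 3), rep(180, 3),
          model$joints$hip$limits[, 2],
          model$joints$knee$limits[, 2],
          model$joints$ankle$limits[, 2])
  names(lo) <- names(hi) <- RG_COORDS
  list(lower = lo, upper = hi)
}

#' Forward kinematics of the marker set
#'
#' Computes lab-frame positions of all 8 markers for one pose of the model.
#' The pelvis transform applies the translations then the intrinsic Z-X-Y
#' rotation (`pelvis_rz`, `pelvis_rx`, `pelvis_ry`); ball joints rotate
#' flexion (Z), adduction (X), axial rotation (Y); the knee hinge flexes
#' about -Z so that positive `knee_flexion` carries the ankle posteriorly.
#'
#' @param model A `rat_model`.
#' @param pose Numeric vector of 13 generalized coordinates (mm / deg) in the
#'   canonical order, see [neutral_pose()].
#' @return 8 x 3 numeric matrix of marker positions in lab mm, rows named by
#'   marker.
#' @export
forward_kinematics <- function(model, pose) {
  if (length(pose) != 13 || any(!is.finite(pose)))
    rg_stop("pose must be 13 finite generalized coordinates",
            "ratgait_error_contract")
  out <- t(fk_compiled(compile_model(model), pose))
  dimnames(out) <- list(RG_MARKERS, c("x", "y", "z"))
  out
}

# Precompute the numeric arrays the solver's inner loop needs; marker order
# is RG_MARKERS (columns of the fk_compiled result).
compile_model <- function(model) {
  sg <- model$segments
  pelvis_off <- vapply(RG_MARKERS[1:5], function(mk)
    sg$pelvis$marker_offsets[[mk]], numeric(3))
  list(pelvis_off = pelvis_off,
       hip_off = as.numeric(sg$femur$origin_in_parent),
       knee_marker = as.numeric(sg$femur$marker_offsets$KNEE),
       knee_off = as.numeric(sg$tibia$origin_in_parent),
       ankle_marker = as.numeric(sg$tibia$marker_offsets$ANKLE),
       ankle_off = as.numeric(sg$foot$origin_in_parent),
       toe_marker = as.numeric(sg$foot$marker_offsets$TOE))
}

# Fast forward kinematics: 3 x 8 matrix, columns in RG_MARKERS order.
fk_compiled <- function(cm, pose) {
  t_p <- pose[1:3]
  R_p <- rot_zxy(pose[6], pose[4], pose[5])   # rz, rx, ry
  out <- matrix(0, 3, 8)
  out[, 1:5] <- R_p %*% cm$pelvis_off + t_p
  hipW <- t_p + R_p %*% cm$hip_off
  R_f <- R_p %*% rot_zxy(pose[7], pose[8], pose[9])
  out[, 6] <- hipW + R_f %*% cm$knee_marker
  kneeW <- hipW + R_f %*% cm$knee_off
  R_t <- R_f %*% rot_z(-pose[10])
  out[, 7] <- kneeW + R_t %*% cm$ankle_marker
  ankleW <- kneeW + R_t %*% cm$ankle_off
  R_a <- R_t %*% rot_zxy(pose[11], pose[12], pose[13])
  out[, 8] <- ankleW + R_a %*% cm$toe_marker
  out
}

#' Scale the generic model to an individual animal
#'
#' Segment lengths are measured from a single static-pose frame with the
#' markers over the joint centers: femur = |HIP-KNEE|, tibia = |KNEE-ANKLE|,
#' foot = |ANKLE-TOE|, pelvis width = |LASI-RASI|. Each segment is scaled
#' independently by measured/generic length, and all marker offsets and child
#' joint-center offsets scale with their segment.
#'
#' @param model Generic `rat_model`.
#' @param static_markers 8 x 3 matrix (rows named by marker) or named list of
#'   3-vectors: one frame of all 8 markers, lab mm.
#' @param static_id Optional identifier of the static frame, recorded in the
#'   returned scale object.
#' @return List with elements `model` (scaled `rat_model`) and `scale`
#'   (class `model_scale`: per-segment factors and the source frame id).
#' @export
scale_model <- function(model, static_markers, static_id = NA_character_) {
  sm <- as_marker_frame(static_markers)
  missing <- setdiff(RG_MARKERS, rownames(sm))
  present <- intersect(RG_MARKERS, rownames(sm))
  bad <- present[!apply(sm[present, , drop = FALSE], 1,
                        function(r) all(is.finite(r)))]
  missing <- union(missing, bad)
  if (length(missing))
    rg_stop(paste0("static frame is missing marker(s): ",
                   paste(missing, collapse = ", ")),
            "ratgait_error_missing_marker")
  dist <- function(a, b) sqrt(sum((sm[a, ] - sm[b, ])^2))
  meas <- c(pelvis = dist("LASI", "RASI"), femur = dist("HIP", "KNEE"),
            tibia = dist("KNEE", "ANKLE"), foot = dist("ANKLE", "TOE"))
  if (any(meas <= 1))
    rg_stop(paste0("degenerate static pose: segment length(s) <= 1 mm: ",
                   paste(names(meas)[meas <= 1], collapse = ", ")),
            "ratgait_error_degenerate_pose")
  generic <- vapply(model$segments, function(s) s$generic_length, 0)
  factors <- meas / generic[names(meas)]
  scaled <- model
  for (seg in names(factors)) {
    k <- factors[[seg]]
    scaled$segments[[seg]]$generic_length <- meas[[seg]]
    scaled$segments[[seg]]$marker_offsets <-
      lapply(scaled$segments[[seg]]$marker_offsets, function(o) o * k)
    child <- names(model$segments)[vapply(model$segments,
                                          function(s) identical(s$parent, seg), NA)]
    for (ch in child)
      scaled$segments[[ch]]$origin_in_parent <-
        scaled$segments[[ch]]$origin_in_parent * k
  }
  sc <- structure(list(factors = factors, static_id = static_id),
                  class = "model_scale")
  list(model = scaled, scale = sc)
}

#' @export
print.model_scale <- function(x, ...) {
  cat("Model scale factors:\n")
  print(round(x$factors, 4))
  invisible(x)
}

as_marker_frame <- function(m) {
  if (is.list(m) && !is.data.frame(m)) {
    m <- do.call(rbind, m)
  }
  m <- as.matrix(m)
  if (ncol(m) != 3)
    rg_stop("marker frame must have 3 columns (x, y, z)", "ratgait_error_contract")
  m
}

#' Sagittal knee angle from the two-link closed form
#'
#' Law of cosines on the hip-knee-ankle triangle: given femur and tibia
#' lengths and the hip-ankle distance, returns the knee flexion angle,
#' defined as 180 deg minus the interior angle at the knee, so that 0 deg is
#' full extension and larger values are flexion. This is the closed-form
#' counterpart of driving the model's hinge knee from the HIP and ANKLE
#' markers alone, and serves as an independent check on the IK solver.
#'
#' @param femur_len,tibia_len Segment lengths, mm.
#' @param hip_ankle_dist Hip-to-ankle distance, mm.
#' @return Knee flexion, degrees.
#' @export
#' @examples
#' knee_angle_two_link(30, 40, 50)  # right triangle: 90 deg
knee_angle_two_link <- function(femur_len, tibia_len, hip_ankle_dist) {
  if (hip_ankle_dist > femur_len + tibia_len + 1e-9 ||
      hip_ankle_dist < abs(femur_len - tibia_len) - 1e-9)
    rg_stop("hip-ankle distance violates the triangle inequality: configuration unreachable",
            "ratgait_error_unreachable")
  cosi <- (femur_len^2 + tibia_len^2 - hip_ankle_dist^2) /
    (2 * femur_len * tibia_len)
  cosi <- min(1, max(-1, cosi))
  180 - acos(cosi) / DEG
}

#' Write / read a model configuration
#'
#' Serializes segment lengths, marker offsets, joint limits and rotation
#' orders to YAML so that a scaled or customized model can be re-used across
#' sessions and tools.
#'
#' @param model A `rat_model`.
#' @param path File path.
#' @return `read_model_config` returns a `rat_model`; `write_model_config`
#'   returns `path` invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    segments = lapply(model$segments, function(s) list(
      name = s$name, parent = if (is.na(s$parent)) NULL else s$parent,
      generic_length = s$generic_length,
      origin_in_parent = if (is.null(s$origin_in_parent)) NULL else as.numeric(s$origin_in_parent),
      marker_offsets = lapply(s$marker_offsets, as.numeric)
    )),
    joints = lapply(model$joints, function(j) list(
      name = j$name, kind = j$kind,
      rotation_order = as.list(j$rotation_order),
      limits = apply(j$limits, 1, as.numeric, simplify = FALSE)
    ))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  segments <- lapply(cfg$segments, function(s) list(
    name = s$name, parent = s$parent %||% NA_character_,
    generic_length = s$generic_length,
    origin_in_parent = if (is.null(s$origin_in_parent)) NULL else unlist(s$origin_in_parent),
    marker_offsets = lapply(s$marker_offsets, unlist)
  ))
  names(segments) <- vapply(segments, `[[`, "", "name")
  joints <- lapply(cfg$joints, function(j) {
    lim <- do.call(rbind, lapply(j$limits, unlist))
    rownames(lim) <- unlist(j$rotation_order)
    list(name = j$name, kind = j$kind,
         rotation_order = unlist(j$rotation_order), limits = lim)
  })
  names(joints) <- vapply(joints, `[[`, "", "name")
  model <- list(segments = segments, joints = joints,
                dof_count = 6 + sum(vapply(joints, function(j) nrow(j$limits), 0L)),
                marker_names = RG_MARKERS)
  class(model) <- "rat_model"
  validate_rat_model(model)
  model
}
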