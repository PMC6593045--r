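test_that("default model has the published structure", {
  m <- build_default_model()
  expect_s3_class(m, "rat_model")
  expect_length(m$segments, 4)
  expect_setequal(names(m$segments), c("pelvis", "femur", "tibia", "foot"))
  expect_identical(m$dof_count, 13)
  markers <- unlist(lapply(m$segments, function(s) names(s$marker_offsets)))
  expect_setequal(markers, MARKERS8)
  expect_length(markers, 8)
  expect_identical(m$joints$hip$kind, "ball")
  expect_identical(m$joints$knee$kind, "hinge")
  expect_identical(m$joints$ankle$kind, "ball")
  lims <- do.call(rbind, lapply(m$joints, function(j) j$limits))
  expect_true(all(lims[, 1] < lims[, 2]))
})

test_that("neutral-pose forward kinematics matches the reference geometry", {
  m <- build_default_model()
  fk <- forward_kinematics(m, neutral_pose())
  femur <- m$segments$femur$generic_length
  tibia <- m$segments$tibia$generic_length
  foot <- m$segments$foot$generic_length
  expect_equal(sqrt(sum((fk["HIP", ] - fk["KNEE", ])^2)), femur, tolerance = 1e-12)
  expect_equal(sqrt(sum((fk["KNEE", ] - fk["ANKLE", ])^2)), tibia, tolerance = 1e-12)
  expect_equal(sqrt(sum((fk["ANKLE", ] - fk["TOE", ])^2)), foot, tolerance = 1e-12)
  expect_equal(sqrt(sum((fk["LASI", ] - fk["RASI", ])^2)),
               m$segments$pelvis$generic_length, tolerance = 1e-12)
  # limb hangs straight down from the hip, foot along +X
  expect_equal(unname(fk["KNEE", c("x", "z")]), unname(fk["HIP", c("x", "z")]))
  expect_equal(unname(fk["TOE", "y"]), unname(fk["ANKLE", "y"]))
})

test_that("pure hip flexion rotates the knee about the hip mediolateral axis", {
  m <- build_default_model()
  fk0 <- forward_kinematics(m, neutral_pose())
  q <- neutral_pose()
  q["hip_flexion"] <- 90
  fk <- forward_kinematics(m, q)
  hip <- fk0["HIP", ]
  v0 <- fk0["KNEE", ] - hip
  v1 <- fk["KNEE", ] - hip
  # 90 deg about +Z through the hip center: (x, y, z) -> (-y, x, z)
  expect_equal(unname(v1), unname(c(-v0[2], v0[1], v0[3])), tolerance = 1e-12)
})

test_that("forward kinematics is rigid: within-segment distances are pose-invariant", {
  m <- build_default_model()
  set.seed(42)
  d0 <- NULL
  pairs <- list(c("HIP", "KNEE"), c("KNEE", "ANKLE"), c("ANKLE", "TOE"),
                c("LASI", "RASI"), c("SPINE", "TAIL"), c("SPINE", "LASI"))
  for (i in 1:25) {
    fk <- forward_kinematics(m, random_pose())
    d <- vapply(pairs, function(p) sqrt(sum((fk[p[1], ] - fk[p[2], ])^2)), 0)
    if (is.null(d0)) d0 <- d
    expect_equal(d, d0, tolerance = 1e-9)
  }
  expect_error(forward_kinematics(m, rep(0, 12)), class = "ratgait_error_contract")
})

test_that("scale_model measures segment lengths from a static frame", {
  m <- build_default_model()
  static <- forward_kinematics(m, neutral_pose())
  sc <- scale_model(m, static)
  expect_equal(unname(sc$scale$factors), rep(1, 4), tolerance = 1e-12)

  sc2 <- scale_model(m, static * 2)
  expect_equal(unname(sc2$scale$factors), rep(2, 4), tolerance = 1e-12)
  expect_equal(sc2$model$segments$femur$generic_length,
               2 * m$segments$femur$generic_length)
  # marker offsets scale with their segment
  expect_equal(sc2$model$segments$foot$marker_offsets$TOE,
               2 * m$segments$foot$marker_offsets$TOE)

  # homogeneity on a random-pose static frame
  set.seed(11)
  fr <- forward_kinematics(m, random_pose())
  k <- 1.37
  f1 <- scale_model(m, fr)$scale$factors
  f2 <- scale_model(m, fr * k)$scale$factors
  expect_equal(unname(f2 / f1), rep(k, 4), tolerance = 1e-9)
})

test_that("scale_model rejects missing markers and degenerate poses", {
  m <- build_default_model()
  static <- forward_kinematics(m, neutral_pose())
  expect_error(scale_model(m, static[-8, ]),
               class = "ratgait_error_missing_marker")
  expect_error(scale_model(m, static[-8, ]), "TOE")
  degenerate <- static
  degenerate["KNEE", ] <- degenerate["HIP", ]
  expect_error(scale_model(m, degenerate),
               class = "ratgait_error_degenerate_pose")
})

test_that("two-link knee angle matches closed-form triangles", {
  expect_equal(knee_angle_two_link(30, 30, 60), 0, tolerance = 1e-9)
  expect_equal(knee_angle_two_link(30, 30, 30), 120, tolerance = 1e-9)
  expect_equal(knee_angle_two_link(30, 40, 50), 90, tolerance = 1e-9)
  expect_error(knee_angle_two_link(30, 30, 61),
               class = "ratgait_error_unreachable")
  expect_error(knee_angle_two_link(30, 10, 5),
               class = "ratgait_error_unreachable")
})

test_that("knee angle is consistent with the kinematic chain", {
  m <- build_default_model()
  for (kf in c(10, 45, 90, 130)) {
    q <- neutral_pose()
    q["knee_flexion"] <- kf
    fk <- forward_kinematics(m, q)
    d <- sqrt(sum((fk["HIP", ] - fk["ANKLE", ])^2))
    expect_equal(knee_angle_two_link(m$segments$femur$generic_length,
                                     m$segments$tibia$generic_length, d),
                 kf, tolerance = 1e-9)
  }
})

test_that("model configuration round-trips through YAML", {
  m <- build_default_model()
  static <- forward_kinematics(m, neutral_pose()) * 1.21
  scaled <- scale_model(m, static)$model
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(scaled, path)
  m2 <- read_model_config(path)
  expect_equal(m2$dof_count, 13)
  expect_equal(m2$segments$femur$generic_length,
               scaled$segments$femur$generic_length, tolerance = 1e-9)
  set.seed(5)
  qr <- random_pose()
  expect_equal(forward_kinematics(m2, qr), forward_kinematics(scaled, qr),
               tolerance = 1e-9)
})
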