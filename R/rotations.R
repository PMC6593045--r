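# Elementary rotation matrices, angles in degrees.
# Lab frame convention used throughout the package:
#   X = belt travel direction (anterior), Y = vertical up, Z = right-lateral.

DEG <- pi / 180

rot_x <- function(a) {
  a <- a * DEG
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

rot_y <- function(a) {
  a <- a * DEG
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

rot_z <- function(a) {
  a <- a * DEG
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# Intrinsic Z-X-Y sequence: flexion about Z, ad/abduction about X,
# internal/external rotation about Y (the segment long axis in neutral).
# Written out elementwise; this sits in the innermost IK loop.
rot_zxy <- function(flex, add, rot) {
  f <- flex * DEG; a <- add * DEG; r <- rot * DEG
  cf <- cos(f); sf <- sin(f)
  ca <- cos(a); sa <- sin(a)
  cr <- cos(r); sr <- sin(r)
  matrix(c(
    cf * cr - sf * sa * sr,  sf * cr + cf * sa * sr, -ca * sr,
    -sf * ca,                cf * ca,                 sa,
    cf * sr + sf * sa * cr,  sf * sr - cf * sa * cr,  ca * cr
  ), 3, 3)
}
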