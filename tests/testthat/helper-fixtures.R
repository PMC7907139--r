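# Shared fixtures, built in code.

# Random proper rigid transform with rotation drawn uniformly via random
# axis + angle and translation within +/- range_mm.
random_transform <- function(range_mm = 100, from = "world", to = "world") {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  compose_free(
    rotation_about_axis(ax, stats::runif(1, -180, 180), from = from, to = to),
    stats::runif(3, -range_mm, range_mm)
  )
}

compose_free <- function(rot, t) {
  rigid_transform(rot$R, t, from = rot$from, to = rot$to)
}

# Non-degenerate 3D test point cloud (mm scale).
random_points <- function(n = 6, scale = 50) {
  matrix(stats::runif(3 * n, -scale, scale), n, 3)
}

# A well-conditioned 4-point planar marker, side `side` mm.
square_template_points <- function(side = 40) {
  s <- side / 2
  rbind(c(-s, -s, 0), c(s, -s, 0), c(s, 0.8 * s, 0), c(-0.6 * s, s, 0))
}

# Marker pose well inside the default rig's working volume.
tracker_test_pose <- function(x = 0, y = 30, z = 800, tilt_deg = 150,
                              from = "m") {
  rigid_transform(rotation_about_axis(c(1, 0, 0), tilt_deg)$R, c(x, y, z),
                  from = from, to = "S")
}

scope_test_intrinsics <- function() {
  camera_intrinsics(420, 420, (640 - 1) / 2, (480 - 1) / 2, 640, 480)
}

# Independent oracle: map a point through the frame chain step by step
# with raw matrix arithmetic (no package compose/invert on the full chain).
chain_point_oracle <- function(T_sM, T_sA, geom, theta_deg, p_M) {
  p_S <- T_sM$R %*% p_M + T_sM$t
  p_A <- t(T_sA$R) %*% (p_S - T_sA$t)
  p_T <- geom$T_AT$R %*% p_A + geom$T_AT$t
  B <- scopesight:::camera_basis_in_tip(geom, theta_deg)
  as.numeric(t(B) %*% p_T)
}
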