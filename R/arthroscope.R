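#' Oblique-viewing arthroscope geometry
#'
#' An angled-lens arthroscope views along an optical axis tilted away from
#' the mechanical shaft axis by the lens-offset angle (30 degrees for the
#' scopes used in elbow arthroscopy). Rotating the lens cylinder by the
#' angle `theta` sweeps the viewing direction around a cone about the shaft
#' axis; the image rotates with the cylinder.
#'
#' @param lens_offset_deg lens-offset angle, degrees, in (0, 90). Default 30.
#' @param T_AT `rigid_transform` from the scope-head marker frame `A` to the
#'   scope tip frame `T` (pre-defined per session, mm).
#' @param scope_axis unit shaft-axis direction in the tip frame.
#' @param cylinder_marker_offset `rigid_transform` cylinder-marker frame
#'   `L` -> `A` at cylinder angle 0 (used by simulations).
#' @return list of class `arthroscope_geometry`.
#' @export
arthroscope_geometry <- function(lens_offset_deg = 30,
                                 T_AT = rigid_transform(diag(3), c(0, 0, -180),
                                                        from = "A", to = "T"),
                                 scope_axis = c(0, 0, 1),
                                 cylinder_marker_offset =
                                   rigid_transform(diag(3), c(0, 25, 60),
                                                   from = "L", to = "A")) {
  if (lens_offset_deg <= 0 || lens_offset_deg >= 90)
    stop_ss("config_error", "lens_offset_deg must lie in (0, 90), got %g", lens_offset_deg)
  scope_axis <- as.numeric(scope_axis)
  if (abs(sqrt(sum(scope_axis^2)) - 1) > 1e-9)
    stop_ss("config_error", "scope_axis must be a unit vector")
  stopifnot(is_rigid_transform(T_AT))
  structure(list(lens_offset_deg = lens_offset_deg, T_AT = T_AT,
                 scope_axis = scope_axis,
                 cylinder_marker_offset = cylinder_marker_offset),
            class = "arthroscope_geometry")
}

# Deterministic unit vector perpendicular to v.
perp_vector <- function(v) {
  e <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) c(1, 0, 0)
       else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
  unit_vector(c(v[2] * e[3] - v[3] * e[2],
                v[3] * e[1] - v[1] * e[3],
                v[1] * e[2] - v[2] * e[1]))
}

# Camera basis (columns = camera x, y, z axes in tip coordinates) for
# cylinder angle theta. Camera z is the optical axis: the scope axis tilted
# by the lens-offset angle, swung by theta about the scope axis. The whole
# basis rotates with theta, so the image rotates with the cylinder.
camera_basis_in_tip <- function(geom, theta_deg) {
  z_s <- geom$scope_axis
  a0 <- perp_vector(z_s)
  y0 <- c(z_s[2] * a0[3] - z_s[3] * a0[2],
          z_s[3] * a0[1] - z_s[1] * a0[3],
          z_s[1] * a0[2] - z_s[2] * a0[1])
  base <- cbind(a0, y0, z_s)
  rotation_matrix_about(z_s, theta_deg) %*%
    rotation_matrix_about(a0, geom$lens_offset_deg) %*% base
}

#' Virtual camera pose for a cylinder angle
#'
#' Places the virtual camera at the scope tip origin with its optical axis
#' tilted from the shaft axis by the lens-offset angle at azimuth `theta`,
#' the up-vector rigidly attached to the cylinder.
#'
#' @param tip_pose `rigid_transform` from some frame `X` to the tip frame `T`
#'   (identity to express the camera in tip coordinates).
#' @param geom an `arthroscope_geometry`.
#' @param theta_deg lens-cylinder rotation angle, degrees.
#' @return `rigid_transform` from `X` to the camera-sight frame `C`.
#' @export
virtual_camera_pose <- function(tip_pose, geom, theta_deg) {
  stopifnot(is_rigid_transform(tip_pose))
  B <- camera_basis_in_tip(geom, theta_deg)
  tip_to_cam <- rigid_transform(t(B), c(0, 0, 0), from = tip_pose$to, to = "C")
  compose(tip_to_cam, tip_pose)
}

#' Optical-axis direction in the tip frame
#'
#' @inheritParams virtual_camera_pose
#' @return unit 3-vector in tip coordinates.
#' @export
optical_axis <- function(geom, theta_deg) {
  camera_basis_in_tip(geom, theta_deg)[, 3]
}

#' Estimate the lens-cylinder rotation angle from two marker poses
#'
#' The relative transform from the scope-head marker to the cylinder marker
#' is compared with a reference pair captured at cylinder angle 0; the
#' rotation between the two, about the shaft axis, is the cylinder angle.
#'
#' @param head_pose,cyl_pose `tracked_pose`s (or bare `rigid_transform`s,
#'   marker-local -> S) of the scope-head and lens-cylinder markers.
#' @param reference list with elements `head` and `cyl`: the pose pair
#'   captured once at cylinder angle 0.
#' @param geom an `arthroscope_geometry` (supplies the shaft axis and `T_AT`).
#' @param misalignment_tol_deg axis-deviation threshold for the warning flag.
#' @return list with `angle_deg` in (-180, 180], `axis_deviation_deg`, and
#'   logical `misaligned` (TRUE when the relative rotation axis deviates
#'   from the shaft axis by more than `misalignment_tol_deg`; a
#'   `misalignment_warning` is also signalled).
#' @export
estimate_cylinder_angle <- function(head_pose, cyl_pose, reference, geom,
                                    misalignment_tol_deg = 5) {
  tf <- function(p) if (inherits(p, "tracked_pose")) p$transform else p
  rel <- function(head, cyl) t(head$R) %*% cyl$R   # cylinder axes in head-marker frame
  R_now <- rel(tf(head_pose), tf(cyl_pose))
  R_ref <- rel(tf(reference$head), tf(reference$cyl))
  R_delta <- R_now %*% t(R_ref)
  # shaft axis expressed in the head-marker frame A
  axis_A <- as.numeric(t(geom$T_AT$R) %*% geom$scope_axis)
  aa <- rotation_axis_angle(R_delta)
  if (aa$angle_deg == 0)
    return(list(angle_deg = 0, axis_deviation_deg = 0, misaligned = FALSE))
  s <- sum(aa$axis * axis_A)
  angle <- if (s < 0) -aa$angle_deg else aa$angle_deg
  dev <- rad2deg(acos(min(1, abs(s))))
  # the axis of a near-identity rotation is noise-dominated; a genuine
  # mount misalignment shows up as an off-axis rotation component, so flag
  # on that component (> 2 deg) together with the axis deviation itself
  off_axis <- abs(angle) * sin(deg2rad(dev))
  mis <- dev > misalignment_tol_deg && off_axis > 2
  if (mis)
    warn_ss("misalignment_warning",
            "relative rotation axis deviates %.2f deg from the shaft axis (off-axis component %.2f deg)",
            dev, off_axis)
  if (angle <= -180) angle <- angle + 360
  list(angle_deg = angle, axis_deviation_deg = dev, misaligned = mis)
}

#' Full arthroscope camera model
#'
#' Bundles intrinsics, lens distortion and scope geometry; this is what a
#' calibration session produces and what the overlay pipeline consumes.
#'
#' @param intrinsics a `camera_intrinsics`.
#' @param distortion a `distortion_model`.
#' @param geometry an `arthroscope_geometry`.
#' @return list of class `arthroscope_model`.
#' @export
arthroscope_model <- function(intrinsics, distortion, geometry) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            inherits(distortion, "distortion_model"),
            inherits(geometry, "arthroscope_geometry"))
  structure(list(intrinsics = intrinsics, distortion = distortion,
                 geometry = geometry),
            class = "arthroscope_model")
}

#' Default simulated arthroscope
#'
#' A 30-degree scope with a mildly fisheye barrel lens: 640 x 480 sensor,
#' f = 420 px, k1 = -0.22, k2 = 0.05.
#'
#' @param ... overrides passed to [arthroscope_geometry()].
#' @return an `arthroscope_model`.
#' @export
default_arthroscope <- function(...) {
  arthroscope_model(
    camera_intrinsics(fx = 420, fy = 420, cx = (640 - 1) / 2, cy = (480 - 1) / 2,
                      width = 640, height = 480),
    distortion_model(k1 = -0.22, k2 = 0.05),
    arthroscope_geometry(...)
  )
}

#' Write / read an arthroscope calibration file (JSON)
#'
#' Layout: `fx, fy, cx, cy, width, height, k1..k3, p1, p2, lens_offset_deg,
#' scope_axis`, and `T_AT` as a 4x4 homogeneous matrix.
#'
#' @param model an `arthroscope_model`; @param path file path.
#' @export
write_calibration_json <- function(model, path) {
  i <- model$intrinsics; d <- model$distortion; g <- model$geometry
  jsonlite::write_json(list(
    fx = i$fx, fy = i$fy, cx = i$cx, cy = i$cy,
    width = i$width, height = i$height,
    k1 = d$k1, k2 = d$k2, k3 = d$k3, p1 = d$p1, p2 = d$p2,
    lens_offset_deg = g$lens_offset_deg,
    scope_axis = g$scope_axis,
    T_AT = unname(as_homogeneous(g$T_AT)),
    cylinder_marker_offset = unname(as_homogeneous(g$cylinder_marker_offset))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  arthroscope_model(
    camera_intrinsics(x$fx, x$fy, x$cx, x$cy, x$width, x$height),
    distortion_model(x$k1, x$k2, x$k3, x$p1, x$p2),
    arthroscope_geometry(
      lens_offset_deg = x$lens_offset_deg,
      T_AT = from_homogeneous(x$T_AT, from = "A", to = "T"),
      scope_axis = x$scope_axis,
      cylinder_marker_offset = from_homogeneous(x$cylinder_marker_offset,
                                                from = "L", to = "A")
    )
  )
}
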