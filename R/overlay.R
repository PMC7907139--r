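#' Model-to-camera transform chain
#'
#' The AR core: combines the tracked pose of the model base plate
#' (`T_sM`, model base M -> sensor S), the tracked pose of the scope-head
#' marker (`T_sA`, A -> S), the pre-calibrated marker-to-tip offset and the
#' lens-cylinder angle into the transform that maps model-base coordinates
#' into the camera-sight frame C:
#' `M -> C  =  virtual_camera_pose(T_AT o invert(T_sA)) o T_sM`.
#'
#' @param T_sM,T_sA `rigid_transform`s (or `tracked_pose`s) of the base and
#'   scope-head markers in the sensor frame.
#' @param geom an `arthroscope_geometry`.
#' @param theta_deg lens-cylinder rotation angle (degrees).
#' @return `rigid_transform` from M to C.
#' @export
model_to_camera <- function(T_sM, T_sA, geom, theta_deg) {
  if (inherits(T_sM, "tracked_pose")) T_sM <- T_sM$transform
  if (inherits(T_sA, "tracked_pose")) T_sA <- T_sA$transform
  if (!identical(T_sM$to, T_sA$to))
    stop_ss("frame_mismatch_error",
            "base and scope poses live in different frames ('%s' vs '%s')",
            T_sM$to, T_sA$to)
  # tracked poses carry template names as from-frames; the chain is defined
  # on the canonical labels M (model base) and A (scope-head marker)
  T_sM <- rigid_transform(T_sM$R, T_sM$t, from = "M", to = T_sM$to)
  T_sA <- rigid_transform(T_sA$R, T_sA$t, from = "A", to = T_sA$to)
  tip_pose <- compose(geom$T_AT, invert(T_sA))       # sensor -> tip
  cam <- virtual_camera_pose(tip_pose, geom, theta_deg)  # sensor -> camera sight
  compose(cam, T_sM)                                 # model base -> camera sight
}

#' AR scene description
#'
#' @param organs list of `organ_model`s.
#' @param templates a `template_database`.
#' @param scope an `arthroscope_model`.
#' @param base_marker,head_marker,cylinder_marker template names; must exist
#'   in the database.
#' @param delta_T registration adjustment (M -> M), default identity; set by
#'   [refine_registration()].
#' @return list of class `ar_scene`.
#' @export
ar_scene <- function(organs, templates, scope,
                     base_marker = "base", head_marker = "head",
                     cylinder_marker = "cylinder",
                     delta_T = rigid_transform(from = "M", to = "M")) {
  nm <- c(base_marker, head_marker, cylinder_marker)
  missing <- setdiff(nm, names(templates))
  if (length(missing))
    stop_ss("config_error", "markers not in template database: %s",
            paste(missing, collapse = ", "))
  stopifnot(inherits(scope, "arthroscope_model"))
  structure(list(organs = organs, templates = templates, scope = scope,
                 base_marker = base_marker, head_marker = head_marker,
                 cylinder_marker = cylinder_marker, delta_T = delta_T),
            class = "ar_scene")
}

# Unique undirected edges of a mesh (E x 2 vertex indices).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Clip 3D segments to the near plane z >= z_near (camera frame), then
# project and clip in 2D to the image rectangle (Liang-Barsky). Returns a
# matrix of segments (u0, v0, u1, v1); segments fully outside are removed,
# partially outside are clipped, never silently mangled.
project_segments <- function(intr, dist, p0, p1, z_near = 1e-6) {
  keep <- p0[, 3] > z_near | p1[, 3] > z_near
  p0 <- p0[keep, , drop = FALSE]; p1 <- p1[keep, , drop = FALSE]
  if (nrow(p0) == 0L) return(matrix(numeric(0), 0, 4))
  crossing <- which((p0[, 3] <= z_near) != (p1[, 3] <= z_near))
  if (length(crossing)) {
    a <- p0[crossing, , drop = FALSE]; b <- p1[crossing, , drop = FALSE]
    t <- (z_near - a[, 3]) / (b[, 3] - a[, 3])
    cut <- a + (b - a) * t
    a_behind <- a[, 3] <= z_near
    p0[crossing[a_behind], ] <- cut[a_behind, , drop = FALSE]
    p1[crossing[!a_behind], ] <- cut[!a_behind, , drop = FALSE]
  }
  q0 <- project_points(intr, dist, p0)
  q1 <- project_points(intr, dist, p1)
  seg <- cbind(q0, q1)
  clip_segments_2d(seg, intr$width, intr$height)
}

clip_segments_2d <- function(seg, width, height) {
  if (nrow(seg) == 0L) return(seg)
  x0 <- seg[, 1]; y0 <- seg[, 2]; x1 <- seg[, 3]; y1 <- seg[, 4]
  dx <- x1 - x0; dy <- y1 - y0
  t0 <- rep(0, nrow(seg)); t1 <- rep(1, nrow(seg))
  ok <- rep(TRUE, nrow(seg))
  for (k in 1:4) {
    p <- switch(k, -dx, dx, -dy, dy)
    q <- switch(k, x0 - 0, (width - 1) - x0, y0 - 0, (height - 1) - y0)
    par <- p == 0
    ok <- ok & !(par & q < 0)
    r <- ifelse(p == 0, NA, q / p)
    ent <- !par & p < 0
    ext <- !par & p > 0
    t0 <- ifelse(ent, pmax(t0, r), t0)
    t1 <- ifelse(ext, pmin(t1, r), t1)
  }
  ok <- ok & t0 <= t1
  if (!any(ok)) return(matrix(numeric(0), 0, 4))
  i <- which(ok)
  out <- cbind(x0[i] + t0[i] * dx[i], y0[i] + t0[i] * dy[i],
               x0[i] + t1[i] * dx[i], y0[i] + t1[i] * dy[i])
  # clamp roundoff so clipped endpoints sit exactly on the image rectangle
  out[, c(1, 3)] <- pmin(pmax(out[, c(1, 3)], 0), width - 1)
  out[, c(2, 4)] <- pmin(pmax(out[, c(2, 4)], 0), height - 1)
  out
}

#' Render the AR overlay for one frame
#'
#' Projects each organ mesh's edges through the model-to-camera chain with
#' lens distortion and clips them to the image. Organs entirely behind the
#' camera yield empty primitive lists, not errors. No hidden-surface
#' removal: structures behind the joint capsule are intentionally drawn.
#'
#' @param scene an `ar_scene`.
#' @param T_MC `rigid_transform` model base -> camera sight for this frame.
#' @param frame_index integer tag.
#' @param base_raster optional background image matrix (values 0..255,
#'   `height x width`); defaults to flat mid-gray.
#' @return `ar_frame`: list with `frame_index`, `primitives` (per-organ
#'   segment matrices in px), `base_raster`, `composited`.
#' @export
render_overlay <- function(scene, T_MC, frame_index = 0L, base_raster = NULL) {
  intr <- scene$scope$intrinsics
  if (is.null(base_raster))
    base_raster <- matrix(128L, nrow = intr$height, ncol = intr$width)
  chain <- compose(T_MC, scene$delta_T)   # adjusted model -> camera
  prims <- lapply(scene$organs, function(o) {
    mm <- organ_mesh_in_model_frame(o)
    vc <- sweep(mm$vertices %*% t(chain$R), 2, chain$t, `+`)
    ed <- mesh_edges(mm)
    seg <- project_segments(intr, scene$scope$distortion,
                            vc[ed[, 1], , drop = FALSE],
                            vc[ed[, 2], , drop = FALSE])
    list(name = o$name, segments = seg)
  })
  comp <- base_raster
  for (p in prims) comp <- draw_segments(comp, p$segments)
  structure(list(frame_index = frame_index, primitives = prims,
                 base_raster = base_raster, composited = comp),
            class = "ar_frame")
}

# Bresenham rasterization of segments into an image matrix (rows = y).
draw_segments <- function(img, seg, value = 255L) {
  if (nrow(seg) == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(nrow(seg))) {
    x0 <- round(seg[i, 1]); y0 <- round(seg[i, 2])
    x1 <- round(seg[i, 3]); y1 <- round(seg[i, 4])
    n <- max(abs(x1 - x0), abs(y1 - y0)) + 1
    xs <- round(seq(x0, x1, length.out = n)); ys <- round(seq(y0, y1, length.out = n))
    keep <- xs >= 0 & xs < w & ys >= 0 & ys < h
    img[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- value
  }
  img
}

#' Write a raster as ASCII PGM (P2)
#'
#' Text-based and byte-deterministic.
#' @param img matrix of gray values 0..255 (rows = image rows).
#' @param path output path.
#' @export
write_pgm <- function(img, path) {
  con <- file(path, "wb")  # binary mode: "\n" endings on every platform
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255",
               apply(img, 1, paste, collapse = " ")),
             con, sep = "\n")
  invisible(path)
}

#' Landmark-based registration refinement
#'
#' Surrogate for the manual registration adjustment done against
#' recognizable intra-articular shapes (capitellum, radial head): a rigid
#' fit of model-frame landmarks to their observed model-frame positions,
#' stored as the scene's pre-multiplying correction `delta_T`.
#'
#' @param scene an `ar_scene`.
#' @param model_pts,observed_pts paired N x 3 landmark sets in the model
#'   base frame, N >= 3, non-collinear.
#' @return list with `scene` (updated), `delta_T`, `rms_residual` (mm).
#' @export
refine_registration <- function(scene, model_pts, observed_pts) {
  fit <- absolute_orientation(model_pts, observed_pts,
                              src_frame = "M", dst_frame = "M")
  scene$delta_T <- fit$transform
  list(scene = scene, delta_T = fit$transform, rms_residual = fit$rms_residual)
}

# Rotation taking unit vector u onto unit vector v.
rotation_from_to <- function(u, v) {
  u <- unit_vector(u); v <- unit_vector(v)
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    p <- perp_vector(u)
    return(rotation_matrix_about(p, 180))
  }
  rotation_matrix_about(ax / s, rad2deg(atan2(s, c_)))
}

# Ground-truth pose layout for a session frame: the scope tip is placed so
# that at cylinder angle `aim_theta` the optical axis passes through
# `target_M` at `distance_mm`. Returns the true marker poses in S.
session_ground_truth <- function(phantom, geom, theta_deg, target_M,
                                 distance_mm = 40, aim_theta = NULL,
                                 view_dir_M = c(0.2, -0.4, -1)) {
  aim_theta <- aim_theta %||% theta_deg
  d <- unit_vector(view_dir_M)
  a <- optical_axis(geom, aim_theta)
  R_MT <- rotation_from_to(a, d)
  tip_pos <- target_M - distance_mm * d
  T_MT <- rigid_transform(R_MT, tip_pos, from = "T", to = "M")
  T_sT <- compose(phantom$T_sM, T_MT)
  T_sA <- compose(T_sT, geom$T_AT)
  axis_A <- as.numeric(t(geom$T_AT$R) %*% geom$scope_axis)
  T_AL <- compose(rotation_about_axis(axis_A, theta_deg, from = "A", to = "A"),
                  geom$cylinder_marker_offset)
  list(T_sM = phantom$T_sM, T_sA = T_sA, T_sL = compose(T_sA, T_AL),
       T_MT = T_MT)
}

#' Run a simulated AR session
#'
#' For each frame: observe the three markers through the stereo tracker,
#' estimate their poses, estimate the cylinder angle against a reference
#' captured at angle 0, build the model-to-camera chain and render the
#' overlay. Deterministic under `(config, seed)`.
#'
#' @param config session configuration list (see [session_config()]).
#' @param seed integer master seed for tracker noise.
#' @return list of class `ar_session`: `frames` (list of `ar_frame`),
#'   `pose_log` (data frame), `theta_log` (commanded vs estimated angle),
#'   `log` (character messages, e.g. skipped frames), `scene`, `rig`.
#' @export
run_session <- function(config = session_config(), seed = 1L) {
  config <- validate_session_config(config)
  phantom <- config$phantom %||% generate_phantom(phantom_spec(seed = config$phantom_seed))
  scope <- config$scope %||% default_arthroscope()
  geom <- scope$geometry
  rig <- config$rig %||% stereo_rig()
  scene <- ar_scene(phantom$organs, phantom$templates, scope)
  thetas <- config$theta_schedule
  joint_M <- c(0, 0, 60)

  ref_gt <- session_ground_truth(phantom, geom, 0, joint_M,
                                 distance_mm = config$working_distance_mm)
  reference <- list(head = ref_gt$T_sA, cyl = ref_gt$T_sL)

  frames <- vector("list", length(thetas))
  pose_rows <- list()
  theta_rows <- list()
  logmsg <- character(0)
  for (k in seq_along(thetas)) {
    gt <- session_ground_truth(phantom, geom, thetas[k], joint_M,
                               distance_mm = config$working_distance_mm)
    est <- tryCatch({
      obs <- function(nm, pose, j) {
        estimate_pose(scene$templates[[nm]],
                      observe_marker(rig, scene$templates[[nm]], pose,
                                     config$noise_sigma_px,
                                     seed = derive_seed(seed, k, j)),
                      frame_index = k)
      }
      list(base = obs(scene$base_marker, gt$T_sM, 1L),
           head = obs(scene$head_marker, gt$T_sA, 2L),
           cyl = obs(scene$cylinder_marker, gt$T_sL, 3L))
    }, scopesight_error = function(e) e)
    if (inherits(est, "error")) {
      logmsg <- c(logmsg, sprintf("frame %d skipped: %s", k, conditionMessage(est)))
      next
    }
    th <- estimate_cylinder_angle(est$head, est$cyl, reference, geom)
    T_MC <- model_to_camera(est$base, est$head, geom, th$angle_deg)
    frames[[k]] <- render_overlay(scene, T_MC, frame_index = k)
    frames[[k]]$chain <- T_MC
    pose_rows <- c(pose_rows, list(est$base, est$head, est$cyl))
    theta_rows[[k]] <- data.frame(frame = k, theta_commanded = thetas[k],
                                  theta_estimated = th$angle_deg)
  }
  structure(list(frames = Filter(Negate(is.null), frames),
                 pose_log = pose_rows,
                 theta_log = do.call(rbind, theta_rows),
                 log = logmsg, scene = scene, rig = rig,
                 phantom = phantom, config = config, seed = seed),
            class = "ar_session")
}

#' @export
print.ar_session <- function(x, ...) {
  cat(sprintf("<ar_session: %d frames rendered, %d skipped, noise %.2f px>\n",
              length(x$frames), length(x$log), x$config$noise_sigma_px))
  if (!is.null(x$theta_log)) {
    err <- abs(x$theta_log$theta_estimated - x$theta_log$theta_commanded)
    cat(sprintf("  cylinder-angle error: mean %.4f deg, max %.4f deg\n",
                mean(err), max(err)))
  }
  invisible(x)
}

#' Session configuration
#'
#' @param n_frames number of frames; @param theta_schedule commanded
#'   cylinder angles per frame (degrees), default a sweep -40..40.
#' @param noise_sigma_px tracker pixel noise sd.
#' @param working_distance_mm scope-tip-to-target distance.
#' @param phantom_seed seed for the built-in phantom.
#' @param phantom,scope,rig optional pre-built objects overriding defaults.
#' @return config list of class `session_config`.
#' @export
session_config <- function(n_frames = 9L,
                           theta_schedule = seq(-40, 40, length.out = n_frames),
                           noise_sigma_px = 0,
                           working_distance_mm = 40,
                           phantom_seed = 1L,
                           phantom = NULL, scope = NULL, rig = NULL) {
  structure(list(n_frames = as.integer(n_frames),
                 theta_schedule = as.numeric(theta_schedule),
                 noise_sigma_px = noise_sigma_px,
                 working_distance_mm = working_distance_mm,
                 phantom_seed = as.integer(phantom_seed),
                 phantom = phantom, scope = scope, rig = rig),
            class = "session_config")
}

validate_session_config <- function(config) {
  if (!inherits(config, "session_config")) {
    required <- c("n_frames", "theta_schedule", "noise_sigma_px")
    miss <- setdiff(required, names(config))
    if (length(miss))
      stop_ss("config_error", "session config missing keys: %s",
              paste(miss, collapse = ", "))
    config <- do.call(session_config, config[intersect(names(config),
                                                       names(formals(session_config)))])
  }
  if (config$noise_sigma_px < 0)
    stop_ss("config_error", "noise_sigma_px must be >= 0")
  if (length(config$theta_schedule) != config$n_frames)
    stop_ss("config_error", "theta_schedule length != n_frames")
  config
}

#' Read a session configuration from YAML
#'
#' Recognized keys: `n_frames`, `theta_start`, `theta_end` (or an explicit
#' `theta_schedule`), `noise_sigma_px`, `working_distance_mm`,
#' `phantom_seed`, `calibration` (path to a calibration JSON).
#'
#' @param path YAML file path.
#' @return a `session_config`.
#' @export
read_session_config <- function(path) {
  y <- yaml::read_yaml(path)
  n <- as.integer(y$n_frames %||% 9L)
  sched <- y$theta_schedule %||%
    seq(y$theta_start %||% -40, y$theta_end %||% 40, length.out = n)
  scope <- if (!is.null(y$calibration))
    read_calibration_json(file.path(dirname(path), y$calibration)) else NULL
  session_config(n_frames = n, theta_schedule = sched,
                 noise_sigma_px = y$noise_sigma_px %||% 0,
                 working_distance_mm = y$working_distance_mm %||% 40,
                 phantom_seed = y$phantom_seed %||% 1L,
                 scope = scope)
}

#' Write session outputs
#'
#' Numbered PGM frames, `poses.csv` and `session.log` into a directory.
#' Output bytes are identical for identical `(config, seed)`.
#'
#' @param session an `ar_session`; @param dir output directory.
#' @param write_rasters write composited PGM frames (default TRUE).
#' @export
write_session_outputs <- function(session, dir, write_rasters = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pose_csv(session$pose_log, file.path(dir, "poses.csv"))
  con <- file(file.path(dir, "session.log"), "wb")
  writeLines(c(sprintf("frames rendered: %d", length(session$frames)),
               session$log), con, sep = "\n")
  close(con)
  if (!is.null(session$theta_log))
    utils::write.csv(format(session$theta_log, digits = 17),
                     file.path(dir, "theta.csv"), row.names = FALSE, quote = FALSE)
  if (write_rasters)
    for (f in session$frames)
      write_pgm(f$composited, file.path(dir, sprintf("frame_%03d.pgm", f$frame_index)))
  invisible(dir)
}
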