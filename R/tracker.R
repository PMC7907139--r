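#' Simulated stereo optical pose tracker
#'
#' Stands in for a hardware optical tracker: a stereo pair of pinhole
#' cameras observes the "Xpoint" fiducials of named marker templates,
#' triangulates them into the sensor frame `S`, and estimates each marker's
#' rigid pose by absolute orientation. Image-level Xpoint detection is not
#' simulated; Xpoints enter as exact projections plus isotropic Gaussian
#' pixel noise.
#'
#' @name tracker
NULL

#' Pinhole camera for the stereo rig
#'
#' @param fx,fy focal lengths (px); @param cx,cy principal point (px);
#' @param width,height image size (px); @param pose `rigid_transform`
#'   mapping camera coordinates to the sensor frame `S`.
#' @return list of class `pinhole_camera`.
#' @export
pinhole_camera <- function(fx = 1000, fy = 1000, cx = (1280 - 1) / 2, cy = (960 - 1) / 2,
                           width = 1280, height = 960,
                           pose = rigid_transform(from = "cam", to = "S")) {
  stopifnot(fx > 0, fy > 0, is_rigid_transform(pose))
  if (cx < 0 || cx > width - 1 || cy < 0 || cy > height - 1)
    stop_ss("invalid_camera_error", "principal point outside image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height, pose = pose),
            class = "pinhole_camera")
}

project_pinhole <- function(cam, p_sensor) {
  p <- transform_points(invert(cam$pose), point_set(p_sensor, frame = "S"))
  p <- matrix(p, ncol = 3)
  if (any(p[, 3] <= 0))
    stop_ss("visibility_error", "point behind camera (index %s)",
            paste(which(p[, 3] <= 0), collapse = ", "))
  cbind(cam$fx * p[, 1] / p[, 3] + cam$cx,
        cam$fy * p[, 2] / p[, 3] + cam$cy)
}

#' Stereo rig for the simulated tracker
#'
#' Default: two identical pinhole cameras (f = 1000 px, 1280 x 960),
#' 120 mm baseline along sensor x, each converged 5 degrees inward
#' (10 degrees total vergence), looking along sensor +z.
#'
#' @param baseline_mm stereo baseline (mm).
#' @param vergence_deg total convergence angle between the optical axes.
#' @param fx,fy,cx,cy,width,height shared pinhole intrinsics.
#' @return list of class `stereo_rig` with elements `left`, `right`.
#' @export
stereo_rig <- function(baseline_mm = 120, vergence_deg = 10,
                       fx = 1000, fy = 1000,
                       cx = (1280 - 1) / 2, cy = (960 - 1) / 2,
                       width = 1280, height = 960) {
  stopifnot(baseline_mm > 0)
  half <- vergence_deg / 2
  mk <- function(x_off, toe_deg) {
    rot <- rotation_about_axis(c(0, 1, 0), toe_deg, from = "cam", to = "S")
    pose <- rigid_transform(rot$R, c(x_off, 0, 0), from = "cam", to = "S")
    pinhole_camera(fx, fy, cx, cy, width, height, pose = pose)
  }
  structure(list(left = mk(-baseline_mm / 2, -half),
                 right = mk(baseline_mm / 2, half),
                 baseline_mm = baseline_mm),
            class = "stereo_rig")
}

#' Triangulate a stereo pixel pair into the sensor frame
#'
#' Back-projects both pixels into rays and returns the midpoint of the
#' shortest segment between them.
#'
#' @param rig a `stereo_rig`.
#' @param left_px,right_px pixel coordinates, numeric length 2.
#' @return 3-vector in the sensor frame `S` (mm).
#' @export
triangulate <- function(rig, left_px, right_px) {
  ray <- function(cam, px) {
    d_cam <- unit_vector(c((px[1] - cam$cx) / cam$fx, (px[2] - cam$cy) / cam$fy, 1))
    list(origin = cam$pose$t, dir = as.numeric(cam$pose$R %*% d_cam))
  }
  r1 <- ray(rig$left, left_px); r2 <- ray(rig$right, right_px)
  cosang <- abs(sum(r1$dir * r2$dir))
  if (acos(min(1, cosang)) < deg2rad(0.1))
    stop_ss("degenerate_triangulation_error",
            "rays nearly parallel (angle %.4f deg)", rad2deg(acos(min(1, cosang))))
  # closest points on the two lines: solve 2x2 normal equations
  w0 <- r1$origin - r2$origin
  a <- 1; b <- sum(r1$dir * r2$dir); c <- 1
  d <- sum(r1$dir * w0); e <- sum(r2$dir * w0)
  denom <- a * c - b * b
  s <- (b * e - c * d) / denom
  t <- (a * e - b * d) / denom
  (r1$origin + s * r1$dir + r2$origin + t * r2$dir) / 2
}

#' Marker templates and the run-time template database
#'
#' A marker template is a named rigid constellation of at least four
#' Xpoint fiducials given in the marker-local frame (mm). The database
#' maps unique names to templates and can be extended at run time.
#'
#' @param name template name (unique within a database).
#' @param xpoints N x 3 matrix, N >= 4, marker-local coordinates (mm);
#'   points must be non-collinear with pairwise distances >= 1 mm.
#' @return `marker_template`: list with `name`, `xpoints`.
#' @export
marker_template <- function(name, xpoints) {
  xpoints <- matrix(as.numeric(xpoints), ncol = 3)
  if (nrow(xpoints) < 4L)
    stop_ss("degenerate_geometry_error", "template '%s' needs >= 4 xpoints", name)
  dmat <- as.matrix(stats::dist(xpoints))
  if (min(dmat[upper.tri(dmat)]) < 1)
    stop_ss("degenerate_geometry_error",
            "template '%s' has xpoints closer than 1 mm", name)
  sv <- svd(sweep(xpoints, 2, colMeans(xpoints)))$d
  if (sv[2] <= sv[1] * 1e-9)
    stop_ss("degenerate_geometry_error", "template '%s' xpoints are collinear", name)
  structure(list(name = as.character(name), xpoints = xpoints),
            class = "marker_template")
}

#' @rdname marker_template
#' @param templates optional list of `marker_template`s to seed the database.
#' @return `template_database`: named list of templates.
#' @export
template_database <- function(templates = list()) {
  db <- structure(list(), class = "template_database")
  for (tp in templates) db <- add_template(db, tp$name, tp$xpoints)
  db
}

#' @rdname marker_template
#' @param db a `template_database`.
#' @export
add_template <- function(db, name, xpoints) {
  stopifnot(inherits(db, "template_database"))
  if (name %in% names(db))
    stop_ss("duplicate_name_error", "template '%s' already in database", name)
  tp <- marker_template(name, xpoints)
  db[[tp$name]] <- tp
  class(db) <- "template_database"
  db
}

#' Observe a marker through the stereo rig
#'
#' Transforms the template's Xpoints by the marker's true pose, projects
#' them into both cameras, perturbs each projection with i.i.d. Gaussian
#' pixel noise, and triangulates back into the sensor frame. Deterministic
#' under a fixed seed.
#'
#' @param rig a `stereo_rig`.
#' @param template a `marker_template`.
#' @param true_pose `rigid_transform` marker-local -> sensor frame `S`.
#' @param noise_sigma_px pixel noise standard deviation (px), >= 0.
#' @param seed RNG seed; required when `noise_sigma_px > 0`.
#' @return `point_set` of triangulated Xpoints in frame `S`.
#' @export
observe_marker <- function(rig, template, true_pose, noise_sigma_px = 0, seed = NULL) {
  stopifnot(noise_sigma_px >= 0)
  if (noise_sigma_px > 0 && is.null(seed))
    stop_ss("config_error", "a seed is required when noise_sigma_px > 0")
  pts_s <- transform_points(true_pose, point_set(template$xpoints, frame = true_pose$from))
  lp <- project_pinhole(rig$left, pts_s)
  rp <- project_pinhole(rig$right, pts_s)
  if (noise_sigma_px > 0) {
    n <- nrow(lp)
    noise <- with_seed(seed, matrix(stats::rnorm(4 * n, sd = noise_sigma_px), n, 4))
    lp <- lp + noise[, 1:2, drop = FALSE]
    rp <- rp + noise[, 3:4, drop = FALSE]
  }
  out <- t(vapply(seq_len(nrow(lp)),
                  function(i) triangulate(rig, lp[i, ], rp[i, ]),
                  numeric(3)))
  point_set(out, frame = "S")
}

#' Estimate a marker pose from triangulated Xpoints
#'
#' Correspondence is by index: `observed` row i matches template Xpoint i.
#'
#' @param template a `marker_template`.
#' @param observed `point_set` in sensor frame `S`, same size as the template.
#' @return `tracked_pose`: list with `name`, `transform` (marker-local -> S),
#'   `rms_residual` (mm) and `frame_index`.
#' @param frame_index optional integer tag for pose logs.
#' @export
estimate_pose <- function(template, observed, frame_index = NA_integer_) {
  if (nrow(template$xpoints) != nrow(observed))
    stop_ss("degenerate_geometry_error",
            "observed %d points for template '%s' with %d xpoints",
            nrow(observed), template$name, nrow(template$xpoints))
  fit <- absolute_orientation(template$xpoints, observed,
                              src_frame = template$name, dst_frame = "S")
  structure(list(name = template$name, transform = fit$transform,
                 rms_residual = fit$rms_residual, frame_index = frame_index),
            class = "tracked_pose")
}

#' Identify which template produced an observation
#'
#' Fits every template with a matching point count and returns the one
#' with the smallest rms pose residual; ties break lexicographically by
#' name. Rejects with a `no_match_error` when the best residual exceeds
#' the acceptance threshold.
#'
#' @param db a `template_database`.
#' @param observed `point_set` of triangulated Xpoints in frame `S`.
#' @param threshold_mm acceptance threshold on the rms residual (default 1 mm).
#' @return list with `name` and `pose` (a `tracked_pose`).
#' @export
identify_template <- function(db, observed, threshold_mm = 1.0) {
  if (length(db) == 0L) stop_ss("empty_database_error", "template database is empty")
  cand <- Filter(function(tp) nrow(tp$xpoints) == nrow(observed), db)
  if (length(cand) == 0L)
    stop_ss("no_match_error", "no template with %d xpoints", nrow(observed))
  fits <- lapply(cand, function(tp) tryCatch(estimate_pose(tp, observed),
                                             scopesight_error = function(e) NULL))
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  if (length(fits) == 0L) stop_ss("no_match_error", "no template fits the observation")
  resid <- vapply(fits, function(f) f$rms_residual, numeric(1))
  ord <- order(resid, names(fits))
  best <- fits[[ord[1]]]
  if (best$rms_residual > threshold_mm)
    stop_ss("no_match_error",
            "best residual %.3f mm exceeds acceptance threshold %.3f mm",
            best$rms_residual, threshold_mm)
  list(name = best$name, pose = best)
}

#' Write a tracked-pose stream as CSV
#'
#' Columns: frame, name, the 4x4 homogeneous matrix row-major (m00..m33),
#' residual_mm. Byte-deterministic for a given pose list.
#'
#' @param poses list of `tracked_pose`.
#' @param path output CSV path.
#' @export
write_pose_csv <- function(poses, path) {
  rows <- lapply(poses, function(p) {
    m <- as_homogeneous(p$transform)
    c(frame = p$frame_index, name = p$name,
      stats::setNames(sprintf("%.17g", as.vector(t(m))),
                      paste0("m", rep(0:3, each = 4), rep(0:3, 4))),
      residual_mm = sprintf("%.17g", p$rms_residual))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write marker template JSON
#'
#' Layout: `{"name": ..., "xpoints": [[x,y,z], ...]}` in mm.
#' @param template a `marker_template`; @param path file path.
#' @export
write_template_json <- function(template, path) {
  jsonlite::write_json(list(name = template$name,
                            xpoints = unname(template$xpoints)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template_json
#' @export
read_template_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_template(x$name, x$xpoints)
}
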