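#' Mesh primitives for the synthetic phantom
#'
#' Axis-aligned box, capped cylinder, and a tube swept along a smooth 3D
#' curve (used for nerves). All dimensions in mm; faces wound outward.
#'
#' @name phantom_primitives
NULL

#' @rdname phantom_primitives
#' @param dx,dy,dz box edge lengths (mm), centered on the origin.
#' @export
box_mesh <- function(dx, dy, dz) {
  stopifnot(dx > 0, dy > 0, dz > 0)
  s <- c(dx, dy, dz) / 2
  v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  v <- sweep(v, 2, s, `*`)
  # two triangles per face, outward winding
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),       # z = -1
    c(5, 6, 7), c(6, 8, 7),       # z = +1
    c(1, 2, 5), c(2, 6, 5),       # y = -1
    c(3, 7, 4), c(4, 7, 8),       # y = +1
    c(1, 5, 3), c(3, 5, 7),       # x = -1
    c(2, 4, 6), c(4, 8, 6)        # x = +1
  )
  triangle_mesh(v, f)
}

#' @rdname phantom_primitives
#' @param radius,length cylinder radius and length (mm); axis along z,
#'   centered on the origin.
#' @param n_seg segments around the circumference.
#' @export
cylinder_mesh <- function(radius, length, n_seg = 24L) {
  stopifnot(radius > 0, length > 0, n_seg >= 3L)
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  ring <- cbind(radius * cos(ang), radius * sin(ang))
  v <- rbind(cbind(ring, -length / 2), cbind(ring, length / 2),
             c(0, 0, -length / 2), c(0, 0, length / 2))
  bot <- seq_len(n_seg); top <- n_seg + bot
  cb <- 2 * n_seg + 1L; ct <- 2 * n_seg + 2L
  nxt <- c(2:n_seg, 1L)
  f <- rbind(
    cbind(bot, top, bot[nxt]),          # side lower triangles
    cbind(bot[nxt], top, top[nxt]),     # side upper triangles
    cbind(cb, bot, bot[nxt]),           # bottom cap (normal -z)
    cbind(ct, top[nxt], top)            # top cap (normal +z)
  )
  triangle_mesh(v, f)
}

#' @rdname phantom_primitives
#' @param control K x 3 control points of a smooth open curve (mm); the
#'   tube follows the natural-spline interpolation of the controls.
#' @param radius tube radius (mm).
#' @param n_along samples along the curve; @param n_around around it.
#' @export
tube_mesh <- function(control, radius, n_along = 40L, n_around = 12L) {
  control <- matrix(as.numeric(control), ncol = 3)
  stopifnot(nrow(control) >= 3L, radius > 0, n_along >= 2L, n_around >= 3L)
  s <- seq(0, 1, length.out = nrow(control))
  u <- seq(0, 1, length.out = n_along)
  curve <- cbind(stats::spline(s, control[, 1], xout = u)$y,
                 stats::spline(s, control[, 2], xout = u)$y,
                 stats::spline(s, control[, 3], xout = u)$y)
  # parallel-transport frames along the curve
  tang <- rbind(curve[2, ] - curve[1, ],
                (curve[3:n_along, , drop = FALSE] -
                   curve[1:(n_along - 2), , drop = FALSE]) / 2,
                curve[n_along, ] - curve[n_along - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- perp_vector(tang[1, ])
  ang <- 2 * pi * (seq_len(n_around) - 1) / n_around
  rings <- vector("list", n_along)
  for (i in seq_len(n_along)) {
    if (i > 1) {  # transport the normal to stay perpendicular to the tangent
      nrm <- nrm - sum(nrm * tang[i, ]) * tang[i, ]
      nrm <- unit_vector(nrm)
    }
    bin <- c(tang[i, 2] * nrm[3] - tang[i, 3] * nrm[2],
             tang[i, 3] * nrm[1] - tang[i, 1] * nrm[3],
             tang[i, 1] * nrm[2] - tang[i, 2] * nrm[1])
    rings[[i]] <- radius * (outer(cos(ang), nrm) + outer(sin(ang), bin)) +
      matrix(curve[i, ], n_around, 3, byrow = TRUE)
  }
  v <- do.call(rbind, rings)
  v <- rbind(v, curve[1, ], curve[n_along, ])
  c0 <- n_along * n_around + 1L; c1 <- c0 + 1L
  nxt <- c(2:n_around, 1L)
  f <- list()
  for (i in seq_len(n_along - 1L)) {
    a <- (i - 1L) * n_around + seq_len(n_around)
    b <- i * n_around + seq_len(n_around)
    f[[i]] <- rbind(cbind(a, b, a[nxt]), cbind(a[nxt], b, b[nxt]))
  }
  first <- seq_len(n_around)
  last <- (n_along - 1L) * n_around + seq_len(n_around)
  f[[n_along]] <- rbind(cbind(c0, first, first[nxt]), cbind(c1, last[nxt], last))
  triangle_mesh(v, do.call(rbind, f))
}

#' Phantom specification
#'
#' Geometry of the synthetic elbow phantom: three bone cylinders (humerus,
#' radius, ulna) meeting near a joint point, four thin nerve tubes running
#' past the joint, a skin cylinder enclosing them, and a mounting frame
#' block, all rigidly arranged over a base plate carrying the tracking
#' marker. Dimensions default to adult-elbow scale.
#'
#' @param seed RNG seed for the small deterministic shape jitter.
#' @param bone_radius_mm radii of humerus, radius, ulna (length 3).
#' @param bone_length_mm bone cylinder lengths (length 3).
#' @param nerve_radius_mm nerve tube radius (about 2 mm at the elbow).
#' @param skin_radius_mm,skin_length_mm skin cylinder dimensions.
#' @param frame_dims_mm mounting-frame block `c(dx, dy, dz)`.
#' @param marker_size_mm side lengths of the base / head / cylinder marker
#'   squares (length 3; distinct so templates are distinguishable).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         bone_radius_mm = c(12, 7, 8),
                         bone_length_mm = c(90, 80, 80),
                         nerve_radius_mm = 2,
                         skin_radius_mm = 45, skin_length_mm = 160,
                         frame_dims_mm = c(70, 70, 12),
                         marker_size_mm = c(60, 34, 26)) {
  vals <- c(bone_radius_mm, bone_length_mm, nerve_radius_mm,
            skin_radius_mm, skin_length_mm, frame_dims_mm, marker_size_mm)
  if (any(vals <= 0)) stop_ss("config_error", "all phantom dimensions must be positive")
  if (length(marker_size_mm) != 3L)
    stop_ss("config_error", "marker_size_mm must give base, head, cylinder sizes")
  structure(list(seed = as.integer(seed),
                 bone_radius_mm = bone_radius_mm, bone_length_mm = bone_length_mm,
                 nerve_radius_mm = nerve_radius_mm,
                 skin_radius_mm = skin_radius_mm, skin_length_mm = skin_length_mm,
                 frame_dims_mm = frame_dims_mm, marker_size_mm = marker_size_mm),
            class = "phantom_spec")
}

marker_square <- function(side) {
  s <- side / 2
  rbind(c(-s, -s, 0), c(s, -s, 0), c(s, 0.8 * s, 0), c(-0.6 * s, s, 0))
}

#' Generate the synthetic phantom
#'
#' Builds the organ meshes, the three marker templates (base plate, scope
#' head, lens cylinder) and the ground-truth static arrangement. Byte
#' deterministic under the spec seed.
#'
#' @param spec a `phantom_spec`.
#' @return list of class `phantom`: `organs` (list of `organ_model`),
#'   `templates` (a `template_database` with entries `base`, `head`,
#'   `cylinder`), `spec`, and `T_sM` (default ground-truth pose of the
#'   model base in the sensor frame).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    joint <- c(0, 0, 60)   # elbow joint center above the base plate (mm)
    place <- function(name, mesh, R = diag(3), t = c(0, 0, 0)) {
      # T_MO maps model-base coordinates to organ-local ones
      organ_model(name, mesh,
                  invert(rigid_transform(R, t, from = name, to = "M")))
    }
    tilt <- function(axis, deg) rotation_matrix_about(axis, deg)
    organs <- list(
      place("frame", box_mesh(spec$frame_dims_mm[1], spec$frame_dims_mm[2],
                              spec$frame_dims_mm[3]),
            t = c(0, 0, spec$frame_dims_mm[3] / 2)),
      place("humerus", cylinder_mesh(spec$bone_radius_mm[1], spec$bone_length_mm[1]),
            R = tilt(c(1, 0, 0), -90),
            t = joint + c(0, spec$bone_length_mm[1] / 2 + 6, 0)),
      place("radius", cylinder_mesh(spec$bone_radius_mm[2], spec$bone_length_mm[2]),
            R = tilt(c(1, 0, 0), 90) %*% tilt(c(0, 0, 1), 8),
            t = joint + c(-9, -spec$bone_length_mm[2] / 2 - 5, 2)),
      place("ulna", cylinder_mesh(spec$bone_radius_mm[3], spec$bone_length_mm[3]),
            R = tilt(c(1, 0, 0), 90) %*% tilt(c(0, 0, 1), -6),
            t = joint + c(9, -spec$bone_length_mm[3] / 2 - 4, 1)),
      place("skin", cylinder_mesh(spec$skin_radius_mm, spec$skin_length_mm, n_seg = 32L),
            R = tilt(c(1, 0, 0), 90), t = joint)
    )
    nerve_names <- c("radial nerve", "ulnar nerve", "median nerve",
                     "musculocutaneous nerve")
    sides <- list(c(-22, 0), c(26, 4), c(-4, -24), c(-14, 14))
    for (i in seq_along(nerve_names)) {
      off <- sides[[i]]
      jitter <- matrix(stats::runif(15, -2, 2), 5, 3)
      ctrl <- cbind(off[1] + c(0, 2, 4, 2, 0),
                    c(-70, -35, 0, 35, 70),
                    60 + off[2] + c(0, -3, -6, -3, 0)) + jitter
      organs[[length(organs) + 1L]] <-
        place(nerve_names[i], tube_mesh(ctrl, spec$nerve_radius_mm), t = c(0, 0, 0))
    }
    templates <- template_database(list(
      marker_template("base", marker_square(spec$marker_size_mm[1])),
      marker_template("head", marker_square(spec$marker_size_mm[2])),
      marker_template("cylinder", marker_square(spec$marker_size_mm[3]))
    ))
    # model base sits ~800 mm in front of the tracker, tilted toward it
    T_sM <- rigid_transform(rotation_matrix_about(c(1, 0, 0), 160),
                            c(0, 40, 820), from = "M", to = "S")
    structure(list(organs = organs, templates = templates,
                   spec = spec, T_sM = T_sM),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %d organs, %d marker templates, seed %d>\n",
              length(x$organs), length(x$templates), x$spec$seed))
  for (o in x$organs)
    cat(sprintf("  %-24s %5d vertices\n", o$name, nrow(o$mesh$vertices)))
  invisible(x)
}

# Max/min distance of tube-mesh side vertices from a densely sampled
# centerline; used to validate nerve geometry.
tube_radius_range <- function(mesh, control, n_dense = 400L) {
  control <- matrix(as.numeric(control), ncol = 3)
  s <- seq(0, 1, length.out = nrow(control))
  u <- seq(0, 1, length.out = n_dense)
  curve <- cbind(stats::spline(s, control[, 1], xout = u)$y,
                 stats::spline(s, control[, 2], xout = u)$y,
                 stats::spline(s, control[, 3], xout = u)$y)
  v <- mesh$vertices
  d <- vapply(seq_len(nrow(v)), function(i) {
    min(sqrt(colSums((t(curve) - v[i, ])^2)))
  }, numeric(1))
  range(d[d > 1e-9])   # drop the two cap-center vertices on the curve
}
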