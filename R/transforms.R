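#' Rigid transforms between named coordinate frames
#'
#' A `rigid_transform` carries a 3x3 rotation matrix `R`, a translation
#' 3-vector `t` (mm) and the labels of the frames it maps between: a point
#' `p` expressed in `from` coordinates maps to `R %*% p + t` in `to`
#' coordinates. Frame labels are checked whenever transforms are chained,
#' which catches the classic navigation bug of composing transforms in the
#' wrong order.
#'
#' @param R 3x3 orthonormal rotation matrix with determinant +1.
#' @param t translation, numeric length 3, millimetres.
#' @param from,to frame labels (character scalars), e.g. `"M"` for the model
#'   base, `"S"` for the tracker sensor, `"A"` for the scope-head marker,
#'   `"T"` for the scope tip, `"C"` for the camera sight.
#' @param tol orthonormality tolerance for validation.
#' @return an object of class `rigid_transform`.
#' @examples
#' t1 <- rotation_about_axis(c(0, 0, 1), 90, from = "a", to = "b")
#' t2 <- rigid_transform(diag(3), c(1, 0, 0), from = "b", to = "c")
#' compose(t2, t1)
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), from = "world", to = "world",
                            tol = 1e-8) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3L)
  if (!all(is.finite(R)) || !all(is.finite(t)))
    stop_ss("invalid_transform_error", "non-finite rotation or translation")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop_ss("invalid_transform_error",
            "rotation is not orthonormal (max deviation %.3g)",
            max(abs(crossprod(R) - diag(3))))
  if (abs(det(R) - 1) > tol)
    stop_ss("invalid_transform_error", "rotation determinant is %.6f, not +1", det(R))
  structure(list(R = R, t = t, from = as.character(from), to = as.character(to)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$from, x$to))
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(c("x", "y", "z"), c("R1", "R2", "R3", "t(mm)"))
  print(round(m, 6))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Compose two rigid transforms
#'
#' `compose(a, b)` is the transform "first `b`, then `a`": it maps
#' `b$from` coordinates to `a$to` coordinates. Frame labels must chain
#' (`b$to == a$from`).
#'
#' @param a,b rigid transforms.
#' @return a `rigid_transform` from `b$from` to `a$to`.
#' @export
compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  if (!identical(b$to, a$from))
    stop_ss("frame_mismatch_error",
            "cannot compose: inner transform ends in frame '%s' but outer starts in '%s'",
            b$to, a$from)
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, from = b$from, to = a$to)
}

#' Invert a rigid transform
#'
#' @param t a rigid transform.
#' @return the transform mapping `t$to` back to `t$from`.
#' @export
invert <- function(t) {
  stopifnot(is_rigid_transform(t))
  Rt <- t(t$R)
  rigid_transform(Rt, as.numeric(-Rt %*% t$t), from = t$to, to = t$from)
}

#' Point sets with a frame label
#'
#' @param points numeric N x 3 matrix (mm); row order is identity-bearing
#'   (row i corresponds across paired sets).
#' @param frame frame label.
#' @return an N x 3 matrix of class `point_set` with a `frame` attribute.
#' @export
point_set <- function(points, frame = "world") {
  m <- matrix(as.numeric(points), ncol = 3)
  if (!all(is.finite(m))) stop_ss("invalid_point_error", "non-finite point coordinates")
  structure(m, frame = as.character(frame), class = c("point_set", class(m)))
}

point_frame <- function(pts) attr(pts, "frame") %||% "world"

#' Apply a rigid transform to a point set
#'
#' @param t a rigid transform.
#' @param pts a `point_set` (or bare N x 3 matrix, taken to be in `t$from`).
#' @return a `point_set` in frame `t$to`.
#' @export
transform_points <- function(t, pts) {
  stopifnot(is_rigid_transform(t))
  if (inherits(pts, "point_set") && !identical(point_frame(pts), t$from))
    stop_ss("frame_mismatch_error",
            "points are in frame '%s' but transform starts from '%s'",
            point_frame(pts), t$from)
  m <- matrix(as.numeric(pts), ncol = 3)
  point_set(sweep(m %*% t(t$R), 2, t$t, `+`), frame = t$to)
}

#' Rotation about an axis (Rodrigues)
#'
#' @param axis unit 3-vector.
#' @param angle_deg rotation angle in degrees (angles are degrees at every
#'   interface of this package; radians are internal).
#' @param from,to frame labels for the resulting transform.
#' @return a `rigid_transform` with zero translation.
#' @export
rotation_about_axis <- function(axis, angle_deg, from = "world", to = "world") {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop_ss("degenerate_geometry_error", "axis must be a unit vector")
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, c(0, 0, 0), from = from, to = to)
}

rotation_matrix_about <- function(axis, angle_deg) {
  rotation_about_axis(axis, angle_deg)$R
}

# Axis-angle decomposition of a rotation matrix. Returns angle in degrees
# (>= 0) and a unit axis; the axis is arbitrary for the identity.
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cos_th <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(cos_th)
  if (th < 1e-12) return(list(angle_deg = 0, axis = c(0, 0, 1)))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  sn <- sqrt(sum(v^2))
  if (sn < 1e-12) {
    # angle near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- unit_vector(sqrt(pmax(diag(B), 0)) *
                          sign(c(1, B[1, 2] + 1e-300, B[1, 3] + 1e-300)))
    return(list(angle_deg = rad2deg(th), axis = axis))
  }
  list(angle_deg = rad2deg(th), axis = v / sn)
}

#' Least-squares rigid fit between paired point sets (absolute orientation)
#'
#' Closed-form SVD (Kabsch) solution of the orthogonal Procrustes problem
#' with a reflection guard: returns the rigid transform minimizing
#' `sum ||dst_i - (R src_i + t)||^2` over rotations with det = +1.
#'
#' @param src,dst paired point sets, N x 3, N >= 3, matched by row index.
#'   `src` must not be collinear. Planar sets are fine.
#' @param src_frame,dst_frame frame labels for the returned transform;
#'   default to the point-set frames when given `point_set` inputs.
#' @return list with `transform` (a `rigid_transform`) and `rms_residual`
#'   (root-mean-square fit residual, mm).
#' @export
absolute_orientation <- function(src, dst, src_frame = NULL, dst_frame = NULL) {
  src_frame <- src_frame %||% if (inherits(src, "point_set")) point_frame(src) else "world"
  dst_frame <- dst_frame %||% if (inherits(dst, "point_set")) point_frame(dst) else "world"
  S <- matrix(as.numeric(src), ncol = 3)
  D <- matrix(as.numeric(dst), ncol = 3)
  n <- nrow(S)
  if (n != nrow(D)) stop_ss("degenerate_geometry_error", "point sets differ in size")
  if (n < 3L) stop_ss("degenerate_geometry_error", "need at least 3 point pairs, got %d", n)
  sc <- colMeans(S); dc <- colMeans(D)
  Sc <- sweep(S, 2, sc); Dc <- sweep(D, 2, dc)
  sv <- svd(Sc)$d
  if (sv[2] <= max(sv[1] * 1e-10, 1e-12))
    stop_ss("degenerate_geometry_error", "source points are collinear")
  H <- t(Sc) %*% Dc
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  t <- dc - as.numeric(R %*% sc)
  res <- Dc - Sc %*% t(R)
  list(
    transform = rigid_transform(R, t, from = src_frame, to = dst_frame),
    rms_residual = sqrt(mean(rowSums(res^2)))
  )
}

#' Serialize / read a rigid transform as a 4x4 homogeneous matrix
#'
#' The JSON layout is `{"from": ..., "to": ..., "matrix": [[...], ...]}` with
#' the 4x4 row-major homogeneous matrix. The reader validates orthonormality.
#'
#' @param t a rigid transform.
#' @return `as_homogeneous`: a 4x4 matrix.
#' @export
as_homogeneous <- function(t) {
  stopifnot(is_rigid_transform(t))
  rbind(cbind(t$R, t$t), c(0, 0, 0, 1))
}

#' @rdname as_homogeneous
#' @param m a 4x4 homogeneous matrix with last row (0,0,0,1).
#' @param from,to frame labels.
#' @export
from_homogeneous <- function(m, from = "world", to = "world") {
  m <- matrix(as.numeric(m), 4, 4)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop_ss("invalid_transform_error", "last row of homogeneous matrix must be (0,0,0,1)")
  rigid_transform(m[1:3, 1:3], m[1:3, 4], from = from, to = to)
}

#' @rdname as_homogeneous
#' @param path file path.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(
    list(from = t$from, to = t$to,
         matrix = unname(as_homogeneous(t))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname as_homogeneous
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_homogeneous(x$matrix, from = x$from, to = x$to)
}
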