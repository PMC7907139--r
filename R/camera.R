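#' Arthroscope camera intrinsics
#'
#' Pixel convention: 0-based, pixel centers at integer coordinates, origin
#' top-left; the image center of a `w x h` sensor is `((w-1)/2, (h-1)/2)`.
#'
#' @param fx,fy focal lengths (px), > 0.
#' @param cx,cy principal point (px), inside the image.
#' @param width,height image size (px).
#' @return list of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  if (cx < 0 || cx > width - 1 || cy < 0 || cy > height - 1)
    stop_ss("invalid_camera_error", "principal point (%.1f, %.1f) outside image", cx, cy)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' Brown-Conrady lens distortion model
#'
#' Radial polynomial `1 + k1 r^2 + k2 r^4 + k3 r^6` plus tangential terms
#' `p1, p2`, applied on normalized image coordinates. Barrel distortion of
#' a fisheye-like arthroscope lens corresponds to `k1 < 0`.
#'
#' @param k1,k2,k3 radial coefficients (dimensionless).
#' @param p1,p2 tangential coefficients (dimensionless).
#' @return list of class `distortion_model`.
#' @export
distortion_model <- function(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  structure(list(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "distortion_model")
}

#' Forward lens distortion
#'
#' @param d a `distortion_model`.
#' @param xn normalized image points, N x 2 matrix or length-2 vector.
#' @return distorted normalized points, same shape as a matrix.
#' @export
distort <- function(d, xn) {
  m <- matrix(as.numeric(xn), ncol = 2)
  x <- m[, 1]; y <- m[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
  xd <- x * radial + 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x^2)
  yd <- y * radial + d$p1 * (r2 + 2 * y^2) + 2 * d$p2 * x * y
  cbind(xd, yd, deparse.level = 0)
}

#' Reverse (inverse) lens distortion
#'
#' Damped fixed-point iteration on `x <- x - lambda * (distort(x) - xd)`
#' starting from the distorted point, the standard reverse-correction loop
#' for the Brown-Conrady model; the step length `lambda` halves whenever a
#' step fails to reduce the residual, which keeps the iteration stable well
#' outside the small-distortion regime.
#'
#' @param d a `distortion_model`.
#' @param xd distorted normalized points, N x 2 or length-2.
#' @param tol convergence tolerance on `||distort(x) - xd||` (default 1e-12).
#' @param max_iter iteration cap (default 50).
#' @return undistorted normalized points, N x 2 matrix.
#' @export
undistort <- function(d, xd, tol = 1e-12, max_iter = 50L) {
  target <- matrix(as.numeric(xd), ncol = 2)
  # fast path: plain fixed point, vectorized over all points
  x <- target
  for (i in seq_len(max_iter)) {
    err <- distort(d, x) - target
    bad <- !is.finite(err)
    if (any(bad)) { err[bad] <- 0; x[bad] <- NA_real_ }
    if (all(is.na(x) | abs(err) < tol)) break
    x <- x - err
  }
  res <- abs(distort(d, x) - target)
  done <- is.finite(res[, 1]) & is.finite(res[, 2]) &
    res[, 1] < tol & res[, 2] < tol
  if (all(done)) return(x)
  out <- x
  for (row in which(!done)) {
    tg <- target[row, ]
    # radial initialization: the radial profile r (1 + k1 r^2 + ...) is
    # monotone on any injective model, so bracket-and-bisect its inverse
    rd <- sqrt(sum(tg^2))
    radial <- function(r) r * (1 + d$k1 * r^2 + d$k2 * r^4 + d$k3 * r^6)
    hi <- max(1, 2 * rd)
    tries <- 0L
    while (is.finite(radial(hi)) && radial(hi) < rd && tries < 200L) {
      hi <- hi * 2; tries <- tries + 1L
    }
    xr <- tg
    if (rd > 0 && is.finite(radial(hi)) && radial(hi) >= rd) {
      lo <- 0
      for (i in 1:100) {
        mid <- (lo + hi) / 2
        if (radial(mid) < rd) lo <- mid else hi <- mid
      }
      xr <- tg * ((lo + hi) / 2) / rd
    }
    err <- distort(d, xr) - tg
    m <- max(abs(err))
    if (!is.finite(m)) { xr <- c(0, 0); err <- distort(d, xr) - tg; m <- max(abs(err)) }
    # far outside the unit field of view the r^5/r^7 polynomial terms limit
    # the attainable residual to their floating-point cancellation level
    tol_eff <- max(tol, .Machine$double.eps * 1e3 * max(1, rd)^5)
    lambda <- 1
    it <- 0L
    while (it < 40L * max_iter && m >= tol_eff) {
      x_new <- xr - lambda * err
      err_new <- distort(d, x_new) - tg
      m_new <- max(abs(err_new))
      if (is.finite(m_new) && m_new < m) {
        xr <- x_new; err <- err_new; m <- m_new
        lambda <- min(1, lambda * 2)
      } else {
        lambda <- lambda / 2
        if (lambda < 1e-14) break
      }
      it <- it + 1L
    }
    if (!is.finite(m) || m >= tol_eff)
      stop_ss("nonconvergence_error",
              "undistortion did not converge (residual %.3g)", m)
    out[row, ] <- xr
  }
  out
}

# Numerical injectivity check of the distortion over a normalized-radius
# disc: the distorted radius must be strictly increasing in r.
distortion_injective <- function(d, r_max = 0.75, n = 200L) {
  r <- seq(0, r_max, length.out = n)
  rd <- r * (1 + d$k1 * r^2 + d$k2 * r^4 + d$k3 * r^6)
  all(diff(rd) > 0)
}

#' Project camera-frame points to pixels
#'
#' Perspective divide, then lens distortion, then intrinsics. Pixels may
#' fall outside the image; they are flagged via the `"inside"` attribute,
#' not treated as errors.
#'
#' @param intr a `camera_intrinsics`.
#' @param d a `distortion_model`.
#' @param p_cam camera-frame points, N x 3 or length 3 (mm); depth (z) must
#'   be positive.
#' @return N x 2 pixel matrix with logical attribute `inside`.
#' @export
project_points <- function(intr, d, p_cam) {
  p <- matrix(as.numeric(p_cam), ncol = 3)
  if (any(p[, 3] <= 0))
    stop_ss("visibility_error", "non-positive depth at index %s",
            paste(which(p[, 3] <= 0), collapse = ", "))
  xn <- cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
  xd <- distort(d, xn)
  px <- cbind(intr$fx * xd[, 1] + intr$cx, intr$fy * xd[, 2] + intr$cy)
  inside <- px[, 1] >= 0 & px[, 1] <= intr$width - 1 &
    px[, 2] >= 0 & px[, 2] <= intr$height - 1
  attr(px, "inside") <- inside
  px
}

#' Back-project a pixel to a normalized, undistorted ray direction
#'
#' @param intr a `camera_intrinsics`; @param d a `distortion_model`.
#' @param px pixel coordinates, N x 2 or length 2.
#' @return N x 3 matrix of unit ray directions in the camera frame.
#' @export
backproject_pixel <- function(intr, d, px) {
  m <- matrix(as.numeric(px), ncol = 2)
  xd <- cbind((m[, 1] - intr$cx) / intr$fx, (m[, 2] - intr$cy) / intr$fy)
  xn <- undistort(d, xd)
  dirs <- cbind(xn, 1)
  dirs / sqrt(rowSums(dirs^2))
}
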