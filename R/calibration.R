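#' Planar checkerboard camera calibration
#'
#' Calibrates intrinsics and Brown-Conrady distortion from several views of
#' a planar checkerboard given as 3D-2D corner correspondence lists (corner
#' detection from pixels is out of scope; the synthetic generator provides
#' correspondences). Closed-form homography-based initialization of the
#' intrinsics, then joint nonlinear least-squares refinement of intrinsics,
#' distortion and per-view poses (Levenberg-Marquardt via
#' \code{minpack.lm::nls.lm}).
#'
#' @param views list (>= 3) of data frames with columns `X, Y, Z` (board
#'   coordinates, mm, Z = 0) and `u, v` (observed pixels); >= 20 corners
#'   per view, non-degenerate orientations.
#' @param width,height image size in pixels.
#' @param max_iter refinement iteration cap.
#' @return list of class `camera_calibration`: `intrinsics`
#'   (`camera_intrinsics`), `distortion` (`distortion_model`), `view_poses`
#'   (list of `rigid_transform`s board -> camera), `rms_px` (root-mean-square
#'   reprojection error, px), `n_views`, `n_points`.
#' @export
calibrate_camera <- function(views, width, height, max_iter = 200L) {
  if (!is.list(views) || length(views) < 3L)
    stop_ss("config_error", "calibration needs >= 3 views, got %d", length(views))
  views <- lapply(views, function(v) {
    v <- as.data.frame(v)
    stopifnot(all(c("X", "Y", "u", "v") %in% names(v)))
    if (nrow(v) < 20L)
      stop_ss("config_error", "each view needs >= 20 corners, got %d", nrow(v))
    if (!is.null(v$Z) && any(abs(v$Z) > 1e-9))
      stop_ss("config_error", "board corners must lie in the plane Z = 0")
    v
  })

  Hs <- lapply(views, function(v) homography_dlt(cbind(v$X, v$Y), cbind(v$u, v$v)))
  K0 <- zhang_intrinsics(Hs)
  if (!is.finite(K0$fx) || !is.finite(K0$fy) || K0$fx <= 0 || K0$fy <= 0)
    stop_ss("degenerate_geometry_error",
            "intrinsic initialization failed (degenerate view configuration)")
  poses0 <- lapply(Hs, function(H) pose_from_homography(H, K0))

  # parameter vector: fx fy cx cy k1 k2 k3 p1 p2, then (rvec, tvec) per view
  par0 <- c(K0$fx, K0$fy, K0$cx, K0$cy, 0, 0, 0, 0, 0,
            unlist(lapply(poses0, function(p) c(p$rvec, p$tvec))))
  obs <- do.call(rbind, lapply(views, function(v) cbind(v$u, v$v)))
  nv <- length(views)

  residual_fn <- function(par) {
    intr <- list(fx = par[1], fy = par[2], cx = par[3], cy = par[4])
    d <- distortion_model(par[5], par[6], par[7], par[8], par[9])
    out <- vector("list", nv)
    for (i in seq_len(nv)) {
      o <- 9 + (i - 1) * 6
      R <- rodrigues_to_matrix(par[o + 1:3])
      tv <- par[o + 4:6]
      P <- as.matrix(views[[i]][, c("X", "Y")])
      pc <- cbind(P, 0) %*% t(R)
      pc <- sweep(pc, 2, tv, `+`)
      xn <- cbind(pc[, 1] / pc[, 3], pc[, 2] / pc[, 3])
      xd <- distort(d, xn)
      out[[i]] <- cbind(intr$fx * xd[, 1] + intr$cx, intr$fy * xd[, 2] + intr$cy)
    }
    as.numeric(do.call(rbind, out) - obs)
  }

  fit <- minpack.lm::nls.lm(
    par = par0, fn = residual_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0, maxfev = 100000L)
  )
  par <- fit$par
  rms <- sqrt(mean(fit$fvec^2))
  poses <- lapply(seq_len(nv), function(i) {
    o <- 9 + (i - 1) * 6
    rigid_transform(rodrigues_to_matrix(par[o + 1:3]), par[o + 4:6],
                    from = "board", to = "C")
  })
  structure(list(
    intrinsics = camera_intrinsics(par[1], par[2], par[3], par[4], width, height),
    distortion = distortion_model(par[5], par[6], par[7], par[8], par[9]),
    view_poses = poses,
    rms_px = rms,
    n_views = nv,
    n_points = nrow(obs),
    niter = fit$niter
  ), class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("Camera calibration from %d views (%d corners)\n", x$n_views, x$n_points))
  cat(sprintf("  fx = %.3f  fy = %.3f  cx = %.3f  cy = %.3f px\n",
              x$intrinsics$fx, x$intrinsics$fy, x$intrinsics$cx, x$intrinsics$cy))
  d <- x$distortion
  cat(sprintf("  k1 = %.5f  k2 = %.5f  k3 = %.5f  p1 = %.5f  p2 = %.5f\n",
              d$k1, d$k2, d$k3, d$p1, d$p2))
  cat(sprintf("  rms reprojection error = %.3g px\n", x$rms_px))
  invisible(x)
}

# Normalized DLT homography from planar (X, Y) to pixels (u, v).
homography_dlt <- function(xy, uv) {
  n <- nrow(xy)
  norm_pts <- function(p) {
    c0 <- colMeans(p)
    pc <- sweep(p, 2, c0)
    s <- sqrt(2) / mean(sqrt(rowSums(pc^2)))
    Tm <- rbind(c(s, 0, -s * c0[1]), c(0, s, -s * c0[2]), c(0, 0, 1))
    list(T = Tm, p = pc * s)
  }
  a <- norm_pts(xy); b <- norm_pts(uv)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(a$p[i, ], 1); u <- b$p[i, 1]; v <- b$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A)$v[, 9]
  H <- solve(b$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% a$T
  H / H[3, 3]
}

# Zhang closed-form intrinsics from a set of plane homographies.
zhang_intrinsics <- function(Hs) {
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))
  }))
  b <- svd(V)$v[, 6]
  if (b[1] < 0) b <- -b
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  v0 <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  alpha <- sqrt(lam / B11)
  beta <- sqrt(lam * B11 / den)
  gamma <- -B12 * alpha^2 * beta / lam
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lam
  # skew discarded: the refined model is zero-skew
  list(fx = alpha, fy = beta, cx = u0, cy = v0)
}

# Pose (as Rodrigues vector + translation) of a plane from its homography.
pose_from_homography <- function(H, K) {
  Km <- rbind(c(K$fx, 0, K$cx), c(0, K$fy, K$cy), c(0, 0, 1))
  A <- solve(Km) %*% H
  lam <- 1 / sqrt(sum(A[, 1]^2))
  r1 <- lam * A[, 1]; r2 <- lam * A[, 2]; tv <- lam * A[, 3]
  if (tv[3] < 0) { r1 <- -r1; r2 <- -r2; tv <- -tv }
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  Q <- cbind(r1, r2, r3)
  dec <- svd(Q)
  R <- dec$u %*% diag(c(1, 1, sign(det(dec$u %*% t(dec$v))))) %*% t(dec$v)
  list(rvec = matrix_to_rodrigues(R), tvec = tv)
}

rodrigues_to_matrix <- function(rvec) {
  th <- sqrt(sum(rvec^2))
  if (th < 1e-14) return(diag(3))
  rotation_matrix_about(rvec / th, rad2deg(th))
}

matrix_to_rodrigues <- function(R) {
  aa <- rotation_axis_angle(R)
  deg2rad(aa$angle_deg) * aa$axis
}

#' Synthesize checkerboard calibration views
#'
#' Renders the inner corners of a planar checkerboard through a known
#' camera model from several poses, optionally adding Gaussian pixel noise;
#' the output feeds [calibrate_camera()] (and its tests) directly.
#'
#' @param intrinsics a `camera_intrinsics`; @param distortion a
#'   `distortion_model` (the ground truth to be recovered).
#' @param n_views number of views (default 10).
#' @param nx,ny inner-corner grid (default 9 x 7); @param square_mm square
#'   size (mm, default 2 -- the checkerboard used at 20 mm working distance).
#' @param noise_sigma_px Gaussian pixel noise sd (default 0).
#' @param seed RNG seed (poses and noise are deterministic under it).
#' @return list of `n_views` data frames with columns `X, Y, Z, u, v`, each
#'   carrying its ground-truth pose as attribute `"pose"`.
#' @export
synthesize_calibration_views <- function(intrinsics, distortion, n_views = 10L,
                                         nx = 9L, ny = 7L, square_mm = 2,
                                         noise_sigma_px = 0, seed = 1L) {
  if (nx * ny < 20L) stop_ss("config_error", "board must have >= 20 inner corners")
  corners <- as.matrix(expand.grid(X = (seq_len(nx) - 1) * square_mm,
                                   Y = (seq_len(ny) - 1) * square_mm))
  center <- c((nx - 1), (ny - 1)) * square_mm / 2
  span <- max((nx - 1), (ny - 1)) * square_mm
  # board center distance chosen so the board fills most of the view
  z0 <- 1.25 * span * max(intrinsics$fx, intrinsics$fy) /
    min(intrinsics$width, intrinsics$height)
  with_seed(seed, {
    views <- vector("list", n_views)
    for (i in seq_len(n_views)) {
      repeat {
        ax <- stats::runif(1, -35, 35); ay <- stats::runif(1, -35, 35)
        az <- stats::runif(1, -30, 30)
        R <- rotation_matrix_about(c(0, 0, 1), az) %*%
          rotation_matrix_about(c(0, 1, 0), ay) %*%
          rotation_matrix_about(c(1, 0, 0), ax)
        z <- z0 * stats::runif(1, 0.9, 1.4)
        jit <- c(stats::runif(2, -0.08, 0.08) * z, 0)
        tv <- c(0, 0, z) - as.numeric(R %*% c(center, 0)) + jit
        pc <- sweep(corners %*% t(R[, 1:2]), 2, tv, `+`)
        if (any(pc[, 3] <= 1e-6)) next
        px <- project_points(intrinsics, distortion, pc)
        if (!all(attr(px, "inside"))) next
        if (noise_sigma_px > 0)
          px <- px + matrix(stats::rnorm(2 * nrow(px), sd = noise_sigma_px),
                            ncol = 2)
        df <- data.frame(X = corners[, 1], Y = corners[, 2], Z = 0,
                         u = px[, 1], v = px[, 2])
        attr(df, "pose") <- rigid_transform(R, tv, from = "board", to = "C")
        views[[i]] <- df
        break
      }
    }
    views
  })
}

#' Write / read calibration correspondence sets as CSV
#'
#' Columns: `view_id, X, Y, Z, u, v`.
#' @param views list of correspondence data frames; @param path file path.
#' @export
write_correspondences_csv <- function(views, path) {
  df <- do.call(rbind, lapply(seq_along(views), function(i)
    cbind(view_id = i, views[[i]][, c("X", "Y", "Z", "u", "v")])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correspondences_csv
#' @export
read_correspondences_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$view_id), function(v) v[, c("X", "Y", "Z", "u", "v")])
}
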