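#' Target registration error protocol
#'
#' Simulates the accuracy protocol used to evaluate the AR overlay: a
#' 2 mm-diameter circular model is superimposed on a checkerboard object
#' whose intersection coincides with the circle centre when registration is
#' perfect; the scope views the intersection at a fixed working distance
#' while the lens cylinder is rotated across a grid of angles. The error is
#' the distance, in millimetres on the object (checkerboard) plane, between
#' the overlaid circle centre back-projected through the true camera and
#' the true intersection point.
#'
#' @param working_distance_mm scope-tip-to-object distance (default 20 mm).
#' @param angles_deg lens-cylinder angle grid (default -40 to 40 in steps
#'   of 10 degrees, endpoints included: 9 angles).
#' @param circle_diameter_mm diameter of the circular target model (2 mm).
#' @param checker_square_mm checkerboard square size on the object (mm).
#' @param noise_sigma_px tracker pixel noise sd (default 0.05 px, which
#'   through the default stereo rig corresponds to the sub-millimetre 3D
#'   jitter of the optical-tracker class being simulated).
#' @param repetitions repetitions per angle (default 100; use 1 for a
#'   single sweep of one reading per angle).
#' @param seed protocol master seed.
#' @param noise_model `"pixel"` (tracker pixel noise, the default) or
#'   `"rotation"` (perturbs the estimated camera orientation about the
#'   camera centre by a random rotation, no pixel noise -- isolates the
#'   angular error component).
#' @param rotation_sigma_deg sd of the rotation perturbation (degrees) for
#'   `noise_model = "rotation"`.
#' @return list of class `tre_protocol`.
#' @export
tre_protocol <- function(working_distance_mm = 20,
                         angles_deg = seq(-40, 40, by = 10),
                         circle_diameter_mm = 2,
                         checker_square_mm = 2,
                         noise_sigma_px = 0.05,
                         repetitions = 100L,
                         seed = 1L,
                         noise_model = c("pixel", "rotation"),
                         rotation_sigma_deg = 0.2) {
  noise_model <- match.arg(noise_model)
  if (working_distance_mm <= 0)
    stop_ss("config_error", "working_distance_mm must be positive")
  if (any(angles_deg <= -180 | angles_deg > 180))
    stop_ss("config_error", "angle grid must lie in (-180, 180]")
  if (repetitions < 1L) stop_ss("config_error", "repetitions must be >= 1")
  structure(list(working_distance_mm = working_distance_mm,
                 angles_deg = as.numeric(angles_deg),
                 circle_diameter_mm = circle_diameter_mm,
                 checker_square_mm = checker_square_mm,
                 noise_sigma_px = noise_sigma_px,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 noise_model = noise_model,
                 rotation_sigma_deg = rotation_sigma_deg),
            class = "tre_protocol")
}

#' Read a TRE protocol from YAML
#'
#' Keys mirror the [tre_protocol()] arguments; `paper_sweep: true` sets
#' `repetitions = 1` (one reading per angle).
#' @param path YAML file path.
#' @export
read_tre_config <- function(path) {
  y <- yaml::read_yaml(path)
  reps <- if (isTRUE(y$paper_sweep)) 1L else as.integer(y$repetitions %||% 100L)
  tre_protocol(
    working_distance_mm = y$working_distance_mm %||% 20,
    angles_deg = y$angles_deg %||% seq(-40, 40, by = 10),
    circle_diameter_mm = y$circle_diameter_mm %||% 2,
    checker_square_mm = y$checker_square_mm %||% 2,
    noise_sigma_px = y$noise_sigma_px %||% 0.05,
    repetitions = reps,
    seed = y$seed %||% 1L,
    noise_model = y$noise_model %||% "pixel",
    rotation_sigma_deg = y$rotation_sigma_deg %||% 0.2
  )
}

# Static measurement scene: checkerboard plane z = 0 in the model base
# frame M with the target intersection at the origin; base marker rigid to
# the board; board ~820 mm in front of the tracker.
tre_rig_setup <- function(scope = default_arthroscope(), rig = stereo_rig()) {
  templates <- template_database(list(
    marker_template("base", marker_square(60) +
                      matrix(rep(c(60, 40, 0), each = 4), 4, 3)),
    marker_template("head", marker_square(34)),
    marker_template("cylinder", marker_square(26))
  ))
  T_sM <- rigid_transform(rotation_matrix_about(c(1, 0, 0), 160),
                          c(0, 40, 820), from = "M", to = "S")
  list(scope = scope, rig = rig, templates = templates,
       stub = list(T_sM = T_sM), target_M = c(0, 0, 0))
}

#' One TRE measurement at a cylinder angle
#'
#' Runs a single simulated observation: noisy marker observation, pose and
#' cylinder-angle estimation, model-to-camera chain, projection of the
#' circle centre with lens distortion, back-projection through the true
#' camera onto the checkerboard plane, and the object-plane distance to
#' the true intersection.
#'
#' @param protocol a `tre_protocol`.
#' @param theta_deg cylinder angle (degrees).
#' @param seed seed for this measurement.
#' @param setup optional cached result of the internal rig setup (used by
#'   [run_tre_protocol()] to avoid rebuilding it per call).
#' @return error in millimetres on the object plane.
#' @export
tre_at_angle <- function(protocol, theta_deg, seed, setup = NULL) {
  setup <- setup %||% tre_rig_setup()
  scope <- setup$scope; geom <- scope$geometry
  wd <- protocol$working_distance_mm
  view_dir <- c(0, 0, -1)   # scope looks straight down at the board

  gt <- session_ground_truth(setup$stub, geom, theta_deg, setup$target_M,
                             distance_mm = wd, view_dir_M = view_dir)
  ref_gt <- session_ground_truth(setup$stub, geom, 0, setup$target_M,
                                 distance_mm = wd, view_dir_M = view_dir)
  reference <- list(head = ref_gt$T_sA, cyl = ref_gt$T_sL)
  true_chain <- model_to_camera(gt$T_sM, gt$T_sA, geom, theta_deg)

  if (protocol$noise_model == "pixel") {
    sig <- protocol$noise_sigma_px
    est_base <- estimate_pose(setup$templates$base,
                              observe_marker(setup$rig, setup$templates$base,
                                             gt$T_sM, sig, derive_seed(seed, 1L)))
    est_head <- estimate_pose(setup$templates$head,
                              observe_marker(setup$rig, setup$templates$head,
                                             gt$T_sA, sig, derive_seed(seed, 2L)))
    est_cyl <- estimate_pose(setup$templates$cylinder,
                             observe_marker(setup$rig, setup$templates$cylinder,
                                            gt$T_sL, sig, derive_seed(seed, 3L)))
    th <- estimate_cylinder_angle(est_head, est_cyl, reference, geom)
    est_chain <- model_to_camera(est_base, est_head, geom, th$angle_deg)
  } else {
    # pure rotation noise about the (fixed) camera centre
    est_chain <- with_seed(seed, {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::rnorm(1, sd = protocol$rotation_sigma_deg)
      compose(rotation_about_axis(ax, ang, from = "C", to = "C"), true_chain)
    })
  }

  # overlay: project the circle centre through the estimated chain
  center_C <- as.numeric(est_chain$R %*% setup$target_M + est_chain$t)
  if (center_C[3] <= 0)
    stop_ss("visibility_error", "target behind the estimated camera at theta %.1f", theta_deg)
  px <- project_points(scope$intrinsics, scope$distortion, center_C)

  # read the error where the surgeon would: on the object plane, through
  # the true camera
  dir_C <- as.numeric(backproject_pixel(scope$intrinsics, scope$distortion, px))
  inv_true <- invert(true_chain)
  origin_M <- inv_true$t                        # true camera centre in M
  dir_M <- as.numeric(inv_true$R %*% dir_C)
  if (abs(dir_M[3]) < 1e-12)
    stop_ss("degenerate_geometry_error", "viewing ray parallel to the object plane")
  tt <- -origin_M[3] / dir_M[3]
  hit <- origin_M + tt * dir_M
  sqrt(sum((hit - setup$target_M)^2))
}

#' Run the full TRE protocol
#'
#' Iterates the angle grid x repetitions with per-measurement seeds derived
#' from the protocol seed, so results are invariant to evaluation order.
#'
#' @param protocol a `tre_protocol`.
#' @param setup optional cached rig setup.
#' @return object of class `tre_result`: `raw` (data frame `angle_deg`,
#'   `rep`, `error_mm`), `summary` (mean, sd, min, max in mm; sd is the
#'   sample sd, n-1), `protocol`.
#' @export
run_tre_protocol <- function(protocol = tre_protocol(), setup = NULL) {
  stopifnot(inherits(protocol, "tre_protocol"))
  setup <- setup %||% tre_rig_setup()
  grid <- expand.grid(rep = seq_len(protocol$repetitions),
                      angle_idx = seq_along(protocol$angles_deg))
  err <- vapply(seq_len(nrow(grid)), function(i) {
    ai <- grid$angle_idx[i]; ri <- grid$rep[i]
    tre_at_angle(protocol, protocol$angles_deg[ai],
                 seed = derive_seed(protocol$seed, ai, ri), setup = setup)
  }, numeric(1))
  raw <- data.frame(angle_deg = protocol$angles_deg[grid$angle_idx],
                    rep = grid$rep, error_mm = err)
  raw <- raw[order(raw$angle_deg, raw$rep), ]
  rownames(raw) <- NULL
  structure(list(raw = raw, summary = tre_summary_stats(raw$error_mm),
                 protocol = protocol),
            class = "tre_result")
}

tre_summary_stats <- function(e) {
  list(mean = mean(e),
       sd = if (length(e) > 1L) stats::sd(e) else 0,
       min = min(e), max = max(e), n = length(e),
       sd_convention = "sample (n-1)")
}

#' @export
print.tre_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Target registration error: %.2f ± %.2f mm (range %.2g–%.2g mm)\n",
              s$mean, s$sd, s$min, s$max))
  cat(sprintf("  %d angles x %d repetitions, working distance %g mm, sd: %s\n",
              length(x$protocol$angles_deg), x$protocol$repetitions,
              x$protocol$working_distance_mm, s$sd_convention))
  invisible(x)
}

#' Summarize a TRE result
#'
#' Formats the grand summary the way accuracy results are reported
#' ("mean ± sd mm (range min–max mm)") plus per-angle means.
#'
#' @param object a `tre_result`; @param ... unused.
#' @return `summary.tre_result`: list with `text`, `per_angle` (data frame),
#'   and the summary statistics.
#' @export
summary.tre_result <- function(object, ...) {
  if (nrow(object$raw) == 0L) stop_ss("config_error", "empty TRE table")
  s <- object$summary
  per_angle <- stats::aggregate(error_mm ~ angle_deg, object$raw, mean)
  names(per_angle)[2] <- "mean_error_mm"
  per_angle$n <- stats::aggregate(error_mm ~ angle_deg, object$raw, length)$error_mm
  txt <- sprintf("%.2f ± %.2f mm (range %.2g–%.2g mm)", s$mean, s$sd, s$min, s$max)
  structure(list(text = txt, per_angle = per_angle, mean = s$mean, sd = s$sd,
                 min = s$min, max = s$max, n = s$n,
                 sd_convention = s$sd_convention),
            class = "summary.tre_result")
}

#' @export
print.summary.tre_result <- function(x, ...) {
  cat("Target registration error:", x$text, "\n")
  cat(sprintf("  n = %d, sd convention: %s\n", x$n, x$sd_convention))
  cat("  per-angle mean error (mm):\n")
  print(x$per_angle, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tre_result <- function(x, ...) {
  graphics::boxplot(error_mm ~ angle_deg, data = x$raw,
                    xlab = "lens-cylinder angle (deg)",
                    ylab = "target registration error (mm)", ...)
  invisible(x)
}

#' Write / read the raw TRE table as CSV
#'
#' Columns `angle_deg, rep, error_mm`, full double precision.
#' @param result a `tre_result`; @param path file path.
#' @export
write_tre_csv <- function(result, path) {
  df <- result$raw
  df$error_mm <- sprintf("%.17g", df$error_mm)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tre_csv
#' @export
read_tre_csv <- function(path) {
  utils::read.csv(path, colClasses = c(angle_deg = "numeric", rep = "integer",
                                       error_mm = "numeric"))
}

#' Write the formatted TRE report
#' @param result a `tre_result`; @param path output text file.
#' @export
write_tre_report <- function(result, path) {
  s <- summary(result)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste("Target registration error:", s$text),
               sprintf("n = %d, sd convention: %s", s$n, s$sd_convention),
               "per-angle mean error (mm):",
               sprintf("  %+.0f deg: %.4f (n = %d)", s$per_angle$angle_deg,
                       s$per_angle$mean_error_mm, s$per_angle$n)),
             con, sep = "\n")
  invisible(path)
}
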