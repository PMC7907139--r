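test_that("triangulation inverts projection and respects rig symmetry", {
  rig <- stereo_rig()
  set.seed(5)
  for (i in 1:20) {
    p <- c(runif(1, -150, 150), runif(1, -100, 100), runif(1, 500, 1100))
    lp <- scopesight:::project_pinhole(rig$left, rbind(p))
    rp <- scopesight:::project_pinhole(rig$right, rbind(p))
    expect_lt(max(abs(triangulate(rig, lp, rp) - p)), 1e-8)
  }
  # a point on the baseline midplane triangulates to x = 0
  p0 <- c(0, 20, 700)
  x <- triangulate(rig,
                   scopesight:::project_pinhole(rig$left, rbind(p0)),
                   scopesight:::project_pinhole(rig$right, rbind(p0)))
  expect_lt(abs(x[1]), 1e-9)
  # near-parallel rays rejected
  expect_error(triangulate(stereo_rig(baseline_mm = 1e-4, vergence_deg = 0),
                           c(639.5, 479.5), c(639.5, 479.5)),
               class = "degenerate_triangulation_error")
})

test_that("triangulation error shrinks when the baseline grows", {
  p <- c(10, 25, 800)
  err_for <- function(baseline, seed) {
    rig <- stereo_rig(baseline_mm = baseline)
    lp <- scopesight:::project_pinhole(rig$left, rbind(p))
    rp <- scopesight:::project_pinhole(rig$right, rbind(p))
    set.seed(seed)
    median(replicate(400, {
      n <- rnorm(4, sd = 0.1)
      sqrt(sum((triangulate(rig, lp + n[1:2], rp + n[3:4]) - p)^2))
    }))
  }
  expect_lt(err_for(240, 99), err_for(120, 99))
})

test_that("observe_marker is exact without noise and deterministic under seed", {
  rig <- stereo_rig()
  tp <- marker_template("m", square_template_points(40))
  pose <- tracker_test_pose()
  clean <- observe_marker(rig, tp, pose)
  truth <- transform_points(pose, point_set(tp$xpoints, "m"))
  expect_lt(max(abs(clean - truth)), 1e-8)

  o1 <- observe_marker(rig, tp, pose, noise_sigma_px = 0.5, seed = 77)
  o2 <- observe_marker(rig, tp, pose, noise_sigma_px = 0.5, seed = 77)
  expect_identical(o1, o2)
  expect_gt(max(abs(o1 - clean)), 0)
  expect_error(observe_marker(rig, tp, pose, noise_sigma_px = 0.5),
               class = "config_error")
  # xpoint behind the cameras is a visibility error
  behind <- rigid_transform(t = c(0, 0, -200), from = "m", to = "S")
  expect_error(observe_marker(rig, tp, behind), class = "visibility_error")
})

test_that("observation error scales about linearly with pixel noise", {
  rig <- stereo_rig()
  tp <- marker_template("m", square_template_points(40))
  pose <- tracker_test_pose()
  truth <- transform_points(pose, point_set(tp$xpoints, "m"))
  med_err <- vapply(c(0.1, 0.2, 0.5), function(sig) {
    median(vapply(1:150, function(k) {
      o <- observe_marker(rig, tp, pose, sig, seed = 1000 + k)
      mean(sqrt(rowSums((o - truth)^2)))
    }, numeric(1)))
  }, numeric(1))
  ratio <- med_err / c(0.1, 0.2, 0.5)
  expect_lt(max(ratio) / min(ratio), 1.25)   # near-proportional
})

test_that("estimate_pose recovers poses, planar templates included", {
  rig <- stereo_rig()
  tp <- marker_template("planar", square_template_points(36))
  pose <- tracker_test_pose(x = -40, from = "planar")
  est <- estimate_pose(tp, observe_marker(rig, tp, pose))
  expect_lt(max(abs(est$transform$R - pose$R)), 1e-8)
  expect_lt(max(abs(est$transform$t - pose$t)), 1e-7)
  expect_lt(est$rms_residual, 1e-8)
  expect_error(estimate_pose(tp, point_set(matrix(0, 3, 3), "S")),
               class = "degenerate_geometry_error")
})

test_that("pose rotation error grows with pixel noise (Monte-Carlo medians)", {
  rig <- stereo_rig()
  tp <- marker_template("m", square_template_points(40))
  pose <- tracker_test_pose()
  geo_err <- function(sig) {
    vapply(1:500, function(k) {
      est <- estimate_pose(tp, observe_marker(rig, tp, pose, sig, seed = 5000 + k))
      scopesight:::rotation_axis_angle(t(pose$R) %*% est$transform$R)$angle_deg
    }, numeric(1))
  }
  expect_lt(median(geo_err(0.2)), median(geo_err(1.0)))
})

test_that("pose translation estimate is unbiased", {
  rig <- stereo_rig()
  tp <- marker_template("m", square_template_points(40))
  pose <- tracker_test_pose()
  errs <- t(vapply(1:500, function(k) {
    est <- estimate_pose(tp, observe_marker(rig, tp, pose, 0.3, seed = 9000 + k))
    est$transform$t - pose$t
  }, numeric(3)))
  se <- apply(errs, 2, sd) / sqrt(nrow(errs))
  expect_true(all(abs(colMeans(errs)) < 3 * se + 1e-12))
})

test_that("template database updates at run time and identifies markers", {
  db <- template_database()
  expect_length(db, 0L)
  db <- add_template(db, "A", square_template_points(40))
  expect_length(db, 1L)
  expect_error(add_template(db, "A", square_template_points(30)),
               class = "duplicate_name_error")
  expect_error(add_template(db, "bad", matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0),
                                              4, 3, byrow = TRUE)),
               class = "degenerate_geometry_error")

  rig <- stereo_rig()
  db <- add_template(db, "B", square_template_points(26))
  pose <- tracker_test_pose(from = "B")
  hit <- identify_template(db, observe_marker(rig, db$B, pose))
  expect_identical(hit$name, "B")
  expect_lt(hit$pose$rms_residual, 1e-8)

  # self-identification right after adding
  db <- add_template(db, "C", square_template_points(55))
  hitC <- identify_template(db, observe_marker(rig, db$C, tracker_test_pose(from = "C")))
  expect_identical(hitC$name, "C")

  # a scaled (non-rigid) observation cannot be absorbed by a rigid fit
  obs <- observe_marker(rig, db$A, tracker_test_pose(from = "A"))
  ctr <- colMeans(obs)
  scaled <- point_set(sweep(sweep(obs, 2, ctr) * 2, 2, ctr, `+`), "S")
  expect_error(identify_template(db, scaled), class = "no_match_error")
  expect_error(identify_template(template_database(), obs),
               class = "empty_database_error")
})

test_that("simultaneous identification over >= 5 templates is reliable at 0.2 px", {
  rig <- stereo_rig()
  db <- template_database()
  sides <- c(24, 32, 41, 52, 66)
  for (i in seq_along(sides))
    db <- add_template(db, paste0("tool", i), square_template_points(sides[i]))
  poses <- lapply(seq_along(sides), function(i)
    tracker_test_pose(x = -160 + 80 * i, from = paste0("tool", i)))
  n_ok <- 0L
  n_trials <- 200L
  for (trial in seq_len(n_trials)) {
    ok <- all(vapply(seq_along(sides), function(i) {
      obs <- observe_marker(rig, db[[i]], poses[[i]], 0.2,
                            seed = 31000 + 10 * trial + i)
      identical(identify_template(db, obs, threshold_mm = 3)$name,
                paste0("tool", i))
    }, logical(1)))
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok / n_trials, 0.99)
})

test_that("template JSON and pose CSV round-trip deterministically", {
  tp <- marker_template("probe", square_template_points(33))
  path <- withr::local_tempfile(fileext = ".json")
  write_template_json(tp, path)
  back <- read_template_json(path)
  expect_identical(back$name, "probe")
  expect_equal(back$xpoints, tp$xpoints, tolerance = 1e-12)

  rig <- stereo_rig()
  est <- estimate_pose(tp, observe_marker(rig, tp, tracker_test_pose(from = "probe")),
                       frame_index = 1L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(list(est), f1)
  write_pose_csv(list(est), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_match(readLines(f1)[1], "frame,name,m00")
})
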