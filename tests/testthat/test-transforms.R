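test_that("compose obeys the group structure and frame-label chaining", {
  rz <- function(a, from, to) rotation_about_axis(c(0, 0, 1), a, from, to)
  T1 <- compose_free(rz(90, "a", "b"), c(1, 2, 3))

  # identity cases
  id_b <- rigid_transform(from = "b", to = "b")
  expect_equal(compose(id_b, T1)$R, T1$R)
  expect_equal(compose(id_b, T1)$t, T1$t)

  # inverse composes to identity within 1e-9 (rotation and translation)
  ti <- compose(T1, invert(T1))
  expect_lt(max(abs(ti$R - diag(3))), 1e-9)
  expect_lt(max(abs(ti$t)), 1e-9)

  # two quarter turns act as a half turn on (1,0,0)
  half <- compose(rz(90, "b", "c"), rz(90, "a", "b"))
  p <- transform_points(half, point_set(rbind(c(1, 0, 0)), "a"))
  expect_equal(as.numeric(p), c(-1, 0, 0), tolerance = 1e-12)

  # labels that do not chain refuse to compose
  expect_error(compose(rz(10, "a", "b"), rz(10, "a", "b")),
               class = "frame_mismatch_error")

  # associativity and closure on random triples
  set.seed(42)
  for (i in 1:25) {
    a <- random_transform(to = "x", from = "y")
    b <- random_transform(to = "y", from = "z")
    c_ <- random_transform(to = "z", from = "w")
    lhs <- compose(a, compose(b, c_))
    rhs <- compose(compose(a, b), c_)
    expect_lt(max(abs(lhs$R - rhs$R)), 1e-12)
    expect_lt(max(abs(lhs$t - rhs$t)), 1e-11)
    expect_lt(max(abs(crossprod(lhs$R) - diag(3))), 1e-9)
    expect_equal(det(lhs$R), 1, tolerance = 1e-9)
  }
})

test_that("invert is the closed-form inverse and an involution", {
  t0 <- compose_free(rotation_about_axis(c(0, 0, 1), 90, "a", "b"), c(1, 2, 3))
  ti <- invert(t0)
  expect_equal(ti$R, rotation_about_axis(c(0, 0, 1), -90)$R, tolerance = 1e-12)
  expect_equal(ti$t, c(-2, 1, -3), tolerance = 1e-12)
  expect_identical(ti$from, "b")
  expect_identical(ti$to, "a")

  set.seed(7)
  for (i in 1:10) {
    tr <- random_transform()
    tii <- invert(invert(tr))
    expect_lt(max(abs(tii$R - tr$R)), 1e-12)
    expect_lt(max(abs(tii$t - tr$t)), 1e-12)
  }
})

test_that("transform_points maps, relabels and round-trips", {
  tr <- compose_free(rotation_about_axis(c(0, 1, 0), 30, "a", "b"), c(1, 0, 0))
  expect_equal(as.numeric(transform_points(
    rigid_transform(t = c(1, 0, 0), from = "a", to = "b"),
    point_set(rbind(c(0, 0, 0)), "a"))), c(1, 0, 0))
  set.seed(3)
  P <- point_set(random_points(20), "a")
  back <- transform_points(tr, transform_points(invert(tr), point_set(P, "b")))
  expect_lt(max(abs(back - P)), 1e-12)
  expect_error(transform_points(tr, point_set(P, "wrong")),
               class = "frame_mismatch_error")
})

test_that("rotation_about_axis satisfies the Rodrigues identities", {
  expect_equal(rotation_about_axis(c(1, 0, 0), 0)$R, diag(3))
  p <- transform_points(rotation_about_axis(c(0, 0, 1), 90),
                        point_set(rbind(c(1, 0, 0))))
  expect_equal(as.numeric(p), c(0, 1, 0), tolerance = 1e-12)
  r <- compose(rotation_about_axis(c(1, 2, 2) / 3, 37),
               rotation_about_axis(c(1, 2, 2) / 3, -37))
  expect_lt(max(abs(r$R - diag(3))), 1e-12)
  expect_error(rotation_about_axis(c(1, 1, 0), 10),
               class = "degenerate_geometry_error")
})

test_that("absolute_orientation recovers exact correspondences and rejects degeneracy", {
  set.seed(11)
  P <- random_points(5)
  same <- absolute_orientation(P, P)
  expect_lt(max(abs(same$transform$R - diag(3))), 1e-12)
  expect_lt(same$rms_residual, 1e-12)

  tr <- compose_free(rotation_about_axis(c(1, 0, 0), 30), c(5, 0, 0))
  fit <- absolute_orientation(P, transform_points(tr, point_set(P)))
  expect_lt(max(abs(fit$transform$R - tr$R)), 1e-9)
  expect_lt(max(abs(fit$transform$t - tr$t)), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  # noise-free exactness over many random instances
  for (i in 1:100) {
    tr <- random_transform()
    P <- random_points(4 + i %% 5)
    fit <- absolute_orientation(P, transform_points(tr, point_set(P)))
    expect_lt(fit$rms_residual, 1e-9)
  }

  expect_error(absolute_orientation(P[1:2, ], P[1:2, ]),
               class = "degenerate_geometry_error")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(absolute_orientation(line, line),
               class = "degenerate_geometry_error")
})

test_that("absolute_orientation attains the brute-force optimum on perturbed sets", {
  set.seed(23)
  src <- square_template_points(40)
  dst <- src
  dst[2, ] <- dst[2, ] + c(0.1, 0, 0)   # one point off by 0.1 mm
  fit <- absolute_orientation(src, dst)
  rms_of <- function(R, t) {
    d <- dst - (src %*% t(R) + matrix(t, nrow(src), 3, byrow = TRUE))
    sqrt(mean(rowSums(d^2)))
  }
  # dense randomized search over a small SE(3) neighbourhood of identity
  cand <- replicate(4000, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- rotation_about_axis(ax, stats::runif(1, -1, 1))$R
    rms_of(R, stats::runif(3, -0.15, 0.15))
  })
  expect_lte(fit$rms_residual, min(cand) + 1e-12)
  # and the searched minimum comes close to the analytic one
  expect_lt(min(cand) - fit$rms_residual, 0.02)
})

test_that("homogeneous serialization round-trips and validates", {
  tr <- compose_free(rotation_about_axis(c(0, 1, 0), 55, "M", "S"), c(4, 5, 6))
  H <- as_homogeneous(tr)
  expect_equal(dim(H), c(4L, 4L))
  back <- from_homogeneous(H, from = "M", to = "S")
  expect_equal(back$R, tr$R, tolerance = 1e-15)

  path <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tr, path)
  rt <- read_transform_json(path)
  expect_equal(rt$R, tr$R, tolerance = 1e-12)
  expect_equal(rt$t, tr$t, tolerance = 1e-12)
  expect_identical(rt$from, "M")

  bad <- H; bad[1, 1] <- 2
  expect_error(from_homogeneous(bad), class = "invalid_transform_error")
})
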