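test_that("rigid transform composition, identity and inverse behave as a group", {
  t1 <- rigid_transform(euler_compose(10, -20, 30), c(1, 2, 3))
  expect_equal(rt_compose(rt_identity(), t1)$rotation, t1$rotation)
  expect_equal(rt_compose(rt_identity(), t1)$translation, t1$translation)
  inv <- rt_compose(t1, rt_inverse(t1))
  expect_lt(max(abs(inv$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(inv$translation)), 1e-9)
  # rotations about the same axis add their angles
  comp <- rt_compose(rigid_transform(euler_compose(30, 0, 0)),
                     rigid_transform(euler_compose(15, 0, 0)))
  expect_lt(max(abs(comp$rotation - euler_compose(45, 0, 0))), 1e-9)
  # compose(a, b) applies b first
  a <- rigid_transform(diag(3), c(1, 0, 0))
  b <- rigid_transform(euler_compose(0, 0, 90), c(0, 0, 0))
  p <- transform_points(rt_compose(a, b), c(1, 0, 0))
  expect_equal(p, c(1, 1, 0), tolerance = 1e-12)
})

test_that("rigid transforms preserve pairwise distances", {
  set.seed(11)
  for (i in 1:20) {
    tr <- rigid_transform(random_rotation(), rnorm(3, 0, 10))
    pts <- matrix(rnorm(30, 0, 50), 10, 3)
    moved <- transform_points(tr, pts)
    expect_lt(max(abs(dist(moved) - dist(pts)) / pmax(dist(pts), 1)), 1e-9)
  }
})

test_that("superpose_rigid recovers exact rigid motions to machine precision", {
  set.seed(21)
  src <- matrix(rnorm(12, 0, 10), 4, 3)
  expect_lt(max(abs(superpose_rigid(src, src)$rotation - diag(3))), 1e-9)
  true <- rigid_transform(euler_compose(0, 0, 25), c(1, 2, 3))
  fit <- superpose_rigid(src, transform_points(true, src))
  expect_lt(max(abs(fit$rotation - true$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - true$translation)), 1e-9)
  expect_lt(attr(fit, "rmsd"), 1e-9)
})

test_that("superpose_rigid never returns a reflection for mirrored targets", {
  set.seed(22)
  src <- matrix(rnorm(18, 0, 10), 6, 3)
  mirrored <- src
  mirrored[, 1] <- -mirrored[, 1]
  fit <- superpose_rigid(src, mirrored)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(fit, "rmsd"), 0)
})

test_that("superpose_rigid rejects degenerate configurations", {
  expect_error(superpose_rigid(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "degenerate")
  line <- cbind(1:5, 2 * (1:5), -(1:5))   # collinear
  expect_error(superpose_rigid(line, line), "collinear")
})

test_that("euler angles compose and decompose consistently", {
  expect_equal(unname(euler_decompose(diag(3))), c(0, 0, 0))
  e <- euler_decompose(euler_compose(5, 0, 0))
  expect_equal(unname(e), c(5, 0, 0), tolerance = 1e-9)
  expect_equal(euler_compose(180, 0, 0), diag(c(1, -1, -1)), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    r <- random_rotation()
    e <- euler_decompose(r)
    expect_lt(max(abs(euler_compose(e) - r)), 1e-9)
  }
  # decompose(compose(.)) is the identity inside (-90, 90)^3
  set.seed(32)
  for (i in 1:50) {
    ang <- runif(3, -89, 89)
    e <- euler_decompose(euler_compose(ang[1], ang[2], ang[3]))
    expect_equal(unname(e), ang, tolerance = 1e-9)
  }
})

test_that("gimbal lock is flagged and resolved with yaw = 0", {
  r <- euler_compose(25, 90, 10)
  expect_warning(e <- euler_decompose(r), "gimbal")
  expect_true(attr(e, "gimbal_lock"))
  expect_equal(e[["yaw"]], 0)
  expect_lt(max(abs(euler_compose(e) - r)), 1e-6)
})

test_that("rotation about a center fixes the center and matches hand values", {
  expect_lt(max(abs(rotation_about_center(c(1, 2, 3), c(0, 0, 1), 0)$rotation -
                      diag(3))), 1e-12)
  r90 <- rotation_about_center(c(0, 0, 0), c(0, 0, 1), 90)
  expect_equal(transform_points(r90, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-9)
  r180 <- rotation_about_center(c(1, 1, 0), c(0, 0, 1), 180)
  expect_equal(transform_points(r180, c(0, 0, 0)), c(2, 2, 0), tolerance = 1e-9)
  ctr <- c(4, -3, 7)
  tr <- rotation_about_center(ctr, c(1, 0, 0) / 1, 37)
  expect_lt(max(abs(transform_points(tr, ctr) - ctr)), 1e-9)
  expect_error(rotation_about_center(c(0, 0, 0), c(0, 0, 0), 10), "axis")
  expect_error(rotation_about_center(c(0, 0, 0), c(0, 0, 2), 10), "unit")
})

test_that("planes normalise and measure signed distance", {
  p <- plane3(c(0, 0, 1), c(0, 0, 5))
  expect_equal(sqrt(sum(p$normal^2)), 1, tolerance = 1e-12)
  expect_equal(plane_distance(p, rbind(c(0, 0, 3), c(0, 0, 0))), c(2, -1))
  expect_error(plane3(c(0, 0, 0), c(0, 0, 0)), "nonzero")
})
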