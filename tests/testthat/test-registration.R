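test_that("k-d tree nearest neighbours match exhaustive search", {
  set.seed(41)
  q <- matrix(rnorm(600), 200, 3)
  ref <- matrix(rnorm(600), 200, 3)
  nn <- nearest_neighbors(q, ref)
  brute <- apply(q, 1L, function(p) which.min(colSums((t(ref) - p)^2)))
  expect_equal(nn$index, unname(brute))
  bd <- sqrt(colSums((t(ref[brute, ]) - t(q))^2))
  expect_equal(nn$distance, unname(bd), tolerance = 1e-12)

  self <- nearest_neighbors(ref, ref)
  expect_equal(self$index, seq_len(200))
  expect_equal(self$distance, rep(0, 200))

  single <- nearest_neighbors(q, ref[1, , drop = FALSE])
  expect_true(all(single$index == 1L))
  expect_error(nearest_neighbors(q, matrix(numeric(0), 0, 3)), "empty")
})

test_that("ICP recovers identity for a subsampled copy and known rigid motions", {
  ph <- default_phantom()
  tgt <- ph$mesh$vertices
  src <- tgt[seq(1, nrow(tgt), by = 3), ]
  res <- icp_register(src, tgt)
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(res$transform$translation)), 1e-6)
  expect_lt(res$rms, 1e-6)

  true <- rigid_transform(euler_compose(0, 0, 10), c(2, 1, 0))
  moved <- transform_points(true, src)
  # recover the inverse starting from a small offset
  init <- rigid_transform(euler_compose(1, 0, -1), c(0.5, 0, 0))
  res2 <- icp_register(moved, tgt, icp_params(), init = rt_compose(init, rt_inverse(true)))
  err <- rt_compose(res2$transform, true)
  expect_lt(max(abs(err$translation)), 1e-4)
  expect_lt(max_euler_error(res2$transform$rotation, rt_inverse(true)$rotation), 1e-4)
})

test_that("ICP errors on fully disjoint sets with a correspondence gate", {
  set.seed(42)
  src <- matrix(rnorm(60), 20, 3)
  tgt <- src + 100
  expect_error(icp_register(src, tgt, icp_params(max_distance = 1)),
               "no overlap")
})

test_that("ICP kept-pair RMS is non-increasing across iterations", {
  ph <- default_phantom()
  src <- transform_points(rigid_transform(euler_compose(1.5, -1, 1), c(1, 2, -1)),
                          ph$mesh$vertices[ph$regions$maxilla, ])
  # re-run ICP manually to observe the per-iteration objective
  params <- icp_params(max_iterations = 30)
  trans <- rt_identity()
  tgt <- ph$mesh$vertices
  rms_seq <- numeric(0)
  for (i in 1:15) {
    moved <- transform_points(trans, src)
    nn <- nearest_neighbors(moved, tgt)
    keep <- order(nn$distance)[seq_len(ceiling(0.9 * nrow(src)))]
    trans <- superpose_rigid(src[keep, ], tgt[nn$index[keep], ])
    resid <- transform_points(trans, src[keep, ]) - tgt[nn$index[keep], ]
    rms_seq <- c(rms_seq, sqrt(mean(rowSums(resid^2))))
  }
  expect_true(all(diff(rms_seq) <= 1e-9))
})

test_that("rigid CPD recovers identity, noisy motions, and resists outliers", {
  ph <- default_phantom()
  y <- ph$mesh$vertices[seq(1, nrow(ph$mesh$vertices), length.out = 300), ]
  # perfect data: the mixture variance legitimately collapses to zero
  expect_warning(res <- cpd_rigid_register(y, y, cpd_params(w = 0)),
                 "variance collapsed")
  expect_true(res$degenerate_variance)
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(res$transform$translation)), 1e-6)

  set.seed(43)
  y2 <- ph$mesh$vertices[sample(nrow(ph$mesh$vertices), 500), ]
  true <- rigid_transform(euler_compose(3, -2, 4), c(2, 1, -1))
  x2 <- transform_points(true, y2) + matrix(rnorm(1500, 0, 0.05), ncol = 3)
  res2 <- cpd_rigid_register(y2, x2, cpd_params(w = 0.1))
  expect_lt(max(abs(res2$transform$translation - true$translation)), 0.02)
  expect_lt(max_euler_error(res2$transform$rotation, true$rotation), 0.05)
  # EM objective is monotonically non-increasing
  obj <- res2$objective
  expect_true(all(diff(obj) <= 1e-9 * pmax(1, abs(obj[-length(obj)]))))

  # 20% uniform outliers in the target
  set.seed(44)
  x3 <- transform_points(true, y2)
  n_out <- round(0.2 * nrow(x3))
  x3[sample(nrow(x3), n_out), ] <- cbind(runif(n_out, -80, 80),
                                         runif(n_out, -80, 120),
                                         runif(n_out, -60, 110))
  res3 <- suppressWarnings(cpd_rigid_register(y2, x3, cpd_params(w = 0.2)))
  expect_lt(max(abs(res3$transform$translation - true$translation)), 0.1)
  expect_lt(max_euler_error(res3$transform$rotation, true$rotation), 0.2)
})

test_that("dentition fusion recovers the scan pose through ICP + CPD", {
  ph <- default_phantom()
  # exact submesh -> identity
  scan0 <- make_dentition_scan(ph$mesh, ph$regions$dentition, rt_identity(),
                               noise_sd = 0, overlap = 1, seed = 1)
  res0 <- suppressWarnings(fuse_dentition(scan0$mesh, ph$mesh))  # noiseless: variance collapse expected
  expect_lt(max(abs(res0$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(res0$transform$translation)), 1e-6)

  # 60% overlap, 0.1 mm noise, known pose: landmark RMS within 0.15 mm
  true <- rigid_transform(euler_compose(4, -3, 6), c(5, -4, 3))
  scan <- make_dentition_scan(ph$mesh, ph$regions$dentition, true,
                              noise_sd = 0.1, overlap = 0.6, seed = 2)
  res <- fuse_dentition(scan$mesh, ph$mesh)
  lm <- as.matrix(ph$landmarks[ph$landmarks$name %in% tooth_landmarks(),
                               c("x", "y", "z")])
  lm_scan <- transform_points(rt_inverse(true), lm)
  err <- transform_points(res$transform, lm_scan) - lm
  expect_lt(sqrt(mean(rowSums(err^2))), 0.15)

  expect_error(fuse_dentition(triangle_mesh(matrix(rnorm(9), 3, 3), NULL),
                              ph$mesh), "no faces")
})

test_that("fusion locks onto the dentition even when the maxilla moved elsewhere", {
  ph <- default_phantom()
  true <- rigid_transform(euler_compose(2, -1, 3), c(3, -2, 2))
  scan <- make_dentition_scan(ph$mesh, ph$regions$dentition, true,
                              noise_sd = 0.02, overlap = 0.8, seed = 9)
  # displace a distant (cranial) patch of the CT model: a non-corresponding
  # region that trimming / the outlier weight must ignore
  ct <- ph$mesh
  patch <- ph$regions$cranial[seq_len(150)]
  ct$vertices[patch, ] <- ct$vertices[patch, ] + 5
  res <- fuse_dentition(scan$mesh, ct)
  lm <- as.matrix(ph$landmarks[ph$landmarks$name %in% tooth_landmarks(),
                               c("x", "y", "z")])
  err <- transform_points(res$transform, transform_points(rt_inverse(true), lm)) - lm
  expect_lt(sqrt(mean(rowSums(err^2))), 0.15)
})

test_that("cranial-base registration uses only the mask and needs enough of it", {
  ph <- default_phantom()
  res <- register_cranial_base(ph$mesh, ph$mesh, ph$regions$cranial)
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-6)
  expect_lt(res$rms, 1e-6)

  # whole model re-posed AND maxilla additionally displaced: the mask must
  # recover the global pose, untouched by the surgical displacement
  gp <- rigid_transform(euler_compose(1.5, -1, 1), c(2, -1, 2))
  moved <- ph$mesh
  moved$vertices[ph$regions$maxilla, ] <-
    moved$vertices[ph$regions$maxilla, ] + matrix(c(2, -3, 1),
                                                  length(ph$regions$maxilla),
                                                  3, byrow = TRUE)
  moved <- transform_mesh(gp, moved)
  res2 <- register_cranial_base(moved, ph$mesh, ph$regions$cranial)
  err <- rt_compose(res2$transform, gp)
  expect_lt(max(abs(err$translation)), 1e-3)
  expect_lt(max(abs(euler_decompose(err$rotation))), 1e-3)

  expect_error(register_cranial_base(ph$mesh, ph$mesh, integer(0)), "mask")
  expect_error(register_cranial_base(ph$mesh, ph$mesh, 1:50), "100")
})
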