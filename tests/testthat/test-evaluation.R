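test_that("linear discrepancies follow the postop - sim convention", {
  ph <- default_phantom()
  lm <- ph$landmarks
  zero <- landmark_linear_discrepancy(lm, lm)
  expect_true(all(abs(as.matrix(zero[, -1])) < 1e-12))

  shifted <- lm
  shifted$x <- shifted$x + 1
  one <- landmark_linear_discrepancy(lm, shifted)
  expect_true(all(one$dx == 1 & one$dy == 0 & one$dz == 0 & one$rms == 1))

  off <- lm
  i <- match("incisor_r", off$name)
  off$x[i] <- off$x[i] + 0.48
  off$y[i] <- off$y[i] + 0.79
  off$z[i] <- off$z[i] + 1.03
  tab <- landmark_linear_discrepancy(lm, off)
  expect_equal(tab$rms[tab$landmark == "incisor_r"], 1.3840, tolerance = 1e-4)

  expect_error(landmark_linear_discrepancy(lm[-1, ], lm), "missing")
})

test_that("per-landmark RMS dominates each component and squares add", {
  set.seed(61)
  ph <- default_phantom()
  lm <- ph$landmarks
  for (i in 1:10) {
    jit <- lm
    jit$x <- jit$x + rnorm(nrow(jit), 0, 1)
    jit$y <- jit$y + rnorm(nrow(jit), 0, 1)
    jit$z <- jit$z + rnorm(nrow(jit), 0, 1)
    tab <- landmark_linear_discrepancy(lm, jit)
    expect_true(all(tab$rms >= pmax(tab$adx, tab$ady, tab$adz) - 1e-12))
    expect_lt(max(abs(tab$rms^2 - (tab$dx^2 + tab$dy^2 + tab$dz^2))), 1e-9)
  }
})

test_that("occlusal angular discrepancy reads off an applied occlusal rotation", {
  ph <- default_phantom()
  lm <- ph$landmarks
  zero <- occlusal_angular_discrepancy(lm, lm)
  expect_equal(as.numeric(zero[1, ]), c(0, 0, 0))

  # a pure pitch applied about the occlusal-frame origin must come back as
  # pitch alone; 1.43 degrees is the clinically typical magnitude
  origin <- occlusal_plane(lm)$plane$origin
  tr <- rt_compose(rigid_transform(diag(3), origin),
                   rt_compose(rigid_transform(euler_compose(1.43, 0, 0)),
                              rigid_transform(diag(3), -origin)))
  rot_lm <- transform_points(tr, lm)
  ang <- occlusal_angular_discrepancy(lm, rot_lm)
  expect_equal(ang$pitch, 1.43, tolerance = 1e-6)
  expect_equal(ang$roll, 0, tolerance = 1e-6)
  expect_equal(ang$yaw, 0, tolerance = 1e-6)

  flat <- landmark_set(mb_cusp_molar1_r = c(-1, 0, 0),
                       mb_cusp_molar1_l = c(1, 0, 0),
                       incisor_midpoint = c(0, 0, 0))
  expect_error(occlusal_angular_discrepancy(flat, flat), "collinear")
})

test_that("displacement summary reproduces the published cohort rows", {
  tab <- bimax_displacements()[, -1]
  s <- summarize_displacements(tab)
  expect_equal(round(s$mean, 2), c(0.11, 0.37, 0.88, 5.48, 0.70, -0.35))
  expect_equal(round(s$sd, 2), c(1.40, 1.40, 1.98, 3.18, 2.63, 1.79))
  # published absolute means (the left-right cell does not recompute from
  # the printed per-patient values and is excluded; see the vignette)
  expect_equal(round(s$abs_mean[-1], 2), c(1.00, 1.67, 5.48, 2.14, 1.41))

  pm <- summarize_displacements(tibble::tibble(v = c(1, -1)))
  expect_equal(pm$mean, 0)
  expect_equal(pm$abs_mean, 1)
  expect_error(summarize_displacements(tibble::tibble(v = 1)), "2 rows")
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  ab <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(ab$statistic, 13.5, tolerance = 1e-9)
  expect_equal(ab$df1, 1)
  expect_equal(ab$df2, 4)
  expect_equal(ab$p.value, 0.0213, tolerance = 1e-3)

  set.seed(62)
  g1 <- rnorm(8); g2 <- rnorm(10, 0.5)
  f <- one_way_anova(list(g1, g2))$statistic
  tstat <- t.test(g1, g2, var.equal = TRUE)$statistic
  expect_equal(f, unname(tstat^2), tolerance = 1e-9)
})

test_that("Pearson correlation handles exact, hand-computed and degenerate cases", {
  x <- c(1, 5, 9, 2)
  expect_equal(pearson_correlation(x, x)$estimate, 1)
  expect_equal(pearson_correlation(x, -2 * x + 3)$estimate, -1)
  r <- pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 5))
  expect_equal(r$estimate, 0.83152, tolerance = 1e-4)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "length")
})

test_that("KS normality test accepts normal data and rejects degenerate input", {
  ok <- 0L
  for (i in 1:100) {
    set.seed(i)
    if (ks_normality(rnorm(1000))$p.value > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 95L)

  # equally spaced normal quantiles are as normal as a sample can be
  n <- 50L
  q <- qnorm((seq_len(n) - 0.5) / n)
  expect_lte(ks_normality(q)$statistic, 1 / (2 * n) + 0.02)

  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("evaluate_case reports zeros for an identical postoperative model", {
  ph <- default_phantom()
  rep0 <- evaluate_case(ph$mesh, ph$landmarks, ph$mesh, ph$landmarks,
                        ph$regions$cranial)
  expect_lt(max(abs(as.matrix(rep0$linear[, -1]))), 1e-6)
  expect_lt(max(abs(as.numeric(rep0$angular[1, ]))), 1e-6)
  expect_error(evaluate_case(ph$mesh, ph$landmarks, ph$mesh, ph$landmarks,
                             integer(0)), "mask")
})

test_that("evaluate_case recovers a pure maxillary translation under re-posing", {
  ph <- default_phantom()
  po <- make_postop_case(ph$mesh, ph$landmarks, ph$regions$maxilla,
                         applied = c(0.5, -0.8, 1.0, 0, 0, 0),
                         global_pose = rigid_transform(euler_compose(3, -2, 4),
                                                       c(6, -3, 8)),
                         cranial_sd = 0, seed = 7)
  rep <- evaluate_case(ph$mesh, ph$landmarks, po$mesh, po$landmarks,
                       ph$regions$cranial)
  expect_lt(max(abs(rep$linear$dx - 0.5)), 0.02)
  expect_lt(max(abs(rep$linear$dy + 0.8)), 0.02)
  expect_lt(max(abs(rep$linear$dz - 1.0)), 0.02)
})

test_that("report CSV serialisation includes landmarks and angular footer", {
  ph <- default_phantom()
  rep0 <- evaluate_case(ph$mesh, ph$landmarks, ph$mesh, ph$landmarks,
                        ph$regions$cranial)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep0, path)
  got <- utils::read.csv(path)
  expect_true(all(tooth_landmarks() %in% got$landmark))
  expect_true(all(c("pitch_deg", "roll_deg", "yaw_deg") %in% got$landmark))
})
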