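# Accuracy evaluation: cranial-base registration of the postoperative
# model onto the simulation model, per-landmark linear discrepancies
# (dx/dy/dz/RMS), occlusal-plane angular discrepancies (pitch/roll/yaw),
# displacement summary statistics, and the accompanying statistics
# (one-way ANOVA, Pearson correlation, Kolmogorov-Smirnov normality).

#' Per-landmark linear discrepancies
#'
#' Signed differences `postop - sim` per axis, their absolute values, and
#' the per-landmark RMS `sqrt(dx^2 + dy^2 + dz^2)` (the Euclidean
#' distance between the paired landmarks).
#'
#' @param sim_landmarks,postop_landmarks landmark tibbles containing every
#'   name in `names`
#' @param names landmarks to evaluate (default the eight maxillary tooth
#'   landmarks)
#' @return tibble: `landmark`, `dx`, `dy`, `dz`, `adx`, `ady`, `adz`, `rms`
#' @export
landmark_linear_discrepancy <- function(sim_landmarks, postop_landmarks,
                                        names = tooth_landmarks()) {
  .lm_check(sim_landmarks); .lm_check(postop_landmarks)
  miss <- setdiff(names, intersect(sim_landmarks$name, postop_landmarks$name))
  if (length(miss)) {
    abort(paste("missing landmark(s):", paste(miss, collapse = ", ")))
  }
  s <- sim_landmarks[match(names, sim_landmarks$name), ]
  p <- postop_landmarks[match(names, postop_landmarks$name), ]
  tibble(landmark = names,
         dx = p$x - s$x, dy = p$y - s$y, dz = p$z - s$z) |>
    mutate(adx = abs(.data$dx), ady = abs(.data$dy), adz = abs(.data$dz),
           rms = sqrt(.data$dx^2 + .data$dy^2 + .data$dz^2))
}

#' Occlusal-plane angular discrepancy
#'
#' Builds the occlusal frame of each landmark set and returns the Euler
#' decomposition of the relative rotation `F_post %*% t(F_sim)`: pitch
#' about x, roll about y, yaw about z, in degrees.
#'
#' @param sim_landmarks,postop_landmarks landmark tibbles containing the
#'   occlusal landmarks
#' @return one-row tibble with `pitch`, `roll`, `yaw` (degrees)
#' @export
occlusal_angular_discrepancy <- function(sim_landmarks, postop_landmarks) {
  fs <- occlusal_plane(sim_landmarks)$frame
  fp <- occlusal_plane(postop_landmarks)$frame
  e <- euler_decompose(fp %*% t(fs))
  tibble(pitch = e[["pitch"]], roll = e[["roll"]], yaw = e[["yaw"]])
}

#' Summary statistics of displacement tables
#'
#' Per column of a six-component displacement table: the signed mean and
#' sample SD (n - 1 denominator), and the mean and sample SD of the
#' absolute values.
#'
#' @param table data frame of displacement rows (numeric columns only are
#'   summarised); at least 2 rows
#' @return tibble: `component`, `mean`, `sd`, `abs_mean`, `abs_sd`
#' @export
summarize_displacements <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (nrow(num) < 2L) abort("need at least 2 rows (SD undefined)")
  tibble(component = names(num),
         mean = unname(vapply(num, mean, numeric(1))),
         sd = unname(vapply(num, sd, numeric(1))),
         abs_mean = unname(vapply(num, function(v) mean(abs(v)), numeric(1))),
         abs_sd = unname(vapply(num, function(v) sd(abs(v)), numeric(1))))
}

#' One-way ANOVA across groups
#'
#' Classic between/within F statistic with (k - 1, N - k) degrees of
#' freedom, fitted via `aov`. A Bonferroni-corrected pairwise Welch t-test
#' table is attached for the post-hoc comparison of directions.
#'
#' @param groups a named or unnamed list of numeric vectors (each length
#'   >= 2)
#' @return tibble of class `stat_test`: `statistic`, `p.value`, `df1`,
#'   `df2`; attribute `posthoc` holds the pairwise p-value matrix
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) abort("each group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- tibble(value = unlist(groups, use.names = FALSE),
               group = factor(rep(names(groups), lengths(groups))))
  tab <- anova(aov(value ~ group, data = df))
  fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.nan(fstat)) { fstat <- 0; p <- 1 }  # zero within-group variance, equal means
  ph <- suppressWarnings(
    pairwise.t.test(df$value, df$group, p.adjust.method = "bonferroni",
                    pool.sd = FALSE)$p.value)
  structure(tibble(statistic = fstat, p.value = p,
                   df1 = tab$Df[1], df2 = tab$Df[2]),
            posthoc = ph, class = c("stat_test", "tbl_df", "tbl", "data.frame"))
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance
#' @return tibble of class `stat_test`: `estimate` (r), `statistic` (t),
#'   `p.value`, `df`
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3")
  }
  if (sd(x) < 1e-300 || sd(y) < 1e-300) {
    abort("undefined correlation: zero variance")
  }
  ct <- cor.test(x, y, method = "pearson")
  structure(tibble(estimate = unname(ct$estimate),
                   statistic = unname(ct$statistic),
                   p.value = ct$p.value,
                   df = unname(ct$parameter)),
            class = c("stat_test", "tbl_df", "tbl", "data.frame"))
}

#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal distribution with the sample
#' mean and SD (no small-sample Lilliefors correction; the asymptotic p is
#' reported and is anti-conservative when parameters are estimated).
#'
#' @param x numeric vector, length >= 5, nonzero variance
#' @return tibble of class `stat_test`: `statistic` (D), `p.value`
#' @export
ks_normality <- function(x) {
  if (length(x) < 5L) abort("need at least 5 values")
  s <- sd(x)
  if (!is.finite(s) || s < 1e-300) abort("zero variance: normality undefined")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), s))
  structure(tibble(statistic = unname(kt$statistic), p.value = kt$p.value),
            class = c("stat_test", "tbl_df", "tbl", "data.frame"))
}

#' Recover a net six-component displacement between landmark sets
#'
#' Least-squares rigid superposition of the named landmarks, re-expressed
#' as a translation at `origin` plus Euler angles — the displacement
#' summary a plan would have produced about that origin.
#'
#' @param sim_landmarks,postop_landmarks landmark tibbles
#' @param origin reference point for the translation component (default the
#'   occlusal centroid of `sim_landmarks`)
#' @param names landmarks used for the fit (default the tooth landmarks)
#' @return one-row [displacement6()] tibble
#' @export
recover_displacement <- function(sim_landmarks, postop_landmarks,
                                 origin = NULL, names = tooth_landmarks()) {
  s <- .as_points_matrix(sim_landmarks[match(names, sim_landmarks$name), ])
  p <- .as_points_matrix(postop_landmarks[match(names, postop_landmarks$name), ])
  tr <- superpose_rigid(s, p)
  if (is.null(origin)) {
    origin <- occlusal_plane(sim_landmarks)$plane$origin
  }
  shift <- transform_points(tr, origin) - origin
  e <- euler_decompose(tr$rotation)
  tibble(left_right = shift[1], advance_setback = shift[2],
         impaction_elongation = shift[3],
         pitch = e[["pitch"]], roll = e[["roll"]], yaw = e[["yaw"]])
}

#' Evaluate a surgical case
#'
#' The full evaluation pipeline: register the postoperative model to the
#' simulation model on the cranial base (so any difference in imaging pose
#' is removed), apply the recovered transform to the postoperative
#' landmarks, then compute per-landmark linear discrepancies, the
#' occlusal-plane angular discrepancy, and the net recovered displacement.
#'
#' @param sim_mesh,sim_landmarks simulation model and landmarks
#' @param postop_mesh,postop_landmarks postoperative model and landmarks
#' @param cranial_mask vertex indices of the cranial base on `postop_mesh`
#' @param icp an [icp_params()] for the cranial-base registration
#' @return an object of class `discrepancy_report`: `linear` (per-landmark
#'   tibble), `angular` (one-row tibble), `net` (recovered
#'   [displacement6()]), `registration` (the cranial-base
#'   `registration_result`), `postop_landmarks_registered`
#' @export
evaluate_case <- function(sim_mesh, sim_landmarks, postop_mesh,
                          postop_landmarks, cranial_mask,
                          icp = icp_params()) {
  # coarse initialisation from the shared (identical) landmarks: removes an
  # arbitrary scanner pose; the surgical displacement biases it by only a
  # few mm/deg, inside the basin of the masked surface ICP that follows
  shared <- intersect(sim_landmarks$name, postop_landmarks$name)
  init <- if (length(shared) >= 3L) {
    superpose_rigid(
      .as_points_matrix(postop_landmarks[match(shared, postop_landmarks$name), ]),
      .as_points_matrix(sim_landmarks[match(shared, sim_landmarks$name), ]))
  } else rt_identity()
  reg <- register_cranial_base(postop_mesh, sim_mesh, cranial_mask, icp,
                               init = init)
  post_lm <- transform_points(reg$transform, postop_landmarks)
  linear <- landmark_linear_discrepancy(sim_landmarks, post_lm)
  angular <- occlusal_angular_discrepancy(sim_landmarks, post_lm)
  net <- recover_displacement(sim_landmarks, post_lm)
  structure(list(linear = linear, angular = angular, net = net,
                 registration = reg,
                 postop_landmarks_registered = post_lm),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat("<discrepancy_report>\n")
  cat(sprintf("  cranial-base registration rms: %.4f mm\n", x$registration$rms))
  cat(sprintf("  mean |dx| %.3f  |dy| %.3f  |dz| %.3f  rms %.3f mm\n",
              mean(x$linear$adx), mean(x$linear$ady), mean(x$linear$adz),
              mean(x$linear$rms)))
  cat(sprintf("  occlusal pitch %.3f  roll %.3f  yaw %.3f deg\n",
              x$angular$pitch, x$angular$roll, x$angular$yaw))
  invisible(x)
}

#' Write a discrepancy report as CSV
#'
#' Per-landmark rows (`landmark, dx, dy, dz, rms`) followed by footer rows
#' for the angular discrepancy and the column means.
#'
#' @param report a `discrepancy_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "discrepancy_report"))
  lin <- report$linear
  rows <- data.frame(landmark = lin$landmark,
                     dx = lin$dx, dy = lin$dy, dz = lin$dz, rms = lin$rms)
  foot <- data.frame(
    landmark = c("mean_abs", "pitch_deg", "roll_deg", "yaw_deg"),
    dx = c(mean(lin$adx), report$angular$pitch, report$angular$roll,
           report$angular$yaw),
    dy = c(mean(lin$ady), NA, NA, NA),
    dz = c(mean(lin$adz), NA, NA, NA),
    rms = c(mean(lin$rms), NA, NA, NA))
  utils::write.csv(rbind(rows, foot), path, row.names = FALSE)
  invisible(path)
}
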