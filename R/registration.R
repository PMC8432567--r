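# Rigid surface registration: trimmed, k-d-tree-accelerated ICP, rigid
# coherent point drift (CPD), and the two pipelines built on them
# (dentition fusion and cranial-base registration).

#' Exact nearest neighbours between point sets
#'
#' For each query point, the index of (and distance to) the closest
#' reference point under the Euclidean metric, computed with a k-d tree.
#' Exact, not approximate.
#'
#' @param query,reference N x 3 point matrices (landmark tibbles accepted)
#' @return list with integer `index` (1-based into `reference`) and numeric
#'   `distance`
#' @export
nearest_neighbors <- function(query, reference) {
  q <- .as_points_matrix(query, "query")
  r <- .as_points_matrix(reference, "reference")
  if (nrow(r) == 0L) abort("reference point set is empty")
  .nn_kdtree(q, r)
}

.points_of <- function(x, arg = "points") {
  if (inherits(x, "triangle_mesh")) x$vertices else .as_points_matrix(x, arg)
}

#' ICP parameters
#'
#' The "modified" ICP is point-to-point ICP with two robustness devices:
#' correspondences farther than `max_distance` are rejected, and the worst
#' `trim` fraction of the survivors is discarded before the least-squares
#' fit. `trim = 0` with `max_distance = Inf` recovers the textbook
#' algorithm.
#'
#' @param max_iterations iteration cap (default 100)
#' @param tolerance convergence threshold on the change in kept-pair RMS
#'   between iterations, mm (default 1e-6)
#' @param max_distance correspondence rejection distance, mm (default `Inf`)
#' @param trim fraction of worst surviving pairs discarded, in \[0, 0.5\]
#' @return a list of class `icp_params`
#' @export
icp_params <- function(max_iterations = 100L, tolerance = 1e-6,
                       max_distance = Inf, trim = 0.1) {
  stopifnot(max_iterations >= 1, tolerance > 0, max_distance > 0,
            trim >= 0, trim <= 0.5)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, max_distance = max_distance,
                 trim = trim),
            class = "icp_params")
}

.registration_result <- function(transform, rms, iterations, converged,
                                 method, ...) {
  structure(list(transform = transform, rms = rms,
                 iterations = iterations, converged = converged,
                 method = method, ...),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result: %s>  rms %.6f mm, %d iterations, %s\n",
              x$method, x$rms, x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

#' Iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence (k-d tree), rejection of
#' pairs beyond `max_distance` and of the worst `trim` fraction, and a
#' closed-form rigid fit on the survivors, until the kept-pair RMS changes
#' by less than `tolerance` or the iteration cap is reached.
#'
#' @param source moving point set (N x 3 matrix or `triangle_mesh`)
#' @param target fixed point set or mesh
#' @param params an [icp_params()]
#' @param init initial `rigid_transform` (default identity)
#' @return a `registration_result` with fields `transform`, `rms`,
#'   `iterations`, `converged`
#' @export
icp_register <- function(source, target, params = icp_params(),
                         init = rt_identity()) {
  src <- .points_of(source, "source")
  tgt <- .points_of(target, "target")
  if (nrow(src) < 3L) abort("need at least 3 source points")
  stopifnot(inherits(params, "icp_params"))
  trans <- init
  rms_prev <- Inf; rms <- Inf
  converged <- FALSE
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    moved <- transform_points(trans, src)
    nn <- nearest_neighbors(moved, tgt)
    keep <- which(nn$distance <= params$max_distance)
    if (length(keep) == 0L) {
      abort("no overlap: every correspondence exceeds max_distance")
    }
    if (params$trim > 0 && length(keep) > 3L) {
      nkeep <- max(3L, ceiling((1 - params$trim) * length(keep)))
      keep <- keep[order(nn$distance[keep])[seq_len(nkeep)]]
    }
    trans <- superpose_rigid(src[keep, , drop = FALSE],
                             tgt[nn$index[keep], , drop = FALSE])
    resid <- transform_points(trans, src[keep, , drop = FALSE]) -
      tgt[nn$index[keep], , drop = FALSE]
    rms <- sqrt(mean(rowSums(resid^2)))
    if (abs(rms_prev - rms) < params$tolerance) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  .registration_result(trans, rms, it, converged, "icp")
}

#' CPD parameters
#'
#' @param w expected outlier weight in \[0, 1) (default 0.1)
#' @param max_iterations EM iteration cap (default 150)
#' @param tolerance convergence threshold on the change in the negative
#'   log-likelihood (default 1e-8)
#' @param estimate_scale also estimate an isotropic scale (default `FALSE`;
#'   dentition scan and CT are both metric mm of the same anatomy)
#' @return a list of class `cpd_params`
#' @export
cpd_params <- function(w = 0.1, max_iterations = 150L, tolerance = 1e-8,
                       estimate_scale = FALSE) {
  stopifnot(w >= 0, w < 1, max_iterations >= 1, tolerance > 0)
  structure(list(w = w, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 estimate_scale = isTRUE(estimate_scale)),
            class = "cpd_params")
}

#' Rigid coherent point drift registration
#'
#' EM over a Gaussian-mixture correspondence model: the moving points are
#' mixture centroids with a shared isotropic variance, plus a uniform
#' outlier component of weight `w`. The M-step solves the rigid (optionally
#' scaled) closed form; the variance is re-estimated each iteration. The
#' negative log-likelihood is non-increasing across EM iterations.
#'
#' @inheritParams icp_register
#' @param params a [cpd_params()]
#' @return a `registration_result`; extra fields `sigma2` (final variance),
#'   `scale`, and `objective` (the NLL trace)
#' @export
cpd_rigid_register <- function(source, target, params = cpd_params(),
                               init = rt_identity()) {
  y0 <- .points_of(source, "source")
  x <- .points_of(target, "target")
  if (nrow(y0) == 0L || nrow(x) == 0L) abort("point sets must be non-empty")
  stopifnot(inherits(params, "cpd_params"))
  y <- transform_points(init, y0)       # run EM in the init frame
  m <- nrow(y); n <- nrow(x); d <- 3
  w <- params$w
  sumx2 <- rowSums(x^2)
  # initial variance: mean squared distance between all pairs / d
  sigma2 <- (n * sum(y^2) + m * sum(x^2) -
               2 * sum(colSums(x) * colSums(y))) / (d * m * n)
  r <- diag(3); tvec <- c(0, 0, 0); s <- 1
  nll_trace <- numeric(0)
  nll_prev <- Inf
  converged <- FALSE
  degenerate <- FALSE
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    ty <- sweep(s * (y %*% t(r)), 2L, tvec, "+")
    # squared distance matrix n x m
    d2 <- outer(sumx2, rowSums(ty^2), "+") - 2 * x %*% t(ty)
    d2[d2 < 0] <- 0
    g <- exp(-d2 / (2 * sigma2))
    cnorm <- (2 * pi * sigma2)^(d / 2)
    uo <- if (w > 0) w / ((1 - w) * n) * m else 0   # outlier term (scaled)
    den <- rowSums(g) + uo * cnorm
    den[den < 1e-300] <- 1e-300
    p <- g / den                                   # n x m posteriors
    # negative log-likelihood of the mixture
    nll <- -sum(log((1 - w) / (m * cnorm) * den)) # den already includes outlier
    nll_trace <- c(nll_trace, nll)
    np <- sum(p)
    if (np < 1e-12) abort("no overlap: all mass assigned to the outlier component")
    p1 <- rowSums(p)     # length n
    pt1 <- colSums(p)    # length m
    mu_x <- colSums(x * p1) / np
    mu_y <- colSums(y * pt1) / np
    xh <- sweep(x, 2L, mu_x)
    yh <- sweep(y, 2L, mu_y)
    a <- t(xh) %*% (p %*% yh)
    dec <- svd(a)
    cdiag <- c(1, 1, sign(det(dec$u %*% t(dec$v))))
    r <- dec$u %*% diag(cdiag) %*% t(dec$v)
    denom_s <- sum(pt1 * rowSums(yh^2))
    s <- if (params$estimate_scale) sum(dec$d * cdiag) / denom_s else 1
    tvec <- mu_x - s * as.numeric(r %*% mu_y)
    # symmetric variance update, valid for fixed (s = 1) and estimated scale
    sigma2_new <- (sum(p1 * rowSums(xh^2)) + s^2 * denom_s -
                     2 * s * sum(dec$d * cdiag)) / (np * d)
    if (!is.finite(sigma2_new) || sigma2_new < 1e-12) {
      sigma2 <- max(sigma2_new, 1e-12)
      degenerate <- TRUE
      converged <- TRUE
      warn("CPD variance collapsed; treating as converged")
      break
    }
    sigma2 <- sigma2_new
    if (abs(nll_prev - nll) < params$tolerance * max(1, abs(nll))) {
      converged <- TRUE
      break
    }
    nll_prev <- nll
  }
  cpd_trans <- rigid_transform(r, tvec)
  total <- rt_compose(cpd_trans, init)
  moved <- sweep(s * (transform_points(init, y0) %*% t(r)), 2L, tvec, "+")
  nnres <- nearest_neighbors(moved, x)
  rms <- sqrt(mean(nnres$distance^2))
  .registration_result(total, rms, it, converged, "cpd",
                       sigma2 = sigma2, scale = s, objective = nll_trace,
                       degenerate_variance = degenerate)
}

#' Fuse an optical dentition scan with a CT skeletal model
#'
#' The fusion pipeline: trimmed ICP on the scan vertices against the CT
#' surface for the initial match, then rigid CPD seeded with the ICP result
#' to refine the alignment. Point sets larger than `max_points` are
#' deterministically subsampled (every k-th vertex) for the CPD stage to
#' bound the size of the correspondence matrix.
#'
#' @param scan dentition scan `triangle_mesh` (moving)
#' @param ct_model CT skeletal `triangle_mesh` (fixed)
#' @param icp an [icp_params()]
#' @param cpd a [cpd_params()]
#' @param max_points CPD subsample cap per set (default 600)
#' @param init initial `rigid_transform` seeding the ICP stage
#' @return a `registration_result` with the composed transform; fields
#'   `icp_result` and `cpd_result` keep the stage outputs
#' @export
fuse_dentition <- function(scan, ct_model, icp = icp_params(),
                           cpd = cpd_params(), max_points = 600L,
                           init = rt_identity()) {
  stopifnot(inherits(scan, "triangle_mesh"), inherits(ct_model, "triangle_mesh"))
  if (nrow(scan$faces) == 0L) abort("scan mesh has no faces")
  if (nrow(ct_model$faces) == 0L) abort("CT model mesh has no faces")
  stage1 <- icp_register(scan$vertices, ct_model$vertices, icp, init = init)
  sub <- function(v) {
    if (nrow(v) <= max_points) return(v)
    v[seq(1L, nrow(v), length.out = max_points), , drop = FALSE]
  }
  stage2 <- cpd_rigid_register(sub(scan$vertices), sub(ct_model$vertices),
                               cpd, init = stage1$transform)
  # final residual of the whole scan against the whole CT surface
  final_nn <- nearest_neighbors(transform_points(stage2$transform, scan$vertices),
                                ct_model$vertices)
  .registration_result(stage2$transform, sqrt(mean(final_nn$distance^2)),
                       stage1$iterations + stage2$iterations,
                       stage1$converged && stage2$converged, "fusion",
                       icp_result = stage1, cpd_result = stage2)
}

#' Cranial-base registration for accuracy evaluation
#'
#' Registers the moving model to the fixed model using only the vertices in
#' `mask` — the cranial base, which surgery does not expose — so that the
#' recovered transform reflects imaging pose only, never the surgical
#' displacement. The transform is then applied to the whole moving model
#' and its landmarks downstream.
#'
#' @param moving,fixed `triangle_mesh` objects
#' @param mask integer vertex indices on `moving` selecting the cranial
#'   base; at least 100 vertices
#' @param params an [icp_params()]
#' @param init initial transform
#' @return a `registration_result`
#' @export
register_cranial_base <- function(moving, fixed, mask,
                                  params = icp_params(),
                                  init = rt_identity()) {
  stopifnot(inherits(moving, "triangle_mesh"), inherits(fixed, "triangle_mesh"))
  mask <- unique(as.integer(mask))
  if (length(mask) < 100L) {
    abort("cranial-base mask must select at least 100 vertices")
  }
  if (min(mask) < 1L || max(mask) > nrow(moving$vertices)) {
    abort("mask indices out of range")
  }
  icp_register(moving$vertices[mask, , drop = FALSE], fixed$vertices,
               params, init = init)
}
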