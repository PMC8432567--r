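# Natural head position (NHP) reproduction: estimate the head rotation
# from a single facial photograph by POSIT (pose from orthography and
# scaling with iterations) and apply the rotation to the skeletal model.
#
# Camera convention: pinhole at the origin looking down +z;
# u = u0 + f * X/Z, v = v0 + f * Y/Z, with (u, v) in pixels.

#' Pinhole camera intrinsics
#'
#' @param focal focal length in pixels (> 0); 2000 px is a reasonable value
#'   for a portrait taken at 1.5 m with a standard lens
#' @param principal_point `(u0, v0)` in pixels (default image centre at the
#'   origin)
#' @return a list of class `camera_model`
#' @export
camera_model <- function(focal = 2000, principal_point = c(0, 0)) {
  stopifnot(is.finite(focal), focal > 0, length(principal_point) == 2L)
  structure(list(focal = focal,
                 principal_point = as.numeric(principal_point)),
            class = "camera_model")
}

#' Build a 2-D photograph landmark set
#'
#' @param ... named length-2 pixel coordinates `(u, v)`, or one named list
#' @return tibble with columns `name`, `u`, `v`
#' @export
photo_landmark_set <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots)[1])) {
    dots <- dots[[1]]
  }
  nm <- names(dots)
  if (is.null(nm) || any(nm == "")) abort("all photo landmarks must be named")
  if (anyDuplicated(nm)) abort("duplicate photo landmark name")
  m <- do.call(rbind, lapply(dots, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2L || !all(is.finite(p))) abort("photo landmarks are (u, v) pixels")
    p
  }))
  tibble(name = nm, u = m[, 1], v = m[, 2])
}

#' Read / write photo landmarks as JSON (`{name: [u, v]}` in pixels)
#' @param path file path
#' @return a photo landmark tibble
#' @export
read_photo_landmarks <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (.json_has_duplicate_keys(txt)) abort("duplicate landmark name in file")
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  photo_landmark_set(obj)
}

#' @rdname read_photo_landmarks
#' @param plm a photo landmark tibble
#' @export
write_photo_landmarks <- function(plm, path) {
  stopifnot(all(c("name", "u", "v") %in% names(plm)))
  obj <- setNames(lapply(seq_len(nrow(plm)), function(i) c(plm$u[i], plm$v[i])),
                  plm$name)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

.model_condition <- function(m) {
  sv <- svd(sweep(m, 2L, colMeans(m)))$d
  if (sv[3] < 1e-300) return(Inf)
  sv[1] / sv[3]
}

#' POSIT pose estimation from one photograph
#'
#' Classic POSIT: starting from the scaled-orthographic approximation, solve
#' the linear system given by the pseudo-inverse of the (reference-centred)
#' model-point matrix for the two scaled rotation rows, orthonormalise to a
#' proper rotation, update the perspective correction terms
#' `eps_i = (R3 . P_i) / Tz`, and iterate until the corrections settle.
#'
#' @param image_points photo landmark tibble (`name`, `u`, `v` in pixels)
#' @param model_points 3-D landmark tibble (`name`, `x`, `y`, `z` in mm)
#' @param camera a [camera_model()]
#' @param tolerance convergence threshold on the max change of the
#'   correction terms (default 1e-8)
#' @param max_iterations cap (default 50)
#' @return a list of class `pose_estimate`: `rotation`, `translation`
#'   (camera frame, mm), `iterations`, `residual` (RMS reprojection error in
#'   pixels), `converged`
#' @export
posit_pose <- function(image_points, model_points, camera = camera_model(),
                       tolerance = 1e-8, max_iterations = 50L) {
  stopifnot(inherits(camera, "camera_model"))
  .lm_check(model_points)
  common <- intersect(model_points$name, image_points$name)
  if (length(common) < 4L) {
    abort("correspondence error: need at least 4 landmarks shared by photo and model")
  }
  mp <- .as_points_matrix(model_points[match(common, model_points$name), ])
  ip <- cbind(image_points$u, image_points$v)[match(common, image_points$name), ,
                                              drop = FALSE]
  if (.model_condition(mp) > 1e6) {
    abort("degenerate geometry: model landmarks are coplanar or collinear")
  }
  f <- camera$focal
  xc <- ip[, 1] - camera$principal_point[1]
  yc <- ip[, 2] - camera$principal_point[2]
  n <- nrow(mp)
  p0 <- mp[1, ]
  pm <- sweep(mp[-1, , drop = FALSE], 2L, p0)   # reference-centred vectors
  b <- .pseudo_inverse(pm)                      # 3 x (n-1)
  eps <- rep(0, n - 1L)
  rot <- diag(3); tz <- f
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    xp <- xc[-1] * (1 + eps) - xc[1]
    yp <- yc[-1] * (1 + eps) - yc[1]
    ivec <- as.numeric(b %*% xp)
    jvec <- as.numeric(b %*% yp)
    s1 <- sqrt(sum(ivec^2)); s2 <- sqrt(sum(jvec^2))
    if (s1 < 1e-12 || s2 < 1e-12) abort("degenerate geometry: POSIT scale collapsed")
    s <- (s1 + s2) / 2
    r1 <- ivec / s1; r2 <- jvec / s2
    # nearest proper rotation to the two estimated rows
    m3 <- rbind(r1, r2, .cross3(r1, r2))
    dec <- svd(m3)
    rot <- dec$u %*% diag(c(1, 1, sign(det(dec$u %*% t(dec$v))))) %*% t(dec$v)
    tz <- f / s
    eps_new <- as.numeric(pm %*% rot[3, ]) / tz
    delta <- max(abs(eps_new - eps))
    eps <- eps_new
    if (delta < tolerance) { converged <- TRUE; break }
    if (it >= max_iterations) break
  }
  trans <- c(xc[1] / s, yc[1] / s, f / s)   # camera coords of the reference point
  # Gauss-Newton polish of the POSIT pose: minimise the pixel reprojection
  # error over rotation and translation (POSIT is exact without noise but
  # not least-squares under noisy landmarks)
  gn <- .refine_pose(rot, trans, sweep(mp, 2L, p0), xc, yc, f)
  rot <- gn$rot; trans <- gn$trans
  # reprojection residual: camera point of p is R (p - p0) + T
  pc <- sweep(sweep(mp, 2L, p0) %*% t(rot), 2L, trans, "+")
  uv <- cbind(camera$principal_point[1] + f * pc[, 1] / pc[, 3],
              camera$principal_point[2] + f * pc[, 2] / pc[, 3])
  residual <- sqrt(mean(rowSums((uv - ip)^2)))
  structure(list(rotation = rot, translation = trans, iterations = it,
                 residual = residual, converged = converged,
                 landmarks = common),
            class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  e <- euler_decompose(x$rotation)
  cat(sprintf(
    "<pose_estimate> pitch %.3f  roll %.3f  yaw %.3f deg; residual %.4f px (%d iter)\n",
    e[["pitch"]], e[["roll"]], e[["yaw"]], x$residual, x$iterations))
  invisible(x)
}

# Levenberg-damped Gauss-Newton on (rotation, translation), image residuals
# in pixels; pm is the reference-centred model matrix, (xc, yc) the
# principal-point-centred image coordinates
.refine_pose <- function(rot, trans, pm, xc, yc, f, iters = 15L) {
  skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0),
                             3, 3)
  cost <- function(rot, trans) {
    pc <- sweep(pm %*% t(rot), 2L, trans, "+")
    if (any(pc[, 3] <= 1e-9)) return(list(r = NULL, c = Inf, pc = pc))
    r <- c(xc - f * pc[, 1] / pc[, 3], yc - f * pc[, 2] / pc[, 3])
    list(r = r, c = sum(r^2), pc = pc)
  }
  cur <- cost(rot, trans)
  if (!is.finite(cur$c)) return(list(rot = rot, trans = trans))
  lambda <- 1e-6
  for (k in seq_len(iters)) {
    pc <- cur$pc
    n <- nrow(pc)
    ju <- matrix(0, n, 6); jv <- matrix(0, n, 6)
    rp <- pm %*% t(rot)                       # rotated (reference-centred) points
    for (i in seq_len(n)) {
      dproj <- rbind(c(f / pc[i, 3], 0, -f * pc[i, 1] / pc[i, 3]^2),
                     c(0, f / pc[i, 3], -f * pc[i, 2] / pc[i, 3]^2))
      dxc <- cbind(-skew(rp[i, ]), diag(3))   # wrt (omega, t)
      jj <- dproj %*% dxc
      ju[i, ] <- jj[1, ]; jv[i, ] <- jj[2, ]
    }
    jac <- rbind(ju, jv)
    g <- crossprod(jac, cur$r)
    h <- crossprod(jac) + lambda * diag(6)
    step <- tryCatch(solve(h, g), error = function(e) NULL)
    if (is.null(step)) break
    w <- as.numeric(step[1:3])
    ang <- sqrt(sum(w^2))
    dr <- if (ang < 1e-14) diag(3) else {
      kx <- skew(w / ang)
      diag(3) + sin(ang) * kx + (1 - cos(ang)) * kx %*% kx
    }
    cand_rot <- dr %*% rot
    cand_trans <- trans + as.numeric(step[4:6])
    cand <- cost(cand_rot, cand_trans)
    if (is.finite(cand$c) && cand$c < cur$c) {
      rot <- cand_rot; trans <- cand_trans; cur <- cand
      lambda <- max(lambda / 4, 1e-10)
      if (cur$c < 1e-24) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  # re-project to the nearest proper rotation (guards accumulated drift)
  dec <- svd(rot)
  rot <- dec$u %*% diag(c(1, 1, sign(det(dec$u %*% t(dec$v))))) %*% t(dec$v)
  list(rot = rot, trans = trans)
}

.pseudo_inverse <- function(m) {
  dec <- svd(m)
  pos <- dec$d > 1e-12 * dec$d[1]
  dec$v[, pos, drop = FALSE] %*%
    (t(dec$u[, pos, drop = FALSE]) / dec$d[pos])
}

#' Reproduce the natural head position of a skeletal model
#'
#' Runs [posit_pose()] on the facial landmarks, keeps only the rotation (the
#' NHP is an orientation, so the camera-frame translation is discarded), and
#' applies it to the model and its landmarks.
#'
#' @param model `triangle_mesh` of the CT skeletal model
#' @param model_landmarks 3-D landmark tibble including at least 4
#'   non-coplanar facial landmarks
#' @param photo_landmarks photo landmark tibble
#' @param camera a [camera_model()]
#' @return list: `mesh` (rotated model), `landmarks` (rotated), `rotation`,
#'   `pose` (the full `pose_estimate`)
#' @export
reproduce_nhp <- function(model, model_landmarks, photo_landmarks,
                          camera = camera_model()) {
  stopifnot(inherits(model, "triangle_mesh"))
  pose <- posit_pose(photo_landmarks, model_landmarks, camera)
  rot <- rigid_transform(pose$rotation, c(0, 0, 0))
  list(mesh = transform_mesh(rot, model),
       landmarks = transform_points(rot, model_landmarks),
       rotation = pose$rotation,
       pose = pose)
}
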