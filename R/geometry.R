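# Rigid-body mathematics shared by every stage of the workflow.
#
# Conventions used throughout the package:
#   * right-handed frame, +x toward the patient's left, +y anterior
#     (advance), +z superior (elongation); units are mm.
#   * Euler angles use fixed (extrinsic) axes, R = Rz(yaw) %*% Ry(roll) %*%
#     Rx(pitch), degrees at every interface, radians internally.

DEG <- pi / 180

.as_point3 <- function(p, arg = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    abort(sprintf("`%s` must be 3 finite coordinates", arg))
  }
  p
}

.as_points_matrix <- function(x, arg = "points") {
  if (is_tibble(x) || is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    m <- cbind(x$x, x$y, x$z)
    if (!is.null(x$name)) rownames(m) <- x$name
  } else {
    m <- as.matrix(x)
    if (length(m) == 3L) m <- matrix(m, 1L, 3L)
  }
  if (ncol(m) != 3L) abort(sprintf("`%s` must be an N x 3 set of points", arg))
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) abort(sprintf("`%s` contains non-finite coordinates", arg))
  m
}

.check_rotation <- function(r, tol = 1e-9) {
  r <- as.matrix(r)
  if (!all(dim(r) == c(3L, 3L))) abort("rotation must be a 3 x 3 matrix")
  if (max(abs(crossprod(r) - diag(3))) > tol) {
    abort("rotation matrix is not orthonormal within tolerance")
  }
  if (abs(det(r) - 1) > tol) {
    abort("rotation matrix must have determinant +1 (no reflections)")
  }
  r
}

#' Rigid transform (proper rotation + translation)
#'
#' The currency of every registration and planning stage: a 3 x 3 proper
#' rotation matrix together with a translation vector in mm. Acting on a
#' point p gives `R p + t`.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1
#' @param translation length-3 numeric vector (mm)
#' @return an object of class `rigid_transform`
#' @examples
#' t1 <- rigid_transform(euler_compose(10, 0, 0), c(1, 2, 3))
#' transform_points(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  structure(
    list(rotation = .check_rotation(rotation),
         translation = .as_point3(translation, "translation")),
    class = "rigid_transform"
  )
}

#' Identity rigid transform
#' @return a `rigid_transform` that leaves every point unchanged
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  e <- euler_decompose(x$rotation)
  cat("<rigid_transform>\n")
  cat(sprintf("  translation (mm): %8.4f %8.4f %8.4f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  rotation (deg)  : pitch %7.4f  roll %7.4f  yaw %7.4f\n",
              e[["pitch"]], e[["roll"]], e[["yaw"]]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform that applies `b` first and then
#' `a`, i.e. `x -> a(b(x))`.
#'
#' @param a,b `rigid_transform` objects
#' @return a `rigid_transform`
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
rt_inverse <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rigid_transform(t(x$rotation), as.numeric(-t(x$rotation) %*% x$translation))
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`
#' @param points an N x 3 matrix, a length-3 vector, or a data frame with
#'   `x`, `y`, `z` columns (a landmark tibble passes through with its other
#'   columns intact)
#' @return points of the same shape/type as the input
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is_tibble(points) || is.data.frame(points)) {
    m <- .as_points_matrix(points)
    m2 <- m %*% t(transform$rotation)
    out <- points
    out$x <- unname(m2[, 1]) + transform$translation[1]
    out$y <- unname(m2[, 2]) + transform$translation[2]
    out$z <- unname(m2[, 3]) + transform$translation[3]
    return(out)
  }
  m <- .as_points_matrix(points)
  out <- sweep(m %*% t(transform$rotation), 2L, transform$translation, "+")
  if (is.numeric(points) && is.null(dim(points))) out <- drop(out)
  out
}

#' Least-squares rigid superposition (Kabsch / Horn)
#'
#' Finds the rigid transform minimising `sum(|T(source_i) - target_i|^2)`
#' over proper rotations: the SVD closed form with determinant correction,
#' so a reflection is never returned even for mirrored inputs.
#'
#' @param source,target paired N x 3 point sets (N >= 3, non-collinear)
#' @return a `rigid_transform`; attribute `rmsd` carries the residual
#'   root-mean-square distance in mm
#' @examples
#' src <- matrix(rnorm(12), 4, 3)
#' tt <- rigid_transform(euler_compose(0, 0, 25), c(1, 2, 3))
#' superpose_rigid(src, transform_points(tt, src))
#' @export
superpose_rigid <- function(source, target) {
  s <- .as_points_matrix(source, "source")
  t_ <- .as_points_matrix(target, "target")
  if (nrow(s) != nrow(t_)) abort("source and target must pair point-for-point")
  if (nrow(s) < 3L) abort("degenerate geometry: need at least 3 paired points")
  cs <- colMeans(s); ct <- colMeans(t_)
  sh <- sweep(s, 2L, cs); th <- sweep(t_, 2L, ct)
  # collinearity check on the source configuration
  sv <- svd(sh)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1)) {
    abort("degenerate geometry: points are collinear")
  }
  h <- crossprod(sh, th)        # 3x3 covariance
  dec <- svd(h)
  d <- sign(det(dec$v %*% t(dec$u)))
  r <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- ct - as.numeric(r %*% cs)
  out <- rigid_transform(r, tr)
  res <- transform_points(out, s) - t_
  attr(out, "rmsd") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Compose Euler angles into a rotation matrix
#'
#' Fixed (extrinsic) axes: `R = Rz(yaw) Ry(roll) Rx(pitch)`, with pitch about
#' the left-right x-axis, roll about the antero-posterior y-axis, and yaw
#' about the vertical z-axis. Angles in degrees.
#'
#' @param pitch,roll,yaw angles in degrees; `pitch` may also be a length-3
#'   vector `(pitch, roll, yaw)`
#' @return a 3 x 3 rotation matrix
#' @export
euler_compose <- function(pitch, roll = NULL, yaw = NULL) {
  if (is.null(roll) && length(pitch) == 3L) {
    yaw <- pitch[[3]]; roll <- pitch[[2]]; pitch <- pitch[[1]]
  }
  stopifnot(is.finite(pitch), is.finite(roll), is.finite(yaw))
  a <- pitch * DEG; b <- roll * DEG; c <- yaw * DEG
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Decompose a rotation matrix into Euler angles
#'
#' Inverse of [euler_compose()] under the same fixed-axes z-y-x convention.
#' At gimbal lock (|roll| = 90 deg) the pitch/yaw split is not unique; the
#' yaw is then set to 0, the remaining angle folded into pitch, and a
#' `gimbal_lock` attribute is set with a warning.
#'
#' @param r a 3 x 3 rotation matrix
#' @return named numeric vector `c(pitch =, roll =, yaw =)` in degrees, each
#'   in (-180, 180]
#' @export
euler_decompose <- function(r) {
  r <- .check_rotation(r, tol = 1e-6)
  lock <- FALSE
  sb <- -r[3, 1]
  if (abs(abs(sb) - 1) < 1e-9) {
    lock <- TRUE
    warn("gimbal lock: |roll| = 90 degrees; yaw set to 0")
    roll <- if (sb > 0) 90 else -90
    yaw <- 0
    # with yaw = 0: r[1,2] = sb*sin(a) ... fold everything into pitch
    pitch <- atan2(sign(sb) * r[1, 2], r[2, 2]) / DEG
  } else {
    roll <- asin(max(-1, min(1, sb))) / DEG
    pitch <- atan2(r[3, 2], r[3, 3]) / DEG
    yaw <- atan2(r[2, 1], r[1, 1]) / DEG
  }
  wrap <- function(x) ifelse(x <= -180, x + 360, ifelse(x > 180, x - 360, x))
  out <- c(pitch = wrap(pitch), roll = wrap(roll), yaw = wrap(yaw))
  if (lock) attr(out, "gimbal_lock") <- TRUE
  out
}

#' Rotation about an arbitrary center
#'
#' Builds the rigid transform rotating by `angle` degrees about the axis
#' through `center`; `center` is a fixed point of the result.
#'
#' @param center length-3 point (mm)
#' @param axis length-3 direction, must have unit norm (tolerance 1e-6)
#' @param angle rotation angle in degrees
#' @return a `rigid_transform`
#' @export
rotation_about_center <- function(center, axis, angle) {
  center <- .as_point3(center, "center")
  axis <- .as_point3(axis, "axis")
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) abort("axis must be nonzero")
  if (abs(nrm - 1) > 1e-6) abort("axis must be a unit vector")
  th <- angle * DEG
  k <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  r <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  rigid_transform(r, center - as.numeric(r %*% center))
}

#' An oriented plane in 3-space
#'
#' @param origin a point on the plane (mm)
#' @param normal plane normal; normalised internally
#' @return an object of class `plane3`
#' @export
plane3 <- function(origin, normal) {
  origin <- .as_point3(origin, "origin")
  normal <- .as_point3(normal, "normal")
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) abort("plane normal must be nonzero")
  structure(list(origin = origin, normal = normal / nrm), class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> origin (%.3f, %.3f, %.3f)  normal (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distances from points to a plane
#' @param plane a [plane3()]
#' @param points N x 3 matrix or length-3 vector
#' @return numeric vector of signed distances (positive on the normal side)
#' @export
plane_distance <- function(plane, points) {
  stopifnot(inherits(plane, "plane3"))
  m <- .as_points_matrix(points)
  drop(sweep(m, 2L, plane$origin) %*% plane$normal)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
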