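# Surgical planning and simulation: plane-cut virtual osteotomy, segment
# displacement (axis translations, center/target/goal rotations), plan
# application to the maxillomandibular complex, and occlusal-plane
# construction.

#' Cut a mesh by a plane
#'
#' Vertices are partitioned by signed distance to the plane; triangles that
#' cross it are split along the intersection segment (each side of a split
#' triangle is re-triangulated from its clipped polygon). The cut is left
#' open — no caps — so the summed surface area of the two outputs equals
#' the input area.
#'
#' @param mesh a `triangle_mesh`
#' @param plane a [plane3()]
#' @return list with `triangle_mesh` elements `positive` and `negative`
#'   (sides by the plane normal); if the plane misses the mesh one side is
#'   empty and a warning is raised
#' @export
cut_mesh_by_plane <- function(mesh, plane) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(plane, "plane3"))
  d <- plane_distance(plane, mesh$vertices)
  eps <- 1e-12
  side <- function(keep_positive) {
    vs <- list(); fs <- list(); nv <- 0L
    sgn <- if (keep_positive) 1 else -1
    for (i in seq_len(nrow(mesh$faces))) {
      tri <- mesh$faces[i, ]
      dd <- sgn * d[tri]
      pts <- mesh$vertices[tri, , drop = FALSE]
      if (all(dd >= -eps)) {            # whole triangle on this side
        vs[[length(vs) + 1L]] <- pts
        fs[[length(fs) + 1L]] <- nv + 1:3
        nv <- nv + 3L
      } else if (all(dd <= eps)) {
        # entirely on the other side
      } else {
        poly <- .clip_triangle(pts, dd, eps)
        if (nrow(poly) >= 3L) {
          vs[[length(vs) + 1L]] <- poly
          fan <- cbind(nv + 1L, nv + seq(2L, nrow(poly) - 1L),
                       nv + seq(3L, nrow(poly)))
          fs[[length(fs) + 1L]] <- fan
          nv <- nv + nrow(poly)
        }
      }
    }
    if (length(vs) == 0L) {
      return(triangle_mesh(matrix(numeric(0), 0, 3), NULL))
    }
    fmat <- do.call(rbind, lapply(fs, function(f) matrix(f, ncol = 3L)))
    merge_vertices(triangle_mesh(do.call(rbind, vs), fmat))
  }
  pos <- side(TRUE); neg <- side(FALSE)
  if (nrow(pos$faces) == 0L || nrow(neg$faces) == 0L) {
    warn("cut plane does not intersect the mesh; one side is empty")
  }
  list(positive = pos, negative = neg)
}

# Sutherland-Hodgman clip of one triangle against d >= 0
.clip_triangle <- function(pts, dd, eps) {
  out <- matrix(numeric(0), 0, 3)
  for (k in 1:3) {
    k2 <- if (k == 3L) 1L else k + 1L
    a <- pts[k, ]; b <- pts[k2, ]
    da <- dd[k]; db <- dd[k2]
    if (da >= -eps) out <- rbind(out, a)
    if ((da > eps && db < -eps) || (da < -eps && db > eps)) {
      t_ <- da / (da - db)
      out <- rbind(out, a + t_ * (b - a))
    }
  }
  out
}

#' Translate a bone segment
#'
#' Moves every vertex and landmark by exactly `(dx, dy, dz)` — the
#' left-right, advance-setback and impaction-elongation displacements of a
#' surgical plan.
#'
#' @param mesh a `triangle_mesh`
#' @param landmarks landmark tibble (may be `NULL`)
#' @param dx,dy,dz displacements in mm
#' @return list: `mesh`, `landmarks`, `transform`
#' @export
translate_segment <- function(mesh, landmarks, dx, dy, dz) {
  stopifnot(all(is.finite(c(dx, dy, dz))))
  tr <- rigid_transform(diag(3), c(dx, dy, dz))
  list(mesh = transform_mesh(tr, mesh),
       landmarks = if (is.null(landmarks)) NULL else transform_points(tr, landmarks),
       transform = tr)
}

#' Rotate a bone segment toward a goal point
#'
#' The rotation is taken about the axis `(target - center) x (goal -
#' center)`, by the angle between the two center-relative directions, so the
#' target *direction* is carried exactly onto the goal direction — the
#' minimal rotation doing so. Distances to the center are preserved, so the
#' goal point fixes a direction, not a radius.
#'
#' @param mesh a `triangle_mesh`
#' @param landmarks landmark tibble (may be `NULL`)
#' @param center rotation center (mm)
#' @param target point whose direction from `center` is to be moved
#' @param goal point whose direction from `center` it is moved onto
#' @return list: `mesh`, `landmarks`, `transform`
#' @export
rotate_segment_to_goal <- function(mesh, landmarks, center, target, goal) {
  center <- .as_point3(center, "center")
  u <- .as_point3(target, "target") - center
  v <- .as_point3(goal, "goal") - center
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) abort("target and goal must differ from center")
  u <- u / nu; v <- v / nv
  cr <- .cross3(u, v)
  ncr <- sqrt(sum(cr^2))
  dt <- sum(u * v)
  if (ncr < 1e-12) {
    if (dt > 0) {
      tr <- rt_identity()
    } else {
      abort("ambiguous axis: target and goal directions are anti-parallel")
    }
  } else {
    angle <- atan2(ncr, dt) / DEG
    tr <- rotation_about_center(center, cr / ncr, angle)
  }
  list(mesh = transform_mesh(tr, mesh),
       landmarks = if (is.null(landmarks)) NULL else transform_points(tr, landmarks),
       transform = tr)
}

#' Plan steps
#'
#' A surgical plan is an ordered list of steps per segment: linear
#' translations along the anatomical axes, then rotations specified by a
#' rotation center, a target point and a goal point.
#'
#' @param dx,dy,dz translation in mm
#' @return a plan step object
#' @export
plan_translate <- function(dx, dy, dz) {
  stopifnot(all(is.finite(c(dx, dy, dz))))
  structure(list(type = "translate", delta = c(dx, dy, dz)),
            class = "plan_step")
}

#' @rdname plan_translate
#' @param center,target,goal points defining the rotation (mm)
#' @export
plan_rotate <- function(center, target, goal) {
  center <- .as_point3(center, "center")
  target <- .as_point3(target, "target")
  goal <- .as_point3(goal, "goal")
  if (sqrt(sum((target - center)^2)) < 1e-12 ||
      sqrt(sum((goal - center)^2)) < 1e-12) {
    abort("rotation step requires target != center and goal != center")
  }
  structure(list(type = "rotate", center = center, target = target, goal = goal),
            class = "plan_step")
}

#' Assemble a surgical plan
#' @param ... `plan_step` objects (or one list of them), applied in order
#' @return an object of class `surgical_plan`
#' @export
surgical_plan <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && !inherits(steps[[1]], "plan_step")) {
    steps <- steps[[1]]
  }
  if (!all(vapply(steps, inherits, logical(1), "plan_step"))) {
    abort("a surgical plan is built from plan_translate()/plan_rotate() steps")
  }
  structure(list(steps = steps), class = "surgical_plan")
}

#' Read / write a surgical plan as JSON
#'
#' Format: `{"steps": [{"translate": [dx,dy,dz]} | {"rotate": {"center":
#' [...], "target": [...], "goal": [...]}}]}`.
#'
#' @param path file path
#' @return a `surgical_plan`
#' @export
read_plan <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  steps <- lapply(obj$steps, function(s) {
    if (!is.null(s$translate)) {
      d <- as.numeric(unlist(s$translate))
      plan_translate(d[1], d[2], d[3])
    } else if (!is.null(s$rotate)) {
      plan_rotate(as.numeric(unlist(s$rotate$center)),
                  as.numeric(unlist(s$rotate$target)),
                  as.numeric(unlist(s$rotate$goal)))
    } else {
      abort("plan step must be 'translate' or 'rotate'")
    }
  })
  surgical_plan(steps)
}

#' @rdname read_plan
#' @param plan a `surgical_plan`
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "surgical_plan"))
  steps <- lapply(plan$steps, function(s) {
    if (s$type == "translate") list(translate = s$delta)
    else list(rotate = list(center = s$center, target = s$target, goal = s$goal))
  })
  jsonlite::write_json(list(steps = steps), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Six-component displacement summary
#'
#' Translations along, and Euler rotations about, the anatomical axes:
#' left-right (x, mm), advance-setback (y, mm), impaction-elongation (z,
#' mm), pitch (x, deg), roll (y, deg), yaw (z, deg).
#'
#' @param transform a `rigid_transform`
#' @return a one-row tibble with columns `left_right`, `advance_setback`,
#'   `impaction_elongation`, `pitch`, `roll`, `yaw`
#' @export
displacement6 <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  e <- euler_decompose(transform$rotation)
  tibble(left_right = transform$translation[1],
         advance_setback = transform$translation[2],
         impaction_elongation = transform$translation[3],
         pitch = e[["pitch"]], roll = e[["roll"]], yaw = e[["yaw"]])
}

#' Apply a surgical plan to the maxillomandibular complex
#'
#' Applies the steps in order (translations first in the usual clinical
#' order, but any order given is respected), composes the net rigid
#' transform, and summarises it as a six-component displacement
#' (translation components of the net transform; Euler decomposition of the
#' net rotation).
#'
#' @param mesh preoperative MMC `triangle_mesh`
#' @param landmarks landmark tibble carried along with the segment
#' @param plan a `surgical_plan`
#' @return list: `mesh` (simulation model), `landmarks`, `transform` (net),
#'   `summary` (one-row [displacement6()] tibble)
#' @export
apply_plan <- function(mesh, landmarks, plan) {
  stopifnot(inherits(plan, "surgical_plan"))
  net <- rt_identity()
  cur_mesh <- mesh; cur_lm <- landmarks
  for (s in plan$steps) {
    res <- if (s$type == "translate") {
      translate_segment(cur_mesh, cur_lm, s$delta[1], s$delta[2], s$delta[3])
    } else {
      rotate_segment_to_goal(cur_mesh, cur_lm, s$center, s$target, s$goal)
    }
    cur_mesh <- res$mesh; cur_lm <- res$landmarks
    net <- rt_compose(res$transform, net)
  }
  list(mesh = cur_mesh, landmarks = cur_lm, transform = net,
       summary = displacement6(net))
}

#' Maxillary occlusal plane and frame
#'
#' The occlusal plane passes through the mesiobuccal cusps of the right and
#' left first upper molars and the central incisors (taken as the
#' `incisor_midpoint` landmark if present, otherwise the midpoint of the
#' right and left incisor landmarks). The attached frame has x from the
#' right to the left molar cusp, z along the plane normal oriented into the
#' +z hemisphere (ties broken toward +y), and y completing the right-handed
#' triad.
#'
#' @param landmarks a landmark tibble
#' @return list: `plane` ([plane3()] through the three points, origin at
#'   their centroid), `frame` (3 x 3 rotation whose columns are the axes)
#' @export
occlusal_plane <- function(landmarks) {
  .lm_check(landmarks)
  pr <- landmark_point(landmarks, "mb_cusp_molar1_r")
  pl <- landmark_point(landmarks, "mb_cusp_molar1_l")
  pi_ <- if ("incisor_midpoint" %in% landmarks$name) {
    landmark_point(landmarks, "incisor_midpoint")
  } else if (all(c("incisor_r", "incisor_l") %in% landmarks$name)) {
    (landmark_point(landmarks, "incisor_r") +
       landmark_point(landmarks, "incisor_l")) / 2
  } else {
    abort("occlusal plane needs incisor_midpoint or both incisor landmarks")
  }
  xv <- pl - pr
  nx <- sqrt(sum(xv^2))
  if (nx < 1e-12) abort("degenerate geometry: molar cusps coincide")
  xv <- xv / nx
  w <- pi_ - pr
  nrm <- .cross3(xv, w)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-9 * max(1, sqrt(sum(w^2)))) {
    abort("degenerate geometry: occlusal landmarks are collinear")
  }
  nrm <- nrm / nn
  if (nrm[3] < 0 || (abs(nrm[3]) < 1e-12 && nrm[2] < 0)) nrm <- -nrm
  yv <- .cross3(nrm, xv)
  frame <- cbind(xv, yv / sqrt(sum(yv^2)), nrm)
  dimnames(frame) <- NULL
  list(plane = plane3((pr + pl + pi_) / 3, nrm),
       frame = .check_rotation(frame, tol = 1e-6))
}
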