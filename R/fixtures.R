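# Synthetic inputs with known ground truth: a stylised skull phantom
# (ellipsoid cranium + dental-arch tube with cusp bumps), partially
# overlapping noisy dentition scans, perspective photo projections under a
# known head rotation, and perturbed "postoperative" cases. The phantom is
# not anatomical: the algorithms only need region structure, asymmetric
# surface detail, and named landmarks.

# run `code` under a seed without disturbing the caller's RNG stream;
# each generator offsets the user seed so streams never interleave
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

#' Phantom specification
#'
#' @param seed integer seed; every phantom output is reproducible per seed
#' @param resolution target vertex count (>= 100)
#' @param noise_sd surface noise for derived scans, mm
#' @param overlap scan overlap fraction in (0, 1]
#' @return a list of class `phantom_spec`
#' @export
phantom_spec <- function(seed = 1L, resolution = 1400L, noise_sd = 0,
                         overlap = 1) {
  stopifnot(noise_sd >= 0, overlap > 0, overlap <= 1)
  if (resolution < 100L) abort("resolution must be at least 100 vertices")
  structure(list(seed = as.integer(seed), resolution = as.integer(resolution),
                 noise_sd = noise_sd, overlap = overlap),
            class = "phantom_spec")
}

# canonical landmark template (mm) in the phantom frame:
# +x patient-left, +y anterior, +z superior; occlusal plane near z = -6
.landmark_template <- function() {
  landmark_set(
    incisor_r = c(-4, 69.5, -6), incisor_l = c(4, 69.5, -6),
    canine_r = c(-10.5, 65, -6), canine_l = c(10.5, 65, -6),
    molar1_r = c(-16.5, 56.4, -6), molar1_l = c(16.5, 56.4, -6),
    molar2_r = c(-24, 41.2, -6), molar2_l = c(24, 41.2, -6),
    mb_cusp_molar1_r = c(-20, 57.5, -5), mb_cusp_molar1_l = c(20, 57.5, -5),
    incisor_midpoint = c(0, 69.5, -6),
    pronasale = c(0, 92, 25),
    exocanthion_r = c(-45, 55, 50), exocanthion_l = c(45, 55, 50),
    endocanthion_r = c(-18, 62, 50), endocanthion_l = c(18, 62, 50),
    cheilion_r = c(-24, 75, -12), cheilion_l = c(24, 75, -12))
}

# ellipsoid with smooth seeded surface irregularity (so rigid registration
# can lock the rotation; a perfect ellipsoid has too much symmetry)
.make_cranium <- function(n_target) {
  nu <- max(12L, round(sqrt(n_target * 1.5)))
  nv <- max(8L, round(nu * 2 / 3))
  th <- seq(0, pi, length.out = nv + 1L)[2:nv]          # rings
  ph <- seq(0, 2 * pi, length.out = nu + 1L)[seq_len(nu)]
  grid <- expand.grid(ph = ph, th = th)
  # random low-order angular lobes; strong enough that the surface has no
  # rotational symmetry left for registration to slide along
  nk <- 6L
  amp <- rnorm(nk, 0, 0.06)
  f1 <- sample(1:2, nk, replace = TRUE)
  f2 <- sample(1:2, nk, replace = TRUE)
  pha <- runif(nk, 0, 2 * pi)
  phb <- runif(nk, 0, 2 * pi)
  bump <- rep(0, nrow(grid))
  for (k in seq_len(nk)) {
    bump <- bump + amp[k] * sin(f1[k] * grid$th + pha[k]) *
      sin(f2[k] * grid$ph + phb[k])
  }
  r <- 1 + bump
  ax <- c(55, 65, 45); ctr <- c(0, 10, 55)
  v <- cbind(ctr[1] + ax[1] * r * sin(grid$th) * cos(grid$ph),
             ctr[2] + ax[2] * r * sin(grid$th) * sin(grid$ph),
             ctr[3] + ax[3] * r * cos(grid$th))
  npole <- c(ctr[1], ctr[2], ctr[3] + ax[3])
  spole <- c(ctr[1], ctr[2], ctr[3] - ax[3])
  verts <- rbind(npole, v, spole)
  nring <- nv - 1L
  idx <- function(i, j) 1L + (i - 1L) * nu + ((j - 1L) %% nu) + 1L  # ring i, slot j
  faces <- list()
  for (j in seq_len(nu)) {                                # north fan
    faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  }
  for (i in seq_len(nring - 1L)) {
    for (j in seq_len(nu)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, c_, b)
      faces[[length(faces) + 1L]] <- c(b, c_, d)
    }
  }
  last <- nrow(verts)
  for (j in seq_len(nu)) {                                # south fan
    faces[[length(faces) + 1L]] <- c(last, idx(nring, j + 1L), idx(nring, j))
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

# dental arch as a closed tube along a parabolic centerline, with radial
# cusp bumps at the tooth stations
.make_arch <- function(n_target) {
  ns <- max(24L, round(n_target / 9))   # stations along the arch
  nr <- 8L                              # points around each ring
  s <- seq(-1, 1, length.out = ns)
  cx <- 30 * s
  cy <- 70 - 45 * s^2
  stations <- c(-0.8, -0.55, -0.35, -0.13, 0.13, 0.35, 0.55, 0.8)  # teeth
  bump <- rep(1, ns)
  for (st in stations) bump <- bump + 0.35 * exp(-((s - st) / 0.045)^2)
  # local frame along the centerline
  tx <- c(diff(cx), tail(diff(cx), 1)); ty <- c(diff(cy), tail(diff(cy), 1))
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl
  nx <- ty; ny <- -tx                   # horizontal normal (buccal)
  ang <- seq(0, 2 * pi, length.out = nr + 1L)[seq_len(nr)]
  verts <- matrix(0, ns * nr, 3L)
  for (i in seq_len(ns)) {
    rad <- 4.5 * bump[i]
    ring <- cbind(cx[i] + rad * cos(ang) * nx[i],
                  cy[i] + rad * cos(ang) * ny[i],
                  -1 + 1.4 * rad * sin(ang))
    verts[(i - 1L) * nr + seq_len(nr), ] <- ring
  }
  faces <- list()
  id <- function(i, j) (i - 1L) * nr + ((j - 1L) %% nr) + 1L
  for (i in seq_len(ns - 1L)) {
    for (j in seq_len(nr)) {
      a <- id(i, j); b <- id(i, j + 1L)
      c_ <- id(i + 1L, j); d <- id(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, c_)
      faces[[length(faces) + 1L]] <- c(b, d, c_)
    }
  }
  # end caps
  cap1 <- nrow(verts) + 1L; cap2 <- nrow(verts) + 2L
  verts <- rbind(verts, c(cx[1], cy[1], -1), c(cx[ns], cy[ns], -1))
  for (j in seq_len(nr)) {
    faces[[length(faces) + 1L]] <- c(cap1, id(1L, j + 1L), id(1L, j))
    faces[[length(faces) + 1L]] <- c(cap2, id(ns, j), id(ns, j + 1L))
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

#' Generate a skull phantom with landmarks and regions
#'
#' A stylised closed surface with two distinct regions — an ellipsoid
#' cranium with seeded asymmetric surface detail, and a dental-arch tube
#' with cusp bumps — plus the full landmark vocabulary (facial landmarks
#' non-coplanar; pronasale offset anteriorly). Deterministic per seed.
#'
#' @param spec a [phantom_spec()]
#' @return list: `mesh`, `landmarks`, `regions` (integer index vectors
#'   `cranial`, `maxilla`, `dentition`), `spec`
#' @export
make_skull_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed + 101L, {
    cran <- .make_cranium(round(spec$resolution * 2 / 3))
    arch <- .make_arch(round(spec$resolution / 3))
    nc <- nrow(cran$vertices)
    mesh <- triangle_mesh(rbind(cran$vertices, arch$vertices),
                          rbind(cran$faces, arch$faces + nc))
    cranial <- which(mesh$vertices[, 3] > 40 & seq_len(nrow(mesh$vertices)) <= nc)
    maxilla <- nc + seq_len(nrow(arch$vertices))
    list(mesh = mesh,
         landmarks = .landmark_template(),
         regions = list(cranial = cranial, maxilla = maxilla,
                        dentition = maxilla),
         spec = spec)
  })
}

#' Simulate an optical dentition scan
#'
#' Extracts the dentition region, randomly drops `1 - overlap` of its faces
#' (seeded), perturbs the remaining vertices with isotropic Gaussian noise,
#' and moves the result by the *inverse* of `true_transform` — so that
#' fusing the scan back onto the model must recover `true_transform`.
#'
#' @param model the phantom `triangle_mesh`
#' @param region dentition vertex indices
#' @param true_transform the `rigid_transform` fusion should recover
#' @param noise_sd Gaussian vertex noise, mm
#' @param overlap fraction of faces kept, in (0, 1]
#' @param seed integer seed
#' @return list: `mesh` (the scan), `true_transform`
#' @export
make_dentition_scan <- function(model, region, true_transform = rt_identity(),
                                noise_sd = 0, overlap = 1, seed = 1L) {
  stopifnot(inherits(model, "triangle_mesh"),
            inherits(true_transform, "rigid_transform"),
            overlap > 0, overlap <= 1, noise_sd >= 0)
  if (length(region) == 0L) abort("region is empty")
  sub <- submesh(model, region)
  .with_seed(seed + 202L, {
    nf <- nrow(sub$faces)
    keep <- sort(sample.int(nf, max(1L, round(overlap * nf))))
    kept_faces <- sub$faces[keep, , drop = FALSE]
    used <- sort(unique(as.vector(kept_faces)))
    if (length(used) < 50L) {
      abort("overlap too low: scan would have fewer than 50 vertices")
    }
    remap <- integer(nrow(sub$vertices)); remap[used] <- seq_along(used)
    v <- sub$vertices[used, , drop = FALSE]
    v <- v + matrix(rnorm(length(v), 0, noise_sd), ncol = 3L)
    scan <- triangle_mesh(v, matrix(remap[kept_faces], ncol = 3L))
    scan <- transform_mesh(rt_inverse(true_transform), scan)
    list(mesh = scan, true_transform = true_transform)
  })
}

#' Simulate facial-photo landmarks under a known head rotation
#'
#' Rotates the landmarks by `true_rotation` about their centroid, places
#' the centroid on the optical axis at `distance` from the pinhole, and
#' perspective-projects through `camera`, adding seeded pixel noise.
#'
#' @param landmarks landmark tibble (facial landmarks are selected
#'   automatically if present)
#' @param true_rotation 3 x 3 rotation the pose estimate should recover
#' @param camera a [camera_model()]
#' @param distance camera-to-subject distance in mm (default 1500)
#' @param pixel_noise Gaussian noise on (u, v), pixels
#' @param seed integer seed
#' @return list: `photo` (photo landmark tibble), `true_rotation`
#' @export
make_photo_projection <- function(landmarks, true_rotation = diag(3),
                                  camera = camera_model(), distance = 1500,
                                  pixel_noise = 0, seed = 1L) {
  .lm_check(landmarks)
  true_rotation <- .check_rotation(true_rotation, tol = 1e-6)
  if (distance <= 0) abort("camera distance must be positive")
  fac <- intersect(landmarks$name, facial_landmarks())
  lm <- if (length(fac) >= 4L) {
    landmarks[match(fac, landmarks$name), ]
  } else landmarks
  m <- .as_points_matrix(lm)
  ctr <- colMeans(m)
  pc <- sweep(m, 2L, ctr) %*% t(true_rotation)
  pc[, 3] <- pc[, 3] + distance
  if (any(pc[, 3] <= 1e-6)) abort("a landmark lies behind the camera")
  .with_seed(seed + 303L, {
    u <- camera$principal_point[1] + camera$focal * pc[, 1] / pc[, 3] +
      rnorm(nrow(pc), 0, pixel_noise)
    v <- camera$principal_point[2] + camera$focal * pc[, 2] / pc[, 3] +
      rnorm(nrow(pc), 0, pixel_noise)
    list(photo = tibble(name = lm$name, u = u, v = v),
         true_rotation = true_rotation)
  })
}

#' Simulate a postoperative case with known ground truth
#'
#' Displaces the maxilla region and its dental landmarks by `applied` — a
#' rotation (Euler pitch/roll/yaw) about the occlusal-plane centroid
#' followed by the axis translations — adds Gaussian surface noise to the
#' rest of the model (the cranial side), and re-poses everything by
#' `global_pose` to emulate a different scanner pose. `evaluate_case()`
#' must undo `global_pose` via the cranial base and report `applied`.
#'
#' @param sim_mesh,sim_landmarks the simulation model and landmarks
#' @param maxilla_region vertex indices of the displaced (surgical) region
#' @param applied numeric length-6 `(left_right, advance_setback,
#'   impaction_elongation, pitch, roll, yaw)` or a one-row
#'   [displacement6()] tibble
#' @param global_pose arbitrary `rigid_transform` applied to the whole case
#' @param cranial_sd Gaussian noise on non-maxilla vertices, mm
#' @param seed integer seed
#' @return list: `mesh`, `landmarks`, `truth` (list: `applied`, `origin`,
#'   `linear` tibble of exact per-landmark discrepancies)
#' @export
make_postop_case <- function(sim_mesh, sim_landmarks, maxilla_region,
                             applied = rep(0, 6),
                             global_pose = rt_identity(),
                             cranial_sd = 0, seed = 1L) {
  stopifnot(inherits(sim_mesh, "triangle_mesh"),
            inherits(global_pose, "rigid_transform"), cranial_sd >= 0)
  if (length(maxilla_region) == 0L) abort("maxilla region is empty")
  if (is.data.frame(applied)) applied <- as.numeric(applied[1, 1:6])
  stopifnot(length(applied) == 6L, all(is.finite(applied)))
  origin <- occlusal_plane(sim_landmarks)$plane$origin
  ra <- euler_compose(applied[4], applied[5], applied[6])
  rot <- rigid_transform(ra, origin - as.numeric(ra %*% origin))
  disp <- rt_compose(rigid_transform(diag(3), applied[1:3]), rot)
  v <- sim_mesh$vertices
  v[maxilla_region, ] <- transform_points(disp, v[maxilla_region, , drop = FALSE])
  dental <- landmark_vocabulary()[1:11]
  lm <- sim_landmarks
  move <- lm$name %in% dental
  mm <- transform_points(disp, .as_points_matrix(lm[move, ]))
  lm$x[move] <- mm[, 1]; lm$y[move] <- mm[, 2]; lm$z[move] <- mm[, 3]
  truth_linear <- landmark_linear_discrepancy(sim_landmarks, lm)
  .with_seed(seed + 404L, {
    noise_idx <- setdiff(seq_len(nrow(v)), maxilla_region)
    v[noise_idx, ] <- v[noise_idx, ] +
      matrix(rnorm(3L * length(noise_idx), 0, cranial_sd), ncol = 3L)
    mesh <- transform_mesh(global_pose, triangle_mesh(v, sim_mesh$faces))
    lm <- transform_points(global_pose, lm)
    list(mesh = mesh, landmarks = lm,
         truth = list(applied = applied, origin = origin,
                      linear = truth_linear))
  })
}

#' Write a complete fixture case to disk
#'
#' Generates a phantom, a dentition scan, photo landmarks, a small surgical
#' plan and a postoperative model, writing STL/JSON files plus a
#' `ground_truth.json` with every generating parameter.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed
#' @return `dir`, invisibly
#' @export
write_fixture_case <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- make_skull_phantom(phantom_spec(seed = seed))
  # modest scan-to-CT misalignment: ICP-based fusion assumes the optical
  # scan arrives roughly pre-aligned with the CT frame
  scan_tr <- rigid_transform(euler_compose(2, -1.5, 3), c(2, -2, 1.5))
  scan <- make_dentition_scan(ph$mesh, ph$regions$dentition, scan_tr,
                              noise_sd = 0.05, overlap = 0.85, seed = seed)
  tilt <- euler_compose(8, 3, -5)
  photo <- make_photo_projection(ph$landmarks, tilt, camera_model(),
                                 distance = 1500, pixel_noise = 0, seed = seed)
  plan <- surgical_plan(plan_translate(2.0, 1.5, -1.0),
                        plan_rotate(c(0, 60, -6), c(10, 60, -6), c(10, 60, -4)))
  applied <- c(0.61, 0.86, 1.00, 1.43, 0.50, 0.58)
  postop <- make_postop_case(ph$mesh, ph$landmarks, ph$regions$maxilla,
                             applied = applied,
                             global_pose = rigid_transform(
                               euler_compose(2, -1.5, 3), c(4, -2, 5)),
                             cranial_sd = 0, seed = seed)
  write_stl(ph$mesh, file.path(dir, "model.stl"))
  write_stl(scan$mesh, file.path(dir, "scan.stl"))
  write_stl(postop$mesh, file.path(dir, "postop.stl"))
  write_landmarks(ph$landmarks, file.path(dir, "landmarks.json"))
  write_landmarks(postop$landmarks, file.path(dir, "postop_landmarks.json"))
  write_photo_landmarks(photo$photo, file.path(dir, "photo_landmarks.json"))
  write_plan(plan, file.path(dir, "plan.json"))
  jsonlite::write_json(
    list(seed = seed,
         scan_transform = list(rotation = lapply(1:3, function(i) scan_tr$rotation[i, ]),
                               translation = scan_tr$translation),
         nhp_rotation = lapply(1:3, function(i) tilt[i, ]),
         applied_displacement = applied,
         cranial_mask = ph$regions$cranial),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = FALSE)
  invisible(dir)
}
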