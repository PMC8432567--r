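# Triangle meshes: the surface representation for CT-derived skeletal
# models, optical dentition scans, and simulated segments. Vertices in mm.

#' Triangle mesh
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates (mm)
#' @param faces M x 3 integer matrix of 1-based vertex indices
#' @return an object of class `triangle_mesh`
#' @export
triangle_mesh <- function(vertices, faces) {
  v <- .as_points_matrix(vertices, "vertices")
  f <- if (is.null(faces) || length(faces) == 0L) {
    matrix(integer(0), 0L, 3L)
  } else {
    as.matrix(faces)
  }
  if (ncol(f) != 3L) abort("faces must be an M x 3 index matrix")
  storage.mode(f) <- "integer"
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) abort("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
      abort("a face repeats a vertex index")
    }
  }
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`
#' @return numeric scalar
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Apply a rigid transform to a mesh
#' @param transform a `rigid_transform`
#' @param mesh a `triangle_mesh`
#' @return the transformed `triangle_mesh`
#' @export
transform_mesh <- function(transform, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  triangle_mesh(transform_points(transform, mesh$vertices), mesh$faces)
}

#' Merge duplicate vertices
#'
#' STL stores every facet independently, so shared vertices arrive
#' triplicated; meshes need them merged for connectivity. Vertices closer
#' than `tol` collapse to one index.
#'
#' @param mesh a `triangle_mesh`
#' @param tol merge tolerance in mm
#' @return a `triangle_mesh` with unique vertices
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  if (nrow(v) == 0L) return(mesh)
  key <- apply(round(v / tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])   # new index in first-occurrence order
  f <- matrix(remap[mesh$faces], ncol = 3L)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  triangle_mesh(v[first, , drop = FALSE], f[keep, , drop = FALSE])
}

#' Extract the submesh spanned by a vertex subset
#'
#' Keeps faces whose three vertices all belong to `region`.
#'
#' @param mesh a `triangle_mesh`
#' @param region integer vector of vertex indices
#' @return a `triangle_mesh` reindexed to the kept vertices
#' @export
submesh <- function(mesh, region) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  region <- sort(unique(as.integer(region)))
  if (length(region) == 0L) abort("region is empty")
  inset <- logical(nrow(mesh$vertices)); inset[region] <- TRUE
  keep <- inset[mesh$faces[, 1]] & inset[mesh$faces[, 2]] & inset[mesh$faces[, 3]]
  remap <- integer(nrow(mesh$vertices)); remap[region] <- seq_along(region)
  fk <- mesh$faces[keep, , drop = FALSE]
  triangle_mesh(mesh$vertices[region, , drop = FALSE],
                matrix(remap[fk], ncol = 3L))
}
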