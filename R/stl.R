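# STL reader/writer, binary and ASCII dialects.
#
# Binary layout: 80-byte header, uint32 little-endian facet count, then per
# facet 12 float32 (normal, v1, v2, v3) + uint16 attribute byte count =
# 50 bytes. ASCII: "solid"/"facet normal"/"vertex" keyword grammar.
# No installed package parses STL, so the byte-level IO lives here.

#' Read an STL file
#'
#' Detects the dialect (binary vs ASCII), parses the facets, and merges
#' duplicate vertices within `merge_tol` mm so the result has shared
#' connectivity rather than one vertex triple per facet.
#'
#' @param path file path
#' @param merge_tol vertex merge tolerance in mm (default 1e-6)
#' @return a [triangle_mesh()]
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  size <- file.info(path)$size
  raw <- readBin(path, "raw", n = size)
  is_ascii <- FALSE
  if (size >= 6L && rawToChar(raw[1:5]) == "solid") {
    txt_probe <- suppressWarnings(
      rawToChar(raw[seq_len(min(size, 2000L))]))
    if (grepl("facet", txt_probe, fixed = TRUE) || size < 84L) is_ascii <- TRUE
    # an empty ascii solid has no facets at all
    if (!is_ascii && size < 84L) is_ascii <- TRUE
  }
  mesh <- if (is_ascii) .read_stl_ascii(raw, path) else .read_stl_binary(raw, path)
  merge_vertices(mesh, tol = merge_tol)
}

.read_stl_binary <- function(raw, path) {
  if (length(raw) < 84L) {
    abort(sprintf("STL parse error in %s: file truncated at byte %d (header needs 84)",
                  path, length(raw)))
  }
  count <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(count)
  if (length(raw) < expected) {
    abort(sprintf("STL parse error in %s: %d facets declared but file ends at byte %d (expected %d)",
                  path, count, length(raw), expected))
  }
  if (count == 0L) return(triangle_mesh(matrix(numeric(0), 0, 3), NULL))
  # gather the 48 float bytes of each 50-byte record, skipping the
  # trailing uint16, then bulk-decode
  rec_starts <- 84 + 50 * (seq_len(count) - 1)
  idx <- rep(rec_starts, each = 48L) + rep(1:48, times = count)
  floats <- readBin(raw[idx], "double", size = 4L, n = 12L * count,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                 m[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * count), ncol = 3L)))
  verts <- verts[ord, , drop = FALSE]   # interleave back to v1,v2,v3 per facet
  faces <- matrix(seq_len(3L * count), ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

.read_stl_ascii <- function(raw, path) {
  txt <- rawToChar(raw)
  lines <- strsplit(txt, "\r?\n")[[1]]
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nfacet <- length(grep("^\\s*facet\\s+normal", lines))
  if (length(vlines) != 3L * nfacet) {
    abort(sprintf("STL parse error in %s: %d facets but %d vertex lines",
                  path, nfacet, length(vlines)))
  }
  if (nfacet == 0L) return(triangle_mesh(matrix(numeric(0), 0, 3), NULL))
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(p) as.numeric(p[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts))) {
    abort(sprintf("STL parse error in %s: non-numeric vertex coordinates", path))
  }
  faces <- matrix(seq_len(3L * nfacet), ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Write an STL file
#'
#' Facet normals are recomputed from the vertex winding order; the
#' right-hand rule defines the outward direction.
#'
#' @param mesh a [triangle_mesh()] with at least one face
#' @param path output path
#' @param dialect `"binary"` (default) or `"ascii"`
#' @return `path`, invisibly
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  if (nrow(mesh$faces) == 0L) abort("refusing to write an empty mesh")
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len < 1e-30] <- 1
  n <- n / len
  if (dialect == "binary") {
    con <- file(path, "wb"); on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "orthoflow binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "little")
    rec <- t(cbind(n, a, b, c_))          # 12 floats per facet, column = facet
    fb <- writeBin(as.numeric(rec), raw(), size = 4L, endian = "little")
    m <- matrix(fb, nrow = 48L)           # 48 float bytes per facet
    full <- rbind(m, matrix(as.raw(0), 2L, ncol(m)))  # + uint16 attribute
    writeBin(as.vector(full), con)
  } else {
    fmt <- function(v) sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])
    out <- character(7L * nrow(mesh$faces) + 2L)
    out[1] <- "solid orthoflow"
    k <- 2L
    for (i in seq_len(nrow(mesh$faces))) {
      out[k:(k + 6L)] <- c(
        paste("facet normal", fmt(n[i, ])),
        "  outer loop",
        paste("    vertex", fmt(a[i, ])),
        paste("    vertex", fmt(b[i, ])),
        paste("    vertex", fmt(c_[i, ])),
        "  endloop",
        "endfacet")
      k <- k + 7L
    }
    out[k] <- "endsolid orthoflow"
    writeLines(out, path)
  }
  invisible(path)
}
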