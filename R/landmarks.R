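# Named anatomical landmarks. A landmark set is a tibble with columns
# name / x / y / z (mm), so it flows through dplyr and the pipe; helpers
# convert to matrices where linear algebra needs them.

#' Controlled landmark vocabulary
#'
#' Names the package recognises: the eight maxillary tooth landmarks used
#' for linear discrepancy (bilateral incisors, canines, first and second
#' molars), the three occlusal-plane landmarks (mesiobuccal cusps of the
#' first molars and the central-incisor midpoint), and the seven facial
#' landmarks used for natural-head-position reproduction (pronasale,
#' bilateral exocanthion, endocanthion, cheilion).
#'
#' @return character vector of landmark names
#' @export
landmark_vocabulary <- function() {
  c(# maxillary dentition
    "incisor_r", "incisor_l", "canine_r", "canine_l",
    "molar1_r", "molar1_l", "molar2_r", "molar2_l",
    # occlusal plane
    "mb_cusp_molar1_r", "mb_cusp_molar1_l", "incisor_midpoint",
    # facial (photo / NHP)
    "pronasale", "exocanthion_r", "exocanthion_l",
    "endocanthion_r", "endocanthion_l", "cheilion_r", "cheilion_l")
}

#' Tooth landmark names used for linear discrepancy
#' @return character vector of the eight maxillary tooth landmark names
#' @export
tooth_landmarks <- function() landmark_vocabulary()[1:8]

#' Facial landmark names used for NHP reproduction
#' @return character vector of the seven facial landmark names
#' @export
facial_landmarks <- function() landmark_vocabulary()[12:18]

#' Build a landmark set
#'
#' @param ... named length-3 vectors, e.g. `pronasale = c(0, 92, 10)`, or a
#'   single named list of them
#' @return a tibble with columns `name`, `x`, `y`, `z`
#' @examples
#' landmark_set(pronasale = c(0, 92, 10), cheilion_r = c(-25, 68, -15))
#' @export
landmark_set <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots)[1])) {
    dots <- dots[[1]]
  }
  nm <- names(dots)
  if (is.null(nm) || any(nm == "")) abort("all landmarks must be named")
  if (anyDuplicated(nm)) abort("duplicate landmark name")
  m <- do.call(rbind, lapply(dots, .as_point3))
  tibble(name = nm, x = unname(m[, 1]), y = unname(m[, 2]), z = unname(m[, 3]))
}

.lm_check <- function(lm) {
  if (!is.data.frame(lm) || !all(c("name", "x", "y", "z") %in% names(lm))) {
    abort("landmark set must have columns name, x, y, z")
  }
  if (anyDuplicated(lm$name)) abort("duplicate landmark name")
  lm
}

#' Look up one landmark as a length-3 vector
#' @param lm a landmark tibble
#' @param name landmark name
#' @return numeric length-3 `c(x, y, z)`
#' @export
landmark_point <- function(lm, name) {
  .lm_check(lm)
  i <- match(name, lm$name)
  if (is.na(i)) abort(sprintf("landmark '%s' not present", name))
  unname(c(lm$x[i], lm$y[i], lm$z[i]))
}

#' Read landmarks from JSON
#'
#' Format: a JSON object mapping landmark name to `[x, y, z]` in mm.
#' Names outside the controlled vocabulary are kept with a warning.
#'
#' @param path file path
#' @return a landmark tibble
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (.json_has_duplicate_keys(txt)) abort("duplicate landmark name in file")
  obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), landmark_vocabulary())
  if (length(unknown)) {
    warn(paste("landmark names outside vocabulary retained:",
               paste(unknown, collapse = ", ")))
  }
  landmark_set(obj)
}

#' Write landmarks to JSON
#' @param lm a landmark tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_landmarks <- function(lm, path) {
  .lm_check(lm)
  obj <- setNames(lapply(seq_len(nrow(lm)),
                         function(i) c(lm$x[i], lm$y[i], lm$z[i])),
                  lm$name)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read / write a rigid transform as JSON
#'
#' Format: `{"rotation": [[...],[...],[...]], "translation": [x, y, z]}`
#' with the rotation in row-major order.
#'
#' @param path file path
#' @return [read_transform()]: a `rigid_transform`
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rigid_transform(matrix(as.numeric(t(obj$rotation)), 3, 3, byrow = TRUE),
                  as.numeric(obj$translation))
}

#' @rdname read_transform
#' @param transform a `rigid_transform`
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  obj <- list(rotation = lapply(1:3, function(i) transform$rotation[i, ]),
              translation = transform$translation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# duplicate-key detection requires a raw parse: jsonlite silently keeps the
# last duplicate, so check the token stream ourselves
.json_has_duplicate_keys <- function(txt) {
  keys <- regmatches(txt, gregexpr('"[^"]*"\\s*:', txt))[[1]]
  keys <- sub('\\s*:$', "", keys)
  anyDuplicated(keys) > 0L
}
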