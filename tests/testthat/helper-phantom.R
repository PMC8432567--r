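# Shared fixtures, built once per test run.

.phantom_env <- new.env(parent = emptyenv())

default_phantom <- function(seed = 3L) {
  key <- paste0("ph", seed)
  if (is.null(.phantom_env[[key]])) {
    .phantom_env[[key]] <- make_skull_phantom(phantom_spec(seed = seed))
  }
  .phantom_env[[key]]
}

random_rotation <- function() {
  # uniform-ish random rotation via QR of a Gaussian matrix, det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

max_euler_error <- function(r_est, r_true) {
  max(abs(euler_decompose(r_est %*% t(r_true))))
}

unit_tetrahedron <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}
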