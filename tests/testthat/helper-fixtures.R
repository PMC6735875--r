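# Shared fixtures, built in code at test time.

# Small, fast phantom configuration used by most tests.
small_phantom_config <- function(seed = 42L, ...) {
  defaults <- list(
    grid_shape = c(40, 40, 40),
    spacing_mm = c(2, 2, 2),
    endo_radius_mm = c(22, 18, 28),
    mesh_resolution = c(32L, 16L),
    n_egm = 200L, n_pace = 60L,
    seed = seed
  )
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# A tiny connected mesh: unit tetrahedron (4 vertices, 4 faces).
tetra_mesh <- function() {
  surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  )
}

# Path graph as a bare vertex graph (for interpolation closed forms).
path_graph <- function(n) {
  list(n_vertices = as.integer(n), edges = cbind(1:(n - 1), 2:n))
}

# Random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid <- function(max_t = 20) {
  rigid_transform(random_rotation(), runif(3, -max_t, max_t))
}
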