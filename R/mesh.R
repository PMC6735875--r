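#' Triangulated surface meshes
#'
#' A `surface_mesh` holds the endocardial surface on which all nodal maps
#' live: vertex positions in world millimetres and triangular faces as
#' 1-based vertex-index triples. Construction validates index ranges,
#' rejects zero-area faces, and requires the vertex-edge graph to be
#' connected (Laplacian interpolation needs every vertex reachable from a
#' measured one).
#'
#' @param vertices Numeric n x 3 matrix of vertex positions (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, and `edges` (unique undirected edge list).
#' @export
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   matrix(c(1, 2, 3), 1))
#' n_vertices(m)
surface_mesh <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  nv <- nrow(vertices)
  assert_that(nv >= 3L, "mesh needs at least 3 vertices")
  assert_that(nrow(faces) >= 1L, "mesh needs at least 1 face")
  assert_that(all(faces >= 1L & faces <= nv), "face index out of range")
  assert_that(all(faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
                    faces[, 1] != faces[, 3]),
              "degenerate face (repeated vertex)")
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  assert_that(all(area2 > 1e-12), "zero-area face in mesh")
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  assert_that(mesh_is_connected(nv, edges), "mesh vertex-edge graph must be connected")
  structure(list(vertices = vertices, faces = faces, edges = edges),
            class = "surface_mesh")
}

mesh_is_connected <- function(nv, edges) {
  # BFS over adjacency built from the edge list
  adj <- vector("list", nv)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(nv)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @rdname surface_mesh
#' @param mesh A `surface_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

# Adjacency (neighbour index list) of the vertex-edge graph.
mesh_adjacency <- function(mesh) {
  nv <- n_vertices(mesh)
  e <- mesh$edges
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(nv)))
  lapply(adj, function(v) sort(unique(v)))
}
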