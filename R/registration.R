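#' Rigid transforms between image and mapping frames
#'
#' A `rigid_transform` is a proper rotation (3x3 orthonormal, det +1) plus a
#' translation in millimetres, relating the MRI image frame to the
#' electroanatomic mapping frame. Orthonormality and the determinant are
#' validated to 1e-9 at construction.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 2, 3))
#' transform_points(rbind(c(0, 0, 0)), t1)
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  assert_that(all(dim(rotation) == c(3L, 3L)), "rotation must be 3x3")
  assert_that(length(translation) == 3L, "translation must be length 3")
  assert_that(max(abs(crossprod(rotation) - diag(3))) < 1e-9,
              "rotation is not orthonormal (tolerance 1e-9)")
  assert_that(abs(det(rotation) - 1) < 1e-9,
              "rotation must be proper (det +1); got det = %g", det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: angle %.3f deg, |t| = %.3f mm>\n",
              rotation_angle_deg(x), sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Rotation helpers
#'
#' `rotation_about_axis()` builds a rotation matrix from an axis and angle
#' (Rodrigues formula); `rotation_angle_deg()` extracts the rotation angle of
#' a transform in degrees.
#'
#' @param axis Numeric length-3 rotation axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  assert_that(nrm > 0, "rotation axis must be non-zero")
  u <- axis / nrm
  th <- angle_deg * pi / 180
  k <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' @rdname rotation_about_axis
#' @param transform A [rigid_transform()].
#' @export
rotation_angle_deg <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

#' Apply, invert, and compose rigid transforms
#'
#' `transform_points()` maps points `p` to `R p + t`; `invert_transform()`
#' returns the inverse motion; `compose_transforms()` returns `a` applied
#' after `b` (i.e. `x -> a(b(x))`).
#'
#' @param points n x 3 matrix (or data frame with `x_mm`, `y_mm`, `z_mm`).
#' @param transform,a,b [rigid_transform()] objects.
#' @return `transform_points()`: n x 3 matrix; the others: a
#'   [rigid_transform()].
#' @export
transform_points <- function(points, transform) {
  p <- as_point_matrix(points)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  out
}

#' @rdname transform_points
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' @rdname transform_points
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

landmark_matrices <- function(landmarks) {
  if (is.data.frame(landmarks)) {
    need <- c("src_x_mm", "src_y_mm", "src_z_mm",
              "dst_x_mm", "dst_y_mm", "dst_z_mm")
    assert_that(all(need %in% names(landmarks)),
                "landmark table must have columns %s", paste(need, collapse = ", "))
    src <- as.matrix(landmarks[, need[1:3]])
    dst <- as.matrix(landmarks[, need[4:6]])
  } else {
    src <- as_point_matrix(landmarks$src)
    dst <- as_point_matrix(landmarks$dst)
  }
  assert_that(nrow(src) == nrow(dst), "source/destination counts differ")
  list(src = src, dst = dst)
}

points_collinear <- function(p, tol = 1e-9) {
  c0 <- sweep(p, 2, colMeans(p))
  sv <- svd(c0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Least-squares rigid registration from point correspondences
#'
#' Fits the rigid transform minimising the sum of squared distances
#' `sum(|R s_i + t - d_i|^2)` over corresponding landmark pairs, using the
#' SVD (Kabsch) solution with the standard sign correction that excludes
#' reflections. This is the point-based landmark registration step aligning
#' the scar segmentation image frame with the mapping-system frame.
#'
#' @param landmarks Data frame with columns `src_x_mm` ... `dst_z_mm`
#'   (as written by [make_landmarks()]), or a list with `src` and `dst`
#'   n x 3 matrices.
#' @return A [rigid_transform()] with attributes `rms_mm` (root-mean-square
#'   residual) and `residuals_mm` (per-landmark residual distances).
#' @export
#' @examples
#' lm <- tibble::tibble(
#'   src_x_mm = c(0, 1, 0, 0), src_y_mm = c(0, 0, 1, 0),
#'   src_z_mm = c(0, 0, 0, 1),
#'   dst_x_mm = c(1, 2, 1, 1), dst_y_mm = c(0, 0, 1, 0),
#'   dst_z_mm = c(0, 0, 0, 1)
#' )
#' fit_rigid_landmarks(lm)  # pure translation (1, 0, 0)
fit_rigid_landmarks <- function(landmarks) {
  m <- landmark_matrices(landmarks)
  n <- nrow(m$src)
  assert_that(n >= 3L, "need at least 3 landmark pairs (got %d)", n)
  assert_that(!points_collinear(m$src), "source landmarks are collinear")
  cs <- colMeans(m$src)
  cd <- colMeans(m$dst)
  h <- crossprod(sweep(m$src, 2, cs), sweep(m$dst, 2, cd))
  sv <- svd(h)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% s %*% t(sv$u)
  t_vec <- cd - as.vector(r %*% cs)
  fit <- rigid_transform(r, t_vec)
  res <- sqrt(rowSums((transform_points(m$src, fit) - m$dst)^2))
  attr(fit, "rms_mm") <- sqrt(mean(res^2))
  attr(fit, "residuals_mm") <- res
  fit
}

#' Iterative closest point refinement against mesh vertices
#'
#' Alternates nearest-vertex correspondence with a rigid (Kabsch) update
#' until the mean correspondence distance changes by less than `tol` or
#' `max_iter` is reached. Used to refine the landmark alignment of the scar
#' point cloud onto the endocardial surface mesh.
#'
#' @param points n x 3 point cloud (image frame).
#' @param mesh A [surface_mesh()].
#' @param init Initial [rigid_transform()] (e.g. from
#'   [fit_rigid_landmarks()]).
#' @param tol Convergence tolerance on the change in mean correspondence
#'   distance (mm); default 1e-4.
#' @param max_iter Maximum iterations; default 100.
#' @return A [rigid_transform()] with attributes `mean_distance_mm`,
#'   `iterations`, `converged`.
#' @export
icp_refine <- function(points, mesh, init = rigid_transform(),
                       tol = 1e-4, max_iter = 100) {
  p0 <- as_point_matrix(points)
  assert_that(nrow(p0) >= 1L, "ICP needs a non-empty point set")
  assert_that(inherits(mesh, "surface_mesh"), "mesh must be a surface_mesh")
  cur <- init
  prev_mean <- Inf
  converged <- FALSE
  iter <- 0L
  mean_d <- NA_real_
  for (iter in seq_len(max_iter)) {
    p <- transform_points(p0, cur)
    idx <- nearest_index(p, mesh$vertices)
    mean_d <- mean(attr(idx, "distance"))
    if (abs(prev_mean - mean_d) < tol) {
      converged <- TRUE
      break
    }
    prev_mean <- mean_d
    target <- mesh$vertices[as.integer(idx), , drop = FALSE]
    # Kabsch update mapping the ORIGINAL points to current correspondences,
    # so numerical error does not accumulate across iterations.
    step <- fit_rigid_landmarks(list(src = p0, dst = target))
    cur <- rigid_transform(step$rotation, step$translation)
  }
  attr(cur, "mean_distance_mm") <- mean_d
  attr(cur, "iterations") <- iter
  attr(cur, "converged") <- converged
  if (!converged) {
    rlang::warn(sprintf("ICP did not converge in %d iterations (mean distance %.4f mm)",
                        max_iter, mean_d))
  }
  cur
}

#' Map registered scar points onto mesh vertices
#'
#' Assigns each point to its nearest mesh vertex (ties broken by lowest
#' vertex index) and labels every vertex receiving at least one point as
#' scar. Points farther than `max_dist_mm` from every vertex are discarded
#' and counted; this drops clearly off-surface points such as the
#' epicardial-side voxels of a transmural scar.
#'
#' @param points n x 3 matrix of scar points, already in the mesh frame.
#' @param mesh A [surface_mesh()].
#' @param max_dist_mm Discard radius in mm (default 5).
#' @return Integer 0/1 vector of length `n_vertices(mesh)` with attribute
#'   `n_discarded`.
#' @export
map_points_to_nodes <- function(points, mesh, max_dist_mm = 5) {
  labels <- integer(n_vertices(mesh))
  p <- as_point_matrix(points)
  n_disc <- 0L
  if (nrow(p) > 0) {
    idx <- nearest_index(p, mesh$vertices)
    keep <- attr(idx, "distance") <= max_dist_mm
    n_disc <- sum(!keep)
    labels[unique(as.integer(idx)[keep])] <- 1L
  }
  attr(labels, "n_discarded") <- n_disc
  labels
}
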