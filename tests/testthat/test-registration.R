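test_that("rigid_transform validates orthonormality and handedness", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "proper")
  t1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 2, 3))
  expect_equal(rotation_angle_deg(t1), 90)
})

test_that("identity landmark fit and exact recovery of a constructed transform", {
  set.seed(101)
  src <- matrix(runif(15, -30, 30), 5)
  lm0 <- list(src = src, dst = src)
  fit0 <- fit_rigid_landmarks(lm0)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-12)

  tru <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 2, 3))
  fit <- fit_rigid_landmarks(list(src = src, dst = transform_points(src, tru)))
  expect_lt(max(abs(fit$rotation - tru$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - tru$translation)), 1e-9)
})

test_that("landmark fit is exact on noiseless correspondences for random rigid motions", {
  set.seed(7)
  for (i in 1:25) {
    tru <- random_rigid()
    src <- matrix(rnorm(3 * 6, sd = 25), ncol = 3)
    fit <- fit_rigid_landmarks(list(src = src, dst = transform_points(src, tru)))
    expect_lt(max(abs(fit$rotation - tru$rotation)), 1e-9)
    expect_lt(max(abs(fit$translation - tru$translation)), 1e-9)
  }
})

test_that("degenerate landmark sets are rejected", {
  src2 <- matrix(rnorm(6), 2)
  expect_error(fit_rigid_landmarks(list(src = src2, dst = src2)), "3 landmark")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rigid_landmarks(list(src = line, dst = line)), "collinear")
})

test_that("apply/invert/compose transforms behave as an action of SE(3)", {
  set.seed(5)
  tru <- random_rigid()
  pts <- matrix(rnorm(30, sd = 10), ncol = 3)
  # elementwise oracle
  oracle <- t(apply(pts, 1, function(p) tru$rotation %*% p + tru$translation))
  expect_equal(transform_points(pts, tru), oracle, tolerance = 1e-12)
  # round trip through the inverse
  back <- transform_points(transform_points(pts, tru), invert_transform(tru))
  expect_equal(back, pts, tolerance = 1e-12)
  # composition
  t2 <- random_rigid()
  expect_equal(transform_points(pts, compose_transforms(t2, tru)),
               transform_points(transform_points(pts, tru), t2),
               tolerance = 1e-12)
})

test_that("ICP recovers a 5 degree / 2 mm perturbed alignment on the phantom surface", {
  cfg <- small_phantom_config(seed = 17L)
  ph <- make_lv_phantom(cfg)
  mesh <- ph$mesh
  # dense on-surface cloud: the vertices themselves
  cloud <- mesh$vertices
  perturb <- rigid_transform(rotation_about_axis(c(1, 1, 0), 5),
                             c(2, 0, 0) / sqrt(2))
  cloud_off <- transform_points(cloud, perturb)
  fit <- icp_refine(cloud_off, mesh, tol = 1e-6, max_iter = 200)
  aligned <- transform_points(cloud_off, fit)
  mean_d <- mean(attr(scarconcord:::nearest_index(aligned, mesh$vertices),
                      "distance"))
  expect_lt(mean_d, 0.5)
  expect_true(attr(fit, "converged"))
})

test_that("ICP from the true alignment stops immediately with zero distance", {
  cfg <- small_phantom_config(seed = 19L)
  ph <- make_lv_phantom(cfg)
  sub <- ph$mesh$vertices[seq(1, n_vertices(ph$mesh), by = 3), ]
  fit <- icp_refine(sub, ph$mesh, init = rigid_transform(), tol = 1e-6)
  expect_lt(attr(fit, "mean_distance_mm"), 1e-6)
  expect_lt(max(abs(fit$rotation - diag(3))), 1e-6)
  expect_error(icp_refine(matrix(numeric(0), ncol = 3), ph$mesh), "non-empty")
})

test_that("ICP mean correspondence distance is non-increasing across iterations", {
  cfg <- small_phantom_config(seed = 23L)
  ph <- make_lv_phantom(cfg)
  cloud <- transform_points(ph$mesh$vertices,
                            rigid_transform(rotation_about_axis(c(0, 1, 0), 4),
                                            c(1, -1, 0.5)))
  # re-run ICP manually, recording the objective
  cur <- rigid_transform()
  dists <- c()
  for (it in 1:20) {
    p <- transform_points(cloud, cur)
    idx <- scarconcord:::nearest_index(p, ph$mesh$vertices)
    dists <- c(dists, mean(attr(idx, "distance")))
    tgt <- ph$mesh$vertices[as.integer(idx), ]
    cur <- fit_rigid_landmarks(list(src = cloud, dst = tgt))
    cur <- rigid_transform(cur$rotation, cur$translation)
  }
  expect_true(all(diff(dists) <= 1e-9))
})

test_that("map_points_to_nodes assigns nearest vertices with deterministic ties", {
  mesh <- tetra_mesh()
  # point exactly at vertex 3
  lab <- map_points_to_nodes(mesh$vertices[3, , drop = FALSE], mesh)
  expect_equal(as.integer(lab), c(0, 0, 1, 0), ignore_attr = TRUE)
  # point equidistant between vertices 1 and 2 -> lowest index wins
  lab2 <- map_points_to_nodes(rbind(c(0.5, 0, 0)), mesh)
  expect_equal(which(lab2 == 1), 1L)
  # empty input -> all-zero map
  lab3 <- map_points_to_nodes(matrix(numeric(0), ncol = 3), mesh)
  expect_equal(sum(lab3), 0L)
  expect_equal(attr(lab3, "n_discarded"), 0L)
  # far point discarded and counted
  lab4 <- map_points_to_nodes(rbind(c(100, 100, 100)), mesh, max_dist_mm = 5)
  expect_equal(sum(lab4), 0L)
  expect_equal(attr(lab4, "n_discarded"), 1L)
})

test_that("nearest-vertex assignment agrees with an exhaustive per-point oracle", {
  cfg <- small_phantom_config(seed = 29L)
  mesh <- make_lv_phantom(cfg)$mesh
  set.seed(30)
  pts <- matrix(runif(3 * 1000, 0, 80), ncol = 3)
  idx <- as.integer(scarconcord:::nearest_index(pts, mesh$vertices))
  oracle <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d <- colSums((t(mesh$vertices) - pts[i, ])^2)
    oracle[i] <- which.min(d)  # which.min: first (lowest-index) minimum
  }
  expect_identical(idx, oracle)
})
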