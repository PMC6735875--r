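test_that("EGM-to-node assignment averages co-located samples and flags knowns", {
  mesh <- tetra_mesh()
  samples <- tibble::tibble(
    x_mm = c(0.01, -0.01, 1.0), y_mm = c(0, 0, 0), z_mm = c(0, 0, 0),
    bipolar_mV = c(1.0, 3.0, 5.0), lat_ms = c(10, 20, NA)
  )
  maps <- assign_egm_to_nodes(samples, mesh)
  expect_equal(maps$voltage$value[1], 2.0)       # mean of 1 and 3
  expect_equal(maps$voltage$value[2], 5.0)
  expect_equal(maps$voltage$known, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(maps$lat$known, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(maps$lat$value[1], 15)
  expect_error(assign_egm_to_nodes(samples[0, ], mesh), "at least one")
})

test_that("EGM-to-node assignment matches a brute-force grouping oracle", {
  cfg <- small_phantom_config(seed = 31L)
  ph <- make_lv_phantom(cfg)
  egm <- simulate_egm_samples(ph$mesh, ph$ground_truth$node_scar_labels, cfg)
  mesh <- transform_mesh(ph$mesh, cfg$frame_transform)
  maps <- assign_egm_to_nodes(egm, mesh)
  # oracle: loop samples, nearest vertex by explicit distance, then average
  acc <- rep(0, n_vertices(mesh)); cnt <- rep(0, n_vertices(mesh))
  for (i in seq_len(nrow(egm))) {
    d <- colSums((t(mesh$vertices) - c(egm$x_mm[i], egm$y_mm[i], egm$z_mm[i]))^2)
    j <- which.min(d)
    acc[j] <- acc[j] + egm$bipolar_mV[i]
    cnt[j] <- cnt[j] + 1
  }
  oracle <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  expect_equal(maps$voltage$value, oracle, tolerance = 1e-12)
  expect_equal(maps$voltage$known, cnt > 0)
})

test_that("a single known vertex propagates its value everywhere (constant harmonic)", {
  mesh <- tetra_mesh()
  pm <- node_map(c(4.2, NA, NA, NA))
  out <- relax_interpolate(pm, mesh)
  expect_equal(out$value, rep(4.2, 4))
  expect_equal(out$known, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("interpolation on a path graph reproduces the exact linear ramp", {
  n <- 11
  pm <- node_map(c(0, rep(NA, n - 2), 1))
  out <- relax_interpolate(pm, path_graph(n))
  expect_equal(out$value, (0:(n - 1)) / (n - 1), tolerance = 1e-8)
})

test_that("interpolation satisfies the discrete maximum principle and is idempotent", {
  cfg <- small_phantom_config(seed = 37L)
  mesh <- make_lv_phantom(cfg)$mesh
  set.seed(38)
  for (rep_i in 1:5) {
    nv <- n_vertices(mesh)
    known <- sample(c(TRUE, FALSE), nv, replace = TRUE, prob = c(0.1, 0.9))
    known[sample(nv, 1)] <- TRUE  # ensure at least one
    vals <- rep(NA_real_, nv)
    vals[known] <- runif(sum(known), -5, 12)
    out <- relax_interpolate(node_map(vals), mesh)
    expect_true(all(out$value >= min(vals, na.rm = TRUE) - 1e-9))
    expect_true(all(out$value <= max(vals, na.rm = TRUE) + 1e-9))
    # idempotence: re-solving with the same knowns reproduces the values
    out2 <- relax_interpolate(node_map(ifelse(known, out$value, NA)), mesh)
    expect_equal(out2$value, out$value, tolerance = 1e-8)
  }
})

test_that("interpolation is linear in the boundary data", {
  mesh <- make_lv_phantom(small_phantom_config(seed = 41L))$mesh
  nv <- n_vertices(mesh)
  set.seed(42)
  known <- seq_len(nv) %in% sample(nv, 40)
  f <- ifelse(known, runif(nv), NA)
  g <- ifelse(known, runif(nv), NA)
  a <- 2.5; b <- -1.25
  lhs <- relax_interpolate(node_map(a * f + b * g), mesh)$value
  rhs <- a * relax_interpolate(node_map(f), mesh)$value +
    b * relax_interpolate(node_map(g), mesh)$value
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("interpolation agrees with a Gauss-Seidel relaxation oracle", {
  mesh <- tetra_mesh()
  pm <- node_map(c(1, NA, NA, 0))
  direct <- relax_interpolate(pm, mesh)$value
  # independent iterative relaxation: each unknown <- mean of neighbours
  adj <- list(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  v <- c(1, 0.5, 0.5, 0)
  for (sweep in 1:500) {
    for (i in c(2, 3)) v[i] <- mean(v[adj[[i]]])
  }
  expect_equal(direct, v, tolerance = 1e-10)
})

test_that("interpolation errors usefully on unconstrained or disconnected input", {
  mesh <- tetra_mesh()
  expect_error(relax_interpolate(node_map(rep(NA_real_, 4)), mesh), "known")
  # two disconnected path components, knowns only in the first
  g <- list(n_vertices = 6L, edges = rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6)))
  pm <- node_map(c(1, NA, NA, NA, NA, NA))
  expect_error(relax_interpolate(pm, g), "component")
})

test_that("binarize_map uses a strict less-than rule and is monotone in the threshold", {
  expect_equal(binarize_map(c(1.49, 1.50, 1.51), 1.5), c(1L, 0L, 0L))
  expect_equal(binarize_map(c(0.4, 2.2), 0), c(0L, 0L))  # voltages positive
  expect_error(binarize_map(c(1, NA)), "non-finite")
  set.seed(43)
  vals <- runif(200, 0, 5)
  sets <- lapply(c(0.5, 1.5, 2.5, 3.5), function(t) which(binarize_map(vals, t) == 1))
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("S-QRS classification follows the strict >40 ms rule and conserves counts", {
  sites <- tibble::tibble(
    captured = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    s_qrs_ms = c(40, 40.1, 85, NA, 10)
  )
  cl <- classify_sqrs(sites)
  expect_equal(cl$sites$category, c("normal", "slow", "slow", "no_capture", "normal"))
  expect_equal(cl$sites$very_slow, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  s <- glance(cl)
  expect_equal(s$n_normal + s$n_slow + s$n_no_capture, s$n_total)
  expect_equal(s$n_captured, 4)
  expect_equal(s$pct_slow, 100 * 2 / 4)
  expect_error(classify_sqrs(tibble::tibble(captured = TRUE, s_qrs_ms = -1)),
               "negative")
  expect_error(classify_sqrs(sites, slow_ms = 90, very_slow_ms = 80), "thresholds")
})

test_that("egm_snr is the amplitude/noise ratio and rejects bad noise", {
  expect_equal(egm_snr(0.1, 0.1), 1)
  expect_equal(egm_snr(4.478, 0.1), 44.78)
  expect_equal(egm_snr(0.2, 0.1), 2)
  expect_error(egm_snr(1, 0), "positive")
})
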