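test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- small_phantom_config(seed = 11L)
  a <- make_lv_phantom(cfg)
  b <- make_lv_phantom(cfg)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$ground_truth$scar_mask$data, b$ground_truth$scar_mask$data)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(simulate_egm_samples(a$mesh, a$ground_truth$node_scar_labels, cfg),
                   simulate_egm_samples(b$mesh, b$ground_truth$node_scar_labels, cfg))
  expect_identical(simulate_pace_sites(a$mesh, a$ground_truth$node_scar_labels, cfg),
                   simulate_pace_sites(b$mesh, b$ground_truth$node_scar_labels, cfg))
  expect_identical(make_landmarks(cfg), make_landmarks(cfg))
})

test_that("zero-extent scar yields an empty mask and all-normal samples", {
  cfg <- small_phantom_config(seed = 5L, scar_angular_extent_deg = 0)
  ph <- make_lv_phantom(cfg)
  expect_equal(sum(ph$ground_truth$scar_mask$data), 0)
  expect_equal(sum(ph$ground_truth$node_scar_labels), 0)
  egm <- simulate_egm_samples(ph$mesh, ph$ground_truth$node_scar_labels, cfg)
  expect_true(all(egm$true_class == "normal"))
})

test_that("scar voxel set matches a brute-force per-voxel membership oracle", {
  cfg <- small_phantom_config(seed = 2L, scar_angular_extent_deg = 60,
                              scar_axial_extent_frac = 0.3)
  ph <- make_lv_phantom(cfg)
  # independent voxel-by-voxel test, looped, from first principles
  gs <- cfg$grid_shape
  ctr <- cfg$lv_center_mm
  endo <- cfg$endo_radius_mm
  epi <- endo + cfg$wall_thickness_mm
  ax <- endo[3] + cfg$wall_thickness_mm
  zmid <- ctr[3] - ax / 2
  half <- cfg$scar_axial_extent_frac * ax / 2
  n_oracle <- 0L
  mism <- 0L
  for (i in 0:(gs[1] - 1)) for (j in 0:(gs[2] - 1)) for (k in 0:(gs[3] - 1)) {
    p <- c(i, j, k) * cfg$spacing_mm
    d <- p - ctr
    re <- sqrt(sum((d / endo)^2))
    rp <- sqrt(sum((d / epi)^2))
    in_wall <- re >= 1 && rp <= 1 && p[3] <= ctr[3]
    th <- atan2(d[2], d[1]) * 180 / pi
    dth <- ((th - cfg$scar_center_deg + 180) %% 360) - 180
    in_scar <- in_wall && abs(dth) <= cfg$scar_angular_extent_deg / 2 &&
      p[3] >= zmid - half && p[3] <= zmid + half
    if (in_scar) n_oracle <- n_oracle + 1L
    if (in_scar != (ph$ground_truth$scar_mask$data[i + 1, j + 1, k + 1] == 1)) {
      mism <- mism + 1L
    }
  }
  expect_equal(mism, 0L)
  expect_equal(sum(ph$ground_truth$scar_mask$data), n_oracle)
  expect_gt(n_oracle, 0L)
})

test_that("wall mask is an ellipsoidal shell containing the scar", {
  ph <- make_lv_phantom(small_phantom_config(seed = 3L))
  wall <- ph$wall$data
  scar <- ph$ground_truth$scar_mask$data
  expect_true(all(wall %in% c(0, 1)))
  expect_true(all(scar <= wall))  # scar subset of wall
  expect_gt(sum(wall), sum(scar))
})

test_that("normal-class EGM voltages recover the configured log-normal median", {
  cfg <- small_phantom_config(seed = 9L, n_egm = 10000L)
  ph <- make_lv_phantom(cfg)
  egm <- simulate_egm_samples(ph$mesh, ph$ground_truth$node_scar_labels, cfg)
  expect_equal(nrow(egm), 10000L)
  med <- median(egm$bipolar_mV[egm$true_class == "normal"])
  expect_lt(abs(med - 3.8) / 3.8, 0.05)
  # jitter contract: every sample within 1 mm of its source vertex
  d <- egm[, c("x_mm", "y_mm", "z_mm")]
  vmap <- transform_points(ph$mesh$vertices[egm$vertex_id, ], cfg$frame_transform)
  expect_lte(max(sqrt(rowSums((as.matrix(d) - vmap)^2))), 1 + 1e-9)
})

test_that("pace-site capture and S-QRS tails follow the configured model", {
  cfg <- small_phantom_config(seed = 13L, n_pace = 5000L)
  ph <- make_lv_phantom(cfg)
  pace <- simulate_pace_sites(ph$mesh, ph$ground_truth$node_scar_labels, cfg)
  expect_equal(nrow(pace), 5000L)
  # s_qrs present exactly at captured sites; all non-negative
  expect_true(all(is.na(pace$s_qrs_ms) == !pace$captured))
  expect_true(all(pace$s_qrs_ms[pace$captured] >= 0))
  # normal sites always capture; scar failure rate near config
  expect_true(all(pace$captured[pace$true_class == "normal"]))
  fail <- mean(!pace$captured[pace$true_class == "scar"])
  expect_lt(abs(fail - cfg$capture_failure_prob), 0.05)
  # scar mean 60 sd 10: captured-scar fraction > 40 ms vs Gaussian tail
  sc <- pace$s_qrs_ms[pace$true_class == "scar" & pace$captured]
  tail_theory <- pnorm(40, 60, 10, lower.tail = FALSE) /
    pnorm(0, 60, 10, lower.tail = FALSE)
  expect_lt(abs(mean(sc > 40) - tail_theory), 0.02)
})

test_that("capture_failure_prob = 0 captures everywhere; n_pace = 0 is empty", {
  cfg <- small_phantom_config(seed = 4L, capture_failure_prob = 0)
  ph <- make_lv_phantom(cfg)
  pace <- simulate_pace_sites(ph$mesh, ph$ground_truth$node_scar_labels, cfg)
  expect_true(all(pace$captured))
  cfg0 <- small_phantom_config(seed = 4L, n_pace = 0L)
  expect_equal(nrow(simulate_pace_sites(ph$mesh, ph$ground_truth$node_scar_labels, cfg0)), 0L)
})

test_that("landmarks: zero noise reproduces the transform exactly; Kabsch residual matches", {
  cfg <- small_phantom_config(seed = 21L, landmark_noise_mm = 0)
  lm <- make_landmarks(cfg)
  src <- as.matrix(lm[, 1:3])
  dst <- as.matrix(lm[, 4:6])
  expect_equal(dst, transform_points(src, cfg$frame_transform),
               tolerance = 1e-12, ignore_attr = TRUE)
  cfgn <- small_phantom_config(seed = 21L, landmark_noise_mm = 0.5)
  lmn <- make_landmarks(cfgn)
  fit <- fit_rigid_landmarks(lmn)
  # independent SVD/Procrustes oracle residual
  s <- as.matrix(lmn[, 1:3]); d <- as.matrix(lmn[, 4:6])
  sc <- scale(s, scale = FALSE); dc <- scale(d, scale = FALSE)
  sv <- svd(t(sc) %*% dc)
  r <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  pred <- sc %*% t(r)
  oracle_rms <- sqrt(mean(rowSums((pred - dc)^2)))
  expect_equal(attr(fit, "rms_mm"), oracle_rms, tolerance = 1e-9)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(wall_thickness_mm = -1), "wall_thickness")
  expect_error(phantom_config(endo_radius_mm = 2, wall_thickness_mm = 6),
               "radius")
  expect_error(phantom_config(capture_failure_prob = 1.5), "capture_failure")
  expect_error(phantom_config(n_egm = -5), "n_egm")
  expect_error(phantom_config(
    voltage_model = list(normal = c(3.8, 0.5), scar = c(0, 0))), "median")
  expect_error(phantom_config(n_landmarks = 2), "landmarks")
})

test_that("widening the voltage-class gap increases downstream detection AUC", {
  aucs <- vapply(c(2.0, 3.8, 8.0), function(nm) {
    cfg <- small_phantom_config(
      seed = 33L,
      voltage_model = list(normal = c(median_mV = nm, sdlog = 0.5),
                           scar = c(median_mV = 0.8, sdlog = 0.5)))
    ph <- make_lv_phantom(cfg)
    egm <- simulate_egm_samples(ph$mesh, ph$ground_truth$node_scar_labels, cfg)
    roc_from_scores(egm$bipolar_mV, as.integer(egm$true_class == "scar"),
                    "low_positive")$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
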