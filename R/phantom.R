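#' @include phantom-config.R
NULL

# --- analytic membership helpers -------------------------------------------
# The phantom geometry is an ellipsoidal half-shell truncated at the basal
# plane z = lv centre, apex towards -z. All membership tests are closed-form
# so that voxel-by-voxel brute-force oracles exist.

ellipsoid_norm <- function(p, center, semi_axes) {
  d <- sweep(p, 2, center)
  d <- sweep(d, 2, semi_axes, "/")
  sqrt(rowSums(d^2))
}

wall_membership <- function(p, config) {
  endo <- config$endo_radius_mm
  epi <- endo + config$wall_thickness_mm
  r_endo <- ellipsoid_norm(p, config$lv_center_mm, endo)
  r_epi <- ellipsoid_norm(p, config$lv_center_mm, epi)
  basal <- p[, 3] <= config$lv_center_mm[3]
  list(
    blood = r_endo < 1 & basal,
    wall = r_endo >= 1 & r_epi <= 1 & basal
  )
}

# Angular + axial membership of the antero-septal scar patch; applied on top
# of wall membership (voxels) or directly to endocardial vertices (nodes).
scar_patch_membership <- function(p, config) {
  if (config$scar_angular_extent_deg <= 0 || config$scar_axial_extent_frac <= 0) {
    return(rep(FALSE, nrow(p)))
  }
  cz <- config$lv_center_mm[3]
  theta <- atan2(p[, 2] - config$lv_center_mm[2],
                 p[, 1] - config$lv_center_mm[1]) * 180 / pi
  delta <- ((theta - config$scar_center_deg + 180) %% 360) - 180
  ang_ok <- abs(delta) <= config$scar_angular_extent_deg / 2
  axial_extent <- config$endo_radius_mm[3] + config$wall_thickness_mm
  zmid <- cz - axial_extent / 2
  half <- config$scar_axial_extent_frac * axial_extent / 2
  ax_ok <- p[, 3] >= zmid - half & p[, 3] <= zmid + half
  ang_ok & ax_ok
}

# --- phantom construction --------------------------------------------------

#' Generate the synthetic LV phantom
#'
#' Builds an LGE-like intensity volume, the LV wall mask, the endocardial
#' triangle mesh, and the ground truth (scar voxel mask, per-vertex scar
#' labels, true image-to-mapping transform). The scar is transmural by
#' construction: every wall voxel inside the configured angular/axial patch
#' is scar, from endocardium to epicardium.
#'
#' @param config A [phantom_config()].
#' @return A list of class `lv_phantom` with elements `image`
#'   ([scar_volume()]), `wall` (binary [scar_volume()]), `mesh`
#'   ([surface_mesh()]), `ground_truth` (list: `scar_mask`,
#'   `node_scar_labels`, `true_transform`), and `config`.
#' @export
#' @examples
#' ph <- make_lv_phantom(phantom_config(grid_shape = c(24, 24, 24),
#'                                      spacing_mm = c(3, 3, 3), seed = 7))
#' sum(ph$ground_truth$scar_mask$data)
make_lv_phantom <- function(config) {
  assert_that(inherits(config, "phantom_config"),
              "config must be a phantom_config")
  gs <- config$grid_shape
  idx <- as.matrix(expand.grid(i = 0:(gs[1] - 1), j = 0:(gs[2] - 1),
                               k = 0:(gs[3] - 1)))
  world <- sweep(idx, 2, config$spacing_mm, "*")
  mem <- wall_membership(world, config)
  scar_vox <- mem$wall & scar_patch_membership(world, config)

  wall_arr <- array(as.numeric(mem$wall), gs)
  scar_arr <- array(as.numeric(scar_vox), gs)

  im <- config$intensity_model
  intens <- with_sub_seed(config$seed, "intensity", {
    v <- rnorm(nrow(world), im$background[["mean"]], im$background[["sd"]])
    v[mem$blood] <- rnorm(sum(mem$blood), im$blood[["mean"]], im$blood[["sd"]])
    v[mem$wall] <- rnorm(sum(mem$wall), im$normal_wall[["mean"]],
                         im$normal_wall[["sd"]])
    v[scar_vox] <- rnorm(sum(scar_vox), im$scar_wall[["mean"]],
                         im$scar_wall[["sd"]])
    v
  })

  mesh <- endocardial_mesh(config)
  node_scar <- as.integer(scar_patch_membership(mesh$vertices, config))

  structure(list(
    image = scar_volume(array(intens, gs), config$spacing_mm),
    wall = scar_volume(wall_arr, config$spacing_mm, binary = TRUE),
    mesh = mesh,
    ground_truth = list(
      scar_mask = scar_volume(scar_arr, config$spacing_mm, binary = TRUE),
      node_scar_labels = node_scar,
      true_transform = config$frame_transform
    ),
    config = config
  ), class = "lv_phantom")
}

# UV-sphere triangulation of the endocardial half-ellipsoid: n_phi rings
# from the equator (basal plane) towards the apex, plus an apex pole vertex.
endocardial_mesh <- function(config) {
  nt <- config$mesh_resolution[[1]]
  np <- config$mesh_resolution[[2]]
  r <- config$endo_radius_mm
  ctr <- config$lv_center_mm
  theta <- 2 * pi * (0:(nt - 1)) / nt
  phi <- pi / 2 + (pi / 2) * (0:(np - 1)) / np
  grid <- expand.grid(theta = theta, phi = phi)
  verts <- cbind(
    ctr[1] + r[1] * cos(grid$theta) * sin(grid$phi),
    ctr[2] + r[2] * sin(grid$theta) * sin(grid$phi),
    ctr[3] + r[3] * cos(grid$phi)
  )
  verts <- rbind(verts, c(ctr[1], ctr[2], ctr[3] - r[3]))
  pole <- nrow(verts)
  vid <- function(k, j) k * nt + (j %% nt) + 1L
  faces <- list()
  for (k in 0:(np - 2)) {
    j <- 0:(nt - 1)
    faces[[length(faces) + 1]] <- cbind(vid(k, j), vid(k, j + 1), vid(k + 1, j + 1))
    faces[[length(faces) + 1]] <- cbind(vid(k, j), vid(k + 1, j + 1), vid(k + 1, j))
  }
  j <- 0:(nt - 1)
  faces[[length(faces) + 1]] <- cbind(vid(np - 1, j), vid(np - 1, j + 1), pole)
  surface_mesh(verts, do.call(rbind, faces))
}

# --- sample simulation -----------------------------------------------------

# Weighted vertex draw shared by EGM and pace-site simulation; scar vertices
# are oversampled to mimic mapping focused on LGE regions.
draw_sample_vertices <- function(n, labels, config) {
  w <- ifelse(labels == 1L, config$scar_oversample, 1)
  sample.int(length(labels), n, replace = TRUE, prob = w)
}

# Uniform jitter inside a 1 mm ball, so samples sit near but not exactly on
# their vertex (catheter-tip localisation error).
jitter_in_ball <- function(n, radius_mm = 1) {
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
  dir * radius_mm * runif(n)^(1 / 3)
}

#' Simulate electrogram samples on the phantom
#'
#' Draws `n_egm` sampling points at (jittered) mesh vertex positions, with
#' scar vertices oversampled by `scar_oversample`. Bipolar voltage is drawn
#' from the class-conditional log-normal; local activation time from a
#' smooth field (linear in distance from an apical activation origin, plus a
#' conduction delay inside scar and Gaussian noise). Output positions are in
#' the mapping frame, i.e. the true frame transform has been applied.
#'
#' @param mesh The phantom's [surface_mesh()] (image frame).
#' @param labels Integer 0/1 per-vertex scar labels.
#' @param config The [phantom_config()].
#' @return A tibble with columns `x_mm`, `y_mm`, `z_mm` (mapping frame),
#'   `bipolar_mV`, `lat_ms`, `true_class` (`"normal"`/`"scar"`), `vertex_id`.
#' @export
simulate_egm_samples <- function(mesh, labels, config) {
  assert_that(length(labels) == n_vertices(mesh),
              "labels must be defined on mesh vertices")
  assert_that(config$n_egm >= 0, "n_egm must be non-negative")
  n <- config$n_egm
  apex <- mesh$vertices[which.min(mesh$vertices[, 3])[1], ]
  lm <- config$lat_model
  with_sub_seed(config$seed, "egm", {
    vi <- draw_sample_vertices(n, labels, config)
    pos <- mesh$vertices[vi, , drop = FALSE] + jitter_in_ball(n)
    cls <- ifelse(labels[vi] == 1L, "scar", "normal")
    vm <- config$voltage_model
    med <- ifelse(cls == "scar", vm$scar[[1]], vm$normal[[1]])
    sdl <- ifelse(cls == "scar", vm$scar[[2]], vm$normal[[2]])
    volt <- rlnorm(n, meanlog = log(med), sdlog = sdl)
    d_apex <- sqrt(rowSums(sweep(mesh$vertices[vi, , drop = FALSE], 2, apex)^2))
    lat <- lm[["offset_ms"]] + lm[["slope_ms_per_mm"]] * d_apex +
      lm[["scar_delay_ms"]] * (cls == "scar") +
      rnorm(n, 0, lm[["noise_sd_ms"]])
    pos_map <- transform_points(pos, config$frame_transform)
    tibble::tibble(
      x_mm = pos_map[, 1], y_mm = pos_map[, 2], z_mm = pos_map[, 3],
      bipolar_mV = volt, lat_ms = lat, true_class = cls,
      vertex_id = as.integer(vi)
    )
  })
}

#' Simulate pace-mapping sites on the phantom
#'
#' Draws `n_pace` pacing sites at mesh vertices (scar oversampled as for
#' EGMs). Pacing at a scar site fails to capture with probability
#' `capture_failure_prob`; captured sites carry a stimulus-to-QRS interval
#' drawn from the class-conditional Gaussian truncated at 0 ms (inverse-CDF
#' sampling). Positions are in the mapping frame.
#'
#' @inheritParams simulate_egm_samples
#' @return A tibble with columns `x_mm`, `y_mm`, `z_mm`, `captured`
#'   (logical), `s_qrs_ms` (`NA` when not captured), `true_class`,
#'   `vertex_id`.
#' @export
simulate_pace_sites <- function(mesh, labels, config) {
  assert_that(length(labels) == n_vertices(mesh),
              "labels must be defined on mesh vertices")
  assert_that(config$n_pace >= 0, "n_pace must be non-negative")
  n <- config$n_pace
  with_sub_seed(config$seed, "pace", {
    vi <- draw_sample_vertices(n, labels, config)
    pos <- mesh$vertices[vi, , drop = FALSE] + jitter_in_ball(n)
    cls <- ifelse(labels[vi] == 1L, "scar", "normal")
    captured <- ifelse(cls == "scar",
                       runif(n) >= config$capture_failure_prob, TRUE)
    sm <- config$sqrs_model
    mu <- ifelse(cls == "scar", sm$scar[[1]], sm$normal[[1]])
    sd <- ifelse(cls == "scar", sm$scar[[2]], sm$normal[[2]])
    # truncated-at-0 normal via inverse CDF
    lo <- pnorm(0, mu, sd)
    sqrs <- qnorm(lo + runif(n) * (1 - lo), mu, sd)
    sqrs[!captured] <- NA_real_
    pos_map <- transform_points(pos, config$frame_transform)
    tibble::tibble(
      x_mm = pos_map[, 1], y_mm = pos_map[, 2], z_mm = pos_map[, 3],
      captured = captured, s_qrs_ms = sqrs, true_class = cls,
      vertex_id = as.integer(vi)
    )
  })
}

#' Generate landmark correspondences between frames
#'
#' Emulates selecting fiducial points in the blood pools of both data sets:
#' source points are drawn around the chamber in the image frame and
#' destination points are the true frame transform applied to them plus
#' isotropic Gaussian localisation noise of `landmark_noise_mm`.
#'
#' @param config The [phantom_config()].
#' @return A tibble with columns `src_x_mm` ... `dst_z_mm`.
#' @export
make_landmarks <- function(config) {
  assert_that(config$n_landmarks >= 3, "need at least 3 landmarks")
  n <- config$n_landmarks
  with_sub_seed(config$seed, "landmarks", {
    dir <- matrix(rnorm(3 * n), ncol = 3)
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
    radius <- runif(n, 0.3, 1.3) * mean(config$endo_radius_mm)
    src <- sweep(dir * radius, 2, config$lv_center_mm, "+")
    assert_that(!points_collinear(src, tol = 1e-6),
                "generated landmarks are collinear; use more landmarks")
    dst <- transform_points(src, config$frame_transform) +
      matrix(rnorm(3 * n, 0, config$landmark_noise_mm), ncol = 3)
    tibble::tibble(
      src_x_mm = src[, 1], src_y_mm = src[, 2], src_z_mm = src[, 3],
      dst_x_mm = dst[, 1], dst_y_mm = dst[, 2], dst_z_mm = dst[, 3]
    )
  })
}
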