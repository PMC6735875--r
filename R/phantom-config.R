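#' Configure the synthetic left-ventricular phantom
#'
#' The phantom stands in for the study's animal data: an LGE-like intensity
#' volume with an antero-septal transmural scar inside an ellipsoidal
#' half-shell LV wall, an endocardial triangle mesh, simulated electrogram
#' and pace-site tables, landmark correspondences, and a known rigid
#' misalignment between the image and mapping coordinate frames. The
#' analytic shell geometry makes every membership question (is this voxel
#' wall? scar?) answerable by a brute-force per-voxel test, which is what
#' the test suite exploits.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing_mm Numeric length-3, voxel size (mm); default the 1.2 mm
#'   isotropic resolution typical of high-resolution 3D LGE.
#' @param lv_center_mm LV centre in world mm; default grid centre.
#' @param endo_radius_mm Endocardial ellipsoid semi-axes (mm); the long axis
#'   is z and the shell is truncated at the basal plane `z = lv_center_mm[3]`
#'   (apex pointing to -z).
#' @param wall_thickness_mm Radial wall thickness (mm).
#' @param scar_center_deg Azimuth (degrees, about +z from +x) of the scar
#'   patch centre.
#' @param scar_angular_extent_deg Angular width of the scar patch (degrees);
#'   0 yields a scar-free phantom.
#' @param scar_axial_extent_frac Fraction of the half-shell's axial extent
#'   covered by the scar band (centred mid-wall axially).
#' @param intensity_model Named list of `c(mean, sd)` signal intensities
#'   (arbitrary units) for `background`, `blood`, `normal_wall`, `scar_wall`.
#' @param voltage_model Named list with `normal` and `scar` entries, each
#'   `c(median_mV, sdlog)`: class-conditional log-normal bipolar amplitudes.
#' @param sqrs_model Named list with `normal` and `scar` entries, each
#'   `c(mean_ms, sd_ms)`: class-conditional stimulus-to-QRS Gaussians,
#'   truncated at 0.
#' @param lat_model `c(offset_ms, slope_ms_per_mm, scar_delay_ms, noise_sd_ms)`
#'   for the smooth activation field (distance from an apical origin).
#' @param capture_failure_prob Probability that pacing at a scar site fails
#'   to capture.
#' @param n_egm,n_pace Numbers of electrogram samples and pace sites.
#' @param scar_oversample Relative sampling weight of scar vertices when
#'   placing EGM/pace points, reflecting mapping focused on LGE regions.
#' @param frame_transform True [rigid_transform()] from the image frame to
#'   the mapping frame.
#' @param n_landmarks,landmark_noise_mm Landmark count and isotropic Gaussian
#'   localisation noise (mm) on destination points.
#' @param mesh_resolution `c(n_theta, n_phi)` angular resolution of the
#'   endocardial mesh.
#' @param seed Integer root seed; every generator operation derives its own
#'   deterministic sub-stream from it.
#'
#' @return A validated list of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(seed = 1)
#' cfg$voltage_model$scar
phantom_config <- function(
    grid_shape = c(64L, 64L, 64L),
    spacing_mm = c(1.2, 1.2, 1.2),
    lv_center_mm = NULL,
    endo_radius_mm = c(22, 18, 28),
    wall_thickness_mm = 6,
    scar_center_deg = 0,
    scar_angular_extent_deg = 90,
    scar_axial_extent_frac = 0.4,
    intensity_model = list(
      background = c(mean = 5, sd = 2),
      blood = c(mean = 60, sd = 5),
      normal_wall = c(mean = 30, sd = 3),
      scar_wall = c(mean = 90, sd = 9)
    ),
    voltage_model = list(
      normal = c(median_mV = 3.8, sdlog = 0.5),
      scar = c(median_mV = 0.8, sdlog = 0.5)
    ),
    sqrs_model = list(
      normal = c(mean_ms = 25, sd_ms = 8),
      scar = c(mean_ms = 60, sd_ms = 10)
    ),
    lat_model = c(offset_ms = 5, slope_ms_per_mm = 1.2,
                  scar_delay_ms = 25, noise_sd_ms = 3),
    capture_failure_prob = 0.3,
    n_egm = 445,
    n_pace = 113,
    scar_oversample = 4,
    frame_transform = rigid_transform(rotation_about_axis(c(0, 0, 1), 10),
                                      c(5, -3, 2)),
    n_landmarks = 8,
    landmark_noise_mm = 0.5,
    mesh_resolution = c(n_theta = 48L, n_phi = 24L),
    seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  assert_that(length(grid_shape) == 3L && all(grid_shape >= 8L),
              "grid_shape must be 3 integers >= 8")
  assert_that(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "spacing_mm must be positive")
  if (is.null(lv_center_mm)) {
    lv_center_mm <- (grid_shape - 1) * spacing_mm / 2
  }
  endo_radius_mm <- as.numeric(endo_radius_mm)
  if (length(endo_radius_mm) == 1L) endo_radius_mm <- rep(endo_radius_mm, 3)
  assert_that(all(endo_radius_mm > 0), "endo_radius_mm must be positive")
  assert_that(wall_thickness_mm > 0, "wall_thickness_mm must be positive")
  assert_that(min(endo_radius_mm) > wall_thickness_mm / 2,
              "endocardial radius must exceed half the wall thickness")
  assert_that(scar_angular_extent_deg >= 0 && scar_angular_extent_deg <= 360,
              "scar_angular_extent_deg must be in [0, 360]")
  assert_that(scar_axial_extent_frac >= 0 && scar_axial_extent_frac <= 1,
              "scar_axial_extent_frac must be in [0, 1]")
  for (cls in c("normal", "scar")) {
    vm <- voltage_model[[cls]]
    assert_that(!is.null(vm) && length(vm) == 2L,
                "voltage_model$%s must be c(median_mV, sdlog)", cls)
    assert_that(vm[[1]] > 0,
                "voltage_model$%s median must be > 0 mV (log-normal)", cls)
    assert_that(vm[[2]] >= 0, "voltage_model$%s log-SD must be >= 0", cls)
    sm <- sqrs_model[[cls]]
    assert_that(!is.null(sm) && length(sm) == 2L && sm[[2]] >= 0,
                "sqrs_model$%s must be c(mean_ms, sd_ms >= 0)", cls)
  }
  assert_that(capture_failure_prob >= 0 && capture_failure_prob <= 1,
              "capture_failure_prob must be in [0, 1]")
  assert_that(n_egm >= 0, "n_egm must be non-negative")
  assert_that(n_pace >= 0, "n_pace must be non-negative")
  assert_that(scar_oversample > 0, "scar_oversample must be positive")
  assert_that(inherits(frame_transform, "rigid_transform"),
              "frame_transform must be a rigid_transform")
  assert_that(n_landmarks >= 3, "need at least 3 landmarks")
  assert_that(landmark_noise_mm >= 0, "landmark_noise_mm must be >= 0")
  mesh_resolution <- as.integer(mesh_resolution)
  assert_that(length(mesh_resolution) == 2L && all(mesh_resolution >= 6L),
              "mesh_resolution must be c(n_theta, n_phi) with both >= 6")
  structure(list(
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    lv_center_mm = as.numeric(lv_center_mm),
    endo_radius_mm = endo_radius_mm, wall_thickness_mm = wall_thickness_mm,
    scar_center_deg = scar_center_deg,
    scar_angular_extent_deg = scar_angular_extent_deg,
    scar_axial_extent_frac = scar_axial_extent_frac,
    intensity_model = intensity_model, voltage_model = voltage_model,
    sqrs_model = sqrs_model, lat_model = lat_model,
    capture_failure_prob = capture_failure_prob,
    n_egm = as.integer(n_egm), n_pace = as.integer(n_pace),
    scar_oversample = scar_oversample, frame_transform = frame_transform,
    n_landmarks = as.integer(n_landmarks),
    landmark_noise_mm = landmark_noise_mm,
    mesh_resolution = mesh_resolution, seed = as.integer(seed)
  ), class = "phantom_config")
}
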