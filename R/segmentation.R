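#' Full-width-half-maximum scar segmentation
#'
#' Labels as scar every LV-wall voxel whose signal intensity is strictly
#' above `fwhm_frac` times the maximum intensity within the wall mask (the
#' FWHM rule with its conventional 50% cut). The maximum is taken over wall
#' voxels only and no pre-filtering is applied; an optional percentile clip
#' (`clip_quantile`) is available to blunt hyper-intense outliers but is off
#' by default.
#'
#' @param volume The LGE-like [scar_volume()].
#' @param wall Binary wall-mask [scar_volume()] on the same grid.
#' @param fwhm_frac Fraction of the wall maximum defining the threshold
#'   (default 0.5).
#' @param clip_quantile If non-`NULL`, use this intensity quantile of wall
#'   voxels instead of the plain maximum (e.g. 0.99).
#' @return A binary [scar_volume()] (scar = 1), a subset of the wall mask,
#'   with attribute `threshold` (the intensity cut actually applied).
#' @export
#' @examples
#' img <- scar_volume(array(c(100, 51, 50, 49, 0, 0, 0, 0), c(2, 2, 2)))
#' wll <- scar_volume(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)), binary = TRUE)
#' sum(fwhm_segment(img, wll)$data)  # 2: only 100 and 51 exceed 50
fwhm_segment <- function(volume, wall, fwhm_frac = 0.5, clip_quantile = NULL) {
  assert_that(inherits(volume, "scar_volume"), "volume must be a scar_volume")
  assert_that(inherits(wall, "scar_volume"), "wall must be a scar_volume")
  assert_that(identical(dim(volume$data), dim(wall$data)),
              "wall mask shape does not match image shape")
  assert_that(fwhm_frac > 0 && fwhm_frac <= 1, "fwhm_frac must be in (0, 1]")
  in_wall <- wall$data == 1
  assert_that(any(in_wall), "wall mask is empty: maximum intensity undefined")
  wall_int <- volume$data[in_wall]
  ref <- if (is.null(clip_quantile)) {
    max(wall_int)
  } else {
    stats::quantile(wall_int, clip_quantile, names = FALSE)
  }
  thr <- fwhm_frac * ref
  scar <- array(0, dim(volume$data))
  scar[in_wall & volume$data > thr] <- 1
  out <- scar_volume(scar, volume$spacing_mm, volume$affine, binary = TRUE)
  attr(out, "threshold") <- thr
  out
}

#' Scar mask to world-coordinate point cloud
#'
#' One point per scar voxel, at the voxel centre mapped through the
#' volume's voxel-to-world affine. This is the point set that gets
#' registered and projected onto the endocardial mesh.
#'
#' @param scar Binary [scar_volume()].
#' @return n x 3 matrix of world positions (mm); 0 rows for an empty mask.
#' @export
scar_point_cloud <- function(scar) {
  assert_that(inherits(scar, "scar_volume"), "scar must be a scar_volume")
  w <- which(scar$data == 1, arr.ind = TRUE)
  if (nrow(w) == 0L) return(matrix(numeric(0), ncol = 3))
  voxel_to_world(scar, w - 1L)
}
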