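#' Image and label volumes
#'
#' A `scar_volume` is a 3D scalar grid plus a voxel-index-to-world-millimetre
#' affine, the minimal container needed to hold an LGE-like intensity image or
#' a binary mask (LV wall, scar). Voxel indices are 0-based and the voxel
#' centre of index `(i, j, k)` maps to world coordinates
#' `affine %*% c(i, j, k, 1)`, following the NIfTI convention.
#'
#' @param data 3D numeric array (signal intensity in arbitrary units, or 0/1
#'   labels for a mask).
#' @param spacing_mm Numeric length-3, voxel size per axis in mm. Ignored when
#'   a full `affine` is supplied.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling by
#'   `spacing_mm` (no rotation, origin at voxel (0,0,0)).
#' @param binary Logical; validate `data` as a 0/1 label volume.
#'
#' @return An object of class `scar_volume` (and `scar_label_volume` when
#'   `binary = TRUE`).
#' @export
#' @examples
#' v <- scar_volume(array(runif(8), c(2, 2, 2)), spacing_mm = c(1.2, 1.2, 1.2))
#' dim(v$data)
scar_volume <- function(data, spacing_mm = c(1, 1, 1), affine = NULL,
                        binary = FALSE) {
  data <- as.array(data)
  assert_that(length(dim(data)) == 3L, "volume data must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  assert_that(length(spacing_mm) == 3L && all(spacing_mm > 0),
              "spacing_mm must be 3 positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
  }
  affine <- as.matrix(affine)
  assert_that(all(dim(affine) == c(4L, 4L)), "affine must be 4x4")
  assert_that(abs(det(affine)) > .Machine$double.eps,
              "affine must be invertible")
  if (binary) {
    assert_that(all(data %in% c(0, 1)), "label volume values must be 0 or 1")
  }
  structure(
    list(data = data, spacing_mm = spacing_mm, affine = affine),
    class = c(if (binary) "scar_label_volume", "scar_volume")
  )
}

#' @export
print.scar_volume <- function(x, ...) {
  kind <- if (inherits(x, "scar_label_volume")) "label volume" else "image volume"
  cat(sprintf("<scar_volume: %s %s, spacing %s mm>\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param volume A [scar_volume()].
#' @param idx Integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world positions (mm).
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- as_point_matrix(idx)
  h <- cbind(idx, 1) %*% t(volume$affine)
  h[, 1:3, drop = FALSE]
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the voxel-to-world affine intact.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param binary Read as a binary label volume.
#' @return [read_volume_nifti()] returns a [scar_volume()];
#'   [write_volume_nifti()] returns `path` invisibly.
#' @export
read_volume_nifti <- function(path, binary = FALSE) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  dat <- as.array(img)
  if (binary) dat <- (dat != 0) + 0
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  scar_volume(dat, spacing_mm = spacing, affine = aff, binary = binary)
}

#' @rdname read_volume_nifti
#' @param volume A [scar_volume()] to write.
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
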