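#' Read and write the pipeline's CSV and JSON artifacts
#'
#' Plain-CSV round-trip helpers for the tables the pipeline exchanges:
#' electrogram samples (`x_mm,y_mm,z_mm,bipolar_mV,lat_ms,true_class`),
#' pace sites (`x_mm,y_mm,z_mm,captured,s_qrs_ms,true_class`), landmark
#' correspondences (`src_x_mm..dst_z_mm`), per-vertex node maps
#' (`vertex_id,value,known`), and rigid transforms as JSON (row-major
#' rotation plus translation).
#'
#' @param x Table or object to write.
#' @param path File path.
#' @return Readers return tibbles (or a [rigid_transform()]); writers return
#'   `path` invisibly.
#' @name scarconcord-io
NULL

write_csv_plain <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname scarconcord-io
#' @export
write_egm_csv <- function(x, path) {
  keep <- intersect(c("x_mm", "y_mm", "z_mm", "bipolar_mV", "lat_ms",
                      "true_class"), names(x))
  write_csv_plain(x[keep], path)
}

#' @rdname scarconcord-io
#' @export
read_egm_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname scarconcord-io
#' @export
write_pace_csv <- function(x, path) {
  keep <- intersect(c("x_mm", "y_mm", "z_mm", "captured", "s_qrs_ms",
                      "true_class"), names(x))
  write_csv_plain(x[keep], path)
}

#' @rdname scarconcord-io
#' @export
read_pace_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out$captured <- as.logical(out$captured)
  out
}

#' @rdname scarconcord-io
#' @export
write_landmarks_csv <- function(x, path) write_csv_plain(x, path)

#' @rdname scarconcord-io
#' @export
read_landmarks_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname scarconcord-io
#' @export
write_node_map_csv <- function(x, path) {
  if (!is.data.frame(x)) x <- node_map(x, known = rep(TRUE, length(x)))
  write_csv_plain(x[c("vertex_id", "value", "known")], path)
}

#' @rdname scarconcord-io
#' @export
read_node_map_csv <- function(path) {
  df <- utils::read.csv(path)
  nm <- node_map(df$value, as.logical(df$known))
  nm
}

#' @rdname scarconcord-io
#' @param transform A [rigid_transform()].
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(
    rotation_row_major = as.numeric(t(transform$rotation)),
    translation_mm = transform$translation,
    rms_mm = attr(transform, "rms_mm"),
    mean_distance_mm = attr(transform, "mean_distance_mm")
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scarconcord-io
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(j$rotation_row_major, 3, 3, byrow = TRUE),
                  j$translation_mm)
}

#' Write all phantom artifacts to a directory
#'
#' Writes the LGE-like image, wall and scar-truth masks (NIfTI), the
#' endocardial mesh (ASCII PLY), the EGM/pace/landmark tables (CSV), and a
#' ground-truth JSON sidecar (node scar labels and the true transform).
#'
#' @param phantom An `lv_phantom` from [make_lv_phantom()].
#' @param egm,pace,landmarks The simulated tables.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, egm, pace, landmarks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume_nifti(phantom$image, file.path(dir, "lge.nii.gz"))
  write_volume_nifti(phantom$wall, file.path(dir, "wall.nii.gz"))
  write_volume_nifti(phantom$ground_truth$scar_mask,
                     file.path(dir, "scar_truth.nii.gz"))
  write_mesh_ply(phantom$mesh, file.path(dir, "endo.ply"))
  # the same mesh expressed in the mapping frame, where egm.csv/pace.csv live
  write_mesh_ply(transform_mesh(phantom$mesh,
                                phantom$ground_truth$true_transform),
                 file.path(dir, "endo_mapping.ply"))
  write_egm_csv(egm, file.path(dir, "egm.csv"))
  write_pace_csv(pace, file.path(dir, "pace.csv"))
  write_landmarks_csv(landmarks, file.path(dir, "landmarks.csv"))
  tt <- phantom$ground_truth$true_transform
  jsonlite::write_json(list(
    node_scar_labels = phantom$ground_truth$node_scar_labels,
    true_transform = list(
      rotation_row_major = as.numeric(t(tt$rotation)),
      translation_mm = tt$translation
    )
  ), file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}
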