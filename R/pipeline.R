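#' Transform a mesh between coordinate frames
#'
#' Applies a rigid transform to every vertex; the face topology (and hence
#' any per-vertex map) is unchanged.
#'
#' @param mesh A [surface_mesh()].
#' @param transform A [rigid_transform()].
#' @return A [surface_mesh()].
#' @export
transform_mesh <- function(mesh, transform) {
  surface_mesh(transform_points(mesh$vertices, transform), mesh$faces)
}

default_pipeline_config <- function() {
  list(
    phantom = list(),          # phantom_config() overrides; NULL disables simulation
    inputs = NULL,             # named file paths when not simulating
    out_dir = NULL,            # where artifacts go; NULL keeps everything in memory
    fwhm_frac = 0.5,
    clip_quantile = NULL,
    voltage_threshold_mV = 1.5,
    dice_thresholds_mV = seq(0.5, 3.5, by = 0.5),
    dice_average = "micro",
    measured_only = FALSE,
    slow_ms = 40,
    very_slow_ms = 80,
    use_icp = TRUE,
    icp_tol = 1e-4,
    icp_max_iter = 100,
    max_dist_mm = 5,
    seed = 1L
  )
}

#' Run the full scar-voltage concordance pipeline
#'
#' Executes the study's analysis sequence end to end: generate (or load)
#' the inputs, FWHM-segment the LGE volume within the wall, register the
#' scar point cloud into the mapping frame (landmark fit, optionally
#' refined by ICP against the endocardial mesh), project scar points onto
#' mesh nodes, build and interpolate the voltage/activation maps from the
#' electrograms, compute nodal Dice concordance at the working threshold
#' and across the threshold sweep, derive per-electrogram and per-pace-site
#' diagnostic accuracy against the LGE-derived gold standard, and classify
#' stimulus-to-QRS delays.
#'
#' @param config A named list overriding the defaults (see Details), or a
#'   path to a YAML file holding such a list. Recognised keys include
#'   `phantom` (overrides passed to [phantom_config()]), `inputs` (file
#'   paths `image`, `wall`, `mesh`, `egm`, `pace`, `landmarks` when not
#'   simulating), `out_dir`, `fwhm_frac`, `voltage_threshold_mV`,
#'   `dice_thresholds_mV`, `dice_average`, `measured_only`, `slow_ms`,
#'   `very_slow_ms`, `use_icp`, `max_dist_mm`, `seed`.
#' @return A list of class `concordance_report`: `registration`, `dice`,
#'   `dice_sweep`, `diagnostics` (voltage and S-QRS summaries + ROC),
#'   `sqrs`, `config`, plus the intermediate objects in `$objects`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }

  # --- inputs -------------------------------------------------------------
  simulate <- is.null(cfg$inputs)
  if (simulate) {
    pcfg <- stage("phantom", do.call(phantom_config,
                                     utils::modifyList(list(seed = cfg$seed),
                                                       as.list(cfg$phantom))))
    phantom <- stage("phantom", make_lv_phantom(pcfg))
    mesh_img <- phantom$mesh
    true_t <- phantom$ground_truth$true_transform
    mesh_map <- transform_mesh(mesh_img, true_t)
    egm <- stage("phantom", simulate_egm_samples(
      mesh_img, phantom$ground_truth$node_scar_labels, pcfg))
    pace <- stage("phantom", simulate_pace_sites(
      mesh_img, phantom$ground_truth$node_scar_labels, pcfg))
    landmarks <- stage("phantom", make_landmarks(pcfg))
    image <- phantom$image
    wall <- phantom$wall
    if (!is.null(cfg$out_dir)) {
      stage("phantom", write_phantom(phantom, egm, pace, landmarks,
                                     file.path(cfg$out_dir, "phantom")))
    }
  } else {
    phantom <- NULL
    image <- stage("inputs", read_volume_nifti(cfg$inputs$image))
    wall <- stage("inputs", read_volume_nifti(cfg$inputs$wall, binary = TRUE))
    mesh_map <- stage("inputs", read_mesh_ply(cfg$inputs$mesh))
    egm <- stage("inputs", read_egm_csv(cfg$inputs$egm))
    pace <- if (!is.null(cfg$inputs$pace)) {
      stage("inputs", read_pace_csv(cfg$inputs$pace))
    }
    landmarks <- stage("inputs", read_landmarks_csv(cfg$inputs$landmarks))
  }

  # --- segmentation -------------------------------------------------------
  scar_mask <- stage("segment", fwhm_segment(image, wall, cfg$fwhm_frac,
                                             cfg$clip_quantile))
  scar_pts <- stage("segment", scar_point_cloud(scar_mask))

  # --- registration -------------------------------------------------------
  t_landmark <- stage("register", fit_rigid_landmarks(landmarks))
  t_final <- t_landmark
  if (isTRUE(cfg$use_icp) && nrow(scar_pts) > 0) {
    t_final <- stage("register", icp_refine(scar_pts, mesh_map,
                                            init = t_landmark,
                                            tol = cfg$icp_tol,
                                            max_iter = cfg$icp_max_iter))
  }
  scar_pts_map <- transform_points(scar_pts, t_final)
  lge_nodes <- stage("register", map_points_to_nodes(scar_pts_map, mesh_map,
                                                     cfg$max_dist_mm))

  # --- voltage / activation maps ------------------------------------------
  maps <- stage("map", assign_egm_to_nodes(egm, mesh_map))
  voltage_full <- stage("map", relax_interpolate(maps$voltage, mesh_map))
  lat_full <- if (any(maps$lat$known)) {
    stage("map", relax_interpolate(maps$lat, mesh_map))
  }

  # --- dice concordance ---------------------------------------------------
  vsel <- if (isTRUE(cfg$measured_only)) which(maps$voltage$known) else
    seq_len(n_vertices(mesh_map))
  volt_vals <- voltage_full$value[vsel]
  lge_sel <- as.integer(lge_nodes)[vsel]
  dice_at <- stage("dice", dice_binary(
    binarize_map(volt_vals, cfg$voltage_threshold_mV), lge_sel,
    threshold_mV = cfg$voltage_threshold_mV, average = cfg$dice_average))
  sweep <- stage("dice", dice_threshold_sweep(
    volt_vals, lge_sel, cfg$dice_thresholds_mV, average = cfg$dice_average))

  # --- diagnostics against the LGE gold standard --------------------------
  egm_truth <- as.integer(lge_nodes)[maps$assignment]
  volt_diag <- stage("diagnostics", {
    test <- as.integer(egm$bipolar_mV < cfg$voltage_threshold_mV)
    diagnostic_summary(confusion_counts(test, egm_truth))
  })
  volt_roc <- if (length(unique(egm_truth)) == 2) {
    stage("diagnostics", roc_from_scores(egm$bipolar_mV, egm_truth,
                                         "low_positive"))
  } else {
    list(skipped = TRUE, reason = "single-class truth")
  }

  sqrs <- NULL
  sqrs_diag <- NULL
  sqrs_roc <- NULL
  if (!is.null(pace) && nrow(pace) > 0) {
    sqrs <- stage("sqrs", classify_sqrs(pace, cfg$slow_ms, cfg$very_slow_ms))
    cap <- sqrs$sites[sqrs$sites$captured, ]
    if (nrow(cap) > 0) {
      pace_idx <- as.integer(nearest_index(cap, mesh_map$vertices))
      pace_truth <- as.integer(lge_nodes)[pace_idx]
      sqrs_diag <- stage("sqrs", diagnostic_summary(confusion_counts(
        as.integer(cap$s_qrs_ms > cfg$slow_ms), pace_truth)))
      sqrs_roc <- if (length(unique(pace_truth)) == 2) {
        stage("sqrs", roc_from_scores(cap$s_qrs_ms, pace_truth,
                                      "high_positive"))
      } else {
        list(skipped = TRUE, reason = "single-class truth")
      }
    }
  }

  report <- structure(list(
    registration = list(
      landmark_rms_mm = attr(t_landmark, "rms_mm"),
      icp_used = isTRUE(cfg$use_icp) && nrow(scar_pts) > 0,
      icp_mean_distance_mm = attr(t_final, "mean_distance_mm"),
      icp_iterations = attr(t_final, "iterations"),
      icp_converged = attr(t_final, "converged"),
      n_scar_points = nrow(scar_pts),
      n_points_discarded = attr(lge_nodes, "n_discarded"),
      transform = t_final
    ),
    dice = dice_at,
    dice_sweep = sweep,
    diagnostics = list(voltage = volt_diag, voltage_roc = volt_roc,
                       sqrs = sqrs_diag, sqrs_roc = sqrs_roc),
    sqrs = sqrs,
    config = cfg,
    objects = list(
      phantom = phantom, mesh = mesh_map, scar_mask = scar_mask,
      lge_nodes = lge_nodes, voltage = voltage_full, lat = lat_full,
      egm = egm, pace = pace, landmarks = landmarks
    )
  ), class = "concordance_report")

  if (!is.null(cfg$out_dir)) {
    write_report_json(report, file.path(cfg$out_dir, "report.json"))
    write_node_map_csv(voltage_full, file.path(cfg$out_dir, "voltage_map.csv"))
    write_node_map_csv(node_map(as.numeric(lge_nodes),
                                rep(TRUE, length(lge_nodes))),
                       file.path(cfg$out_dir, "lge_node_map.csv"))
    write_transform_json(t_final, file.path(cfg$out_dir, "transform.json"))
  }
  report
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  cat(sprintf("  registration: landmark RMS %.3f mm, %s\n",
              x$registration$landmark_rms_mm,
              if (x$registration$icp_used) {
                sprintf("ICP mean distance %.3f mm (%d iterations)",
                        x$registration$icp_mean_distance_mm,
                        x$registration$icp_iterations)
              } else "no ICP"))
  cat(sprintf("  dice @ %.1f mV: total %.3f, scar %.3f, normal %.3f\n",
              x$dice$threshold_mV, x$dice$dsc_total, x$dice$dsc_scar,
              x$dice$dsc_normal))
  d <- x$diagnostics$voltage
  cat(sprintf("  voltage diagnostics: sens %.2f, spec %.2f, ppv %.2f, npv %.2f\n",
              d$sensitivity, d$specificity, d$ppv, d$npv))
  if (!is.null(x$diagnostics$voltage_roc$auc)) {
    cat(sprintf("  voltage ROC AUC: %.3f\n", x$diagnostics$voltage_roc$auc))
  }
  if (!is.null(x$diagnostics$sqrs_roc$auc)) {
    cat(sprintf("  S-QRS ROC AUC: %.3f\n", x$diagnostics$sqrs_roc$auc))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Writes the quantitative content of a [run_pipeline()] report (Dice
#' table, diagnostic summaries, AUCs, S-QRS proportions, registration
#' residuals and discard counts) as a single JSON document; intermediate
#' objects are not serialised.
#'
#' @param report A `concordance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  roc_entry <- function(r) {
    if (is.null(r)) return(NULL)
    if (!is.null(r$skipped)) return(r)
    list(auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg,
         orientation = r$orientation)
  }
  reg <- report$registration
  reg$transform <- list(
    rotation_row_major = as.numeric(t(reg$transform$rotation)),
    translation_mm = reg$transform$translation
  )
  out <- list(
    registration = reg,
    dice = as.list(report$dice),
    dice_sweep = lapply(seq_len(nrow(report$dice_sweep)), function(i) {
      as.list(report$dice_sweep[i, ])
    }),
    diagnostics = list(
      voltage = as.list(report$diagnostics$voltage),
      voltage_roc = roc_entry(report$diagnostics$voltage_roc),
      sqrs = if (!is.null(report$diagnostics$sqrs)) {
        as.list(report$diagnostics$sqrs)
      },
      sqrs_roc = roc_entry(report$diagnostics$sqrs_roc)
    ),
    sqrs_summary = if (!is.null(report$sqrs)) as.list(report$sqrs$summary),
    settings = report$config[setdiff(names(report$config),
                                     c("inputs", "phantom", "out_dir"))]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
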