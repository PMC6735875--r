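#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   labs theme_minimal facet_wrap scale_colour_viridis_c coord_equal
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `roc_curve` from [roc_from_scores()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(linewidth = 0.8) +
    coord_equal() +
    labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC for LGE scar detection (AUC = %.3f)", object$auc)
    ) +
    theme_minimal()
}

#' Plot Dice concordance across voltage thresholds
#'
#' @param object A `dice_sweep` tibble from [dice_threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot of total, scar and normal-myocardium DSC against the
#'   voltage cut-off.
#' @method autoplot dice_sweep
#' @export
autoplot.dice_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("threshold_mV", "dsc_total", "dsc_scar", "dsc_normal")],
    cols = dplyr::starts_with("dsc_"),
    names_to = "region", names_prefix = "dsc_", values_to = "dsc"
  )
  ggplot(long, aes(x = .data$threshold_mV, y = .data$dsc,
                   colour = .data$region)) +
    geom_line() +
    geom_point() +
    labs(x = "Voltage threshold (mV)", y = "Dice similarity coefficient",
         colour = "Region",
         title = "Nodal Dice concordance vs voltage threshold") +
    theme_minimal()
}

#' Scatter plot of a per-vertex map on the mesh
#'
#' Quick-look projection of a nodal scalar map (e.g. interpolated voltage):
#' vertices are drawn in two axis-aligned views coloured by value. Not a
#' 3D renderer; intended for sanity checks and vignettes.
#'
#' @param mesh A [surface_mesh()].
#' @param map A [node_map()] or numeric per-vertex vector.
#' @param name Legend title.
#' @return A ggplot.
#' @export
plot_node_map <- function(mesh, map, name = "value") {
  vals <- if (is.data.frame(map)) map$value else as.numeric(map)
  assert_that(length(vals) == n_vertices(mesh),
              "map length must equal vertex count")
  v <- mesh$vertices
  df <- dplyr::bind_rows(
    tibble::tibble(u = v[, 1], w = v[, 3], value = vals, view = "x-z"),
    tibble::tibble(u = v[, 2], w = v[, 3], value = vals, view = "y-z")
  )
  ggplot(df, aes(x = .data$u, y = .data$w, colour = .data$value)) +
    geom_point(size = 0.8) +
    facet_wrap(~view) +
    scale_colour_viridis_c(name = name) +
    coord_equal() +
    labs(x = "mm", y = "mm") +
    theme_minimal()
}
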