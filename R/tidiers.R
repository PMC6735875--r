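#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods
#'
#' `tidy()` returns the per-observation table of a result object (ROC
#' operating points, per-site S-QRS categories); `glance()` returns a
#' one-row summary (AUC, category percentages).
#'
#' @param x A `roc_curve` or `sqrs_classification` object.
#' @param ... Unused.
#' @return A tibble.
#' @name scarconcord-tidiers
NULL

#' @rdname scarconcord-tidiers
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$curve

#' @rdname scarconcord-tidiers
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
                 orientation = x$orientation)
}

#' @rdname scarconcord-tidiers
#' @method tidy sqrs_classification
#' @export
tidy.sqrs_classification <- function(x, ...) tibble::as_tibble(x$sites)

#' @rdname scarconcord-tidiers
#' @method glance sqrs_classification
#' @export
glance.sqrs_classification <- function(x, ...) x$summary
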