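#' Confusion counts against the LGE gold standard
#'
#' Cross-tabulates a binary test (low voltage or slow conduction) against
#' the LGE-derived scar truth. Positive means truth 1 (scar);
#' test-positive means label 1.
#'
#' @param test Integer 0/1 test labels (per vertex or per site).
#' @param truth Integer 0/1 gold-standard labels, same length.
#' @return A one-row tibble of class `confusion_counts` with columns
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_counts(c(1, 0, 1, 0), c(1, 0, 0, 0))
confusion_counts <- function(test, truth) {
  test <- as.integer(test)
  truth <- as.integer(truth)
  assert_that(length(test) == length(truth),
              "test/truth lengths differ (%d vs %d)", length(test), length(truth))
  assert_that(all(test %in% 0:1) && all(truth %in% 0:1),
              "labels must be binary 0/1")
  new_confusion(
    tp = sum(test == 1 & truth == 1), fp = sum(test == 1 & truth == 0),
    tn = sum(test == 0 & truth == 0), fn = sum(test == 0 & truth == 1)
  )
}

new_confusion <- function(tp, fp, tn, fn) {
  assert_that(all(c(tp, fp, tn, fn) >= 0), "counts must be non-negative")
  assert_that(tp + fp + tn + fn > 0, "all counts are zero")
  out <- tibble::tibble(tp = as.numeric(tp), fp = as.numeric(fp),
                        tn = as.numeric(tn), fn = as.numeric(fn))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Sensitivity, specificity and predictive values
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`. A zero denominator leaves that
#' field undefined (`NA`), not 0.
#'
#' @param counts A [confusion_counts()] row (real-valued counts allowed).
#' @return A one-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   plus the input counts.
#' @export
#' @examples
#' diagnostic_summary(reconstruct_confusion(138, 307, 0.57, 0.96))
diagnostic_summary <- function(counts) {
  assert_that(all(c("tp", "fp", "tn", "fn") %in% names(counts)),
              "counts must have tp, fp, tn, fn")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  ))
}

#' Reconstruct expected confusion counts from rates
#'
#' Given the numbers of truly positive and negative units and a
#' sensitivity/specificity pair, returns the implied (real-valued, not
#' rounded) confusion counts. Useful for worked examples: predictive values
#' follow from prevalence and the two rates, e.g.
#' `PPV = sens * pi / (sens * pi + (1 - spec) * (1 - pi))` with prevalence
#' `pi = n_pos / (n_pos + n_neg)`.
#'
#' @param n_pos,n_neg Numbers of gold-standard positive/negative units.
#' @param sens,spec Sensitivity and specificity, each in `[0, 1]`.
#' @return A [confusion_counts()] row (real-valued).
#' @export
reconstruct_confusion <- function(n_pos, n_neg, sens, spec) {
  assert_that(n_pos >= 0 && n_neg >= 0, "n_pos/n_neg must be non-negative")
  assert_that(sens >= 0 && sens <= 1, "sens must be in [0, 1]")
  assert_that(spec >= 0 && spec <= 1, "spec must be in [0, 1]")
  new_confusion(
    tp = sens * n_pos, fn = (1 - sens) * n_pos,
    tn = spec * n_neg, fp = (1 - spec) * n_neg
  )
}

#' ROC curve and AUC from continuous scores
#'
#' Builds the empirical ROC curve over all unique score thresholds, with
#' tied scores grouped at a single operating point, and computes the area
#' under the curve by the trapezoidal rule (equal to the Mann–Whitney
#' concordance probability with ties counted one half). `orientation`
#' declares which direction indicates disease: `"low_positive"` for bipolar
#' voltage (scar is low-voltage), `"high_positive"` for S-QRS delay (scar
#' conducts slowly).
#'
#' @param scores Numeric scores.
#' @param truth Integer 0/1 gold-standard labels (1 = LGE scar).
#' @param orientation `"low_positive"` or `"high_positive"`.
#' @return An object of class `roc_curve`: list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `orientation`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_from_scores(c(0.2, 0.4, 3, 5), c(1, 1, 0, 0), "low_positive")
#' r$auc  # 1: perfectly separated
roc_from_scores <- function(scores, truth,
                            orientation = c("high_positive", "low_positive")) {
  orientation <- match.arg(orientation)
  truth <- as.integer(truth)
  assert_that(length(scores) == length(truth), "scores/truth lengths differ")
  assert_that(all(is.finite(scores)), "scores must be finite")
  assert_that(all(truth %in% 0:1), "truth must be binary 0/1")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  assert_that(n_pos >= 1 && n_neg >= 1,
              "ROC needs at least one positive and one negative")
  s <- if (orientation == "low_positive") -scores else scores
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  t_sorted <- truth[ord]
  grp <- cumsum(!duplicated(s_sorted))
  tp_g <- tapply(t_sorted == 1, grp, sum)
  fp_g <- tapply(t_sorted == 0, grp, sum)
  tpr <- c(0, as.numeric(cumsum(tp_g)) / n_pos)
  fpr <- c(0, as.numeric(cumsum(fp_g)) / n_neg)
  thr <- c(Inf, s_sorted[!duplicated(s_sorted)])
  names(thr) <- NULL
  if (orientation == "low_positive") thr <- -thr
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(
    curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
    auc = auc, orientation = orientation, n_pos = n_pos, n_neg = n_neg
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.3f (%s), %d positives / %d negatives>\n",
              x$auc, x$orientation, x$n_pos, x$n_neg))
  invisible(x)
}
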