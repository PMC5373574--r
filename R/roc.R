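#' ROC curve of layer thickness against absolute-scotoma status
#'
#' Builds the ROC curve for the rule "thickness <= t predicts an absolute
#' scotoma" (the positive class). Thresholds are placed at the midpoints of
#' consecutive sorted unique values, plus -Inf and +Inf, so every achievable
#' confusion table is represented. The area under the curve is computed by
#' the trapezoid rule, which for this construction equals the
#' rank-statistic (Mann-Whitney) formulation with ties counted 1/2.
#'
#' @param values Numeric vector of per-point layer thicknesses (um).
#' @param labels Logical (or 0/1) vector: `TRUE` = absolute scotoma.
#' @return An object of class `pp_roc`: list with `thresholds` (ascending),
#'   `sensitivity`, `specificity`, `auc`, `youden_j`, `youden_cutoff`
#'   (um), and `capture_rate` (fraction of scotoma points strictly below
#'   the cutoff).
#' @export
#' @examples
#' r <- roc_curve(c(10, 12, 30, 35), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc  # 1
roc_curve <- function(values, labels) {
  labels <- as.logical(labels)
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must be finite")
  if (anyNA(labels)) stop("labels must be TRUE/FALSE")
  if (length(values) != length(labels)) stop("length mismatch")
  if (!any(labels) || all(labels))
    stop("both classes (scotoma and non-scotoma) must be present")
  u <- sort(unique(values))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  vpos <- sort(values[labels]); vneg <- sort(values[!labels])
  sens <- findInterval(thr, vpos) / length(vpos)   # P(value <= t | scotoma)
  spec <- 1 - findInterval(thr, vneg) / length(vneg)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which.max(j)   # first maximum = lowest threshold on ties
  cutoff <- thr[best]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_j = j[best], youden_cutoff = cutoff,
                 capture_rate = mean(values[labels] < cutoff),
                 n_pos = length(vpos), n_neg = length(vneg)),
            class = "pp_roc")
}

#' @export
print.pp_roc <- function(x, ...) {
  cat(sprintf("ROC (%d scotoma / %d non-scotoma points): AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  cat(sprintf("  Youden cutoff = %.2f um (J = %.3f), capture rate %.1f%%\n",
              x$youden_cutoff, x$youden_j, 100 * x$capture_rate))
  invisible(x)
}

#' @export
plot.pp_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1;
#' ties are broken toward the lower threshold. Shifting all input values by
#' a constant shifts the cutoff by the same constant.
#'
#' @param roc A `pp_roc` object.
#' @return The cutoff in the units of the ROC values (um).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "pp_roc"))
  roc$youden_cutoff
}

#' Fraction of scotoma points captured below a cutoff
#'
#' @param values Per-point thicknesses (um).
#' @param labels Scotoma indicators.
#' @param cutoff Finite thickness cutoff (um).
#' @return Fraction of scotoma-labelled points with `value < cutoff`.
#'   Errors when no scotoma points are present (the rate is undefined).
#' @export
capture_rate <- function(values, labels, cutoff) {
  labels <- as.logical(labels)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (!any(labels)) stop("no scotoma points: capture rate undefined")
  mean(values[labels] < cutoff)
}

#' Pooled per-point scotoma ROC for a cohort
#'
#' Pools the (layer cell thickness, 0-dB indicator) pairs of all analysis
#' eyes of one group and runs [roc_curve()]. This is the cohort-level
#' analysis from which the ganglion-cell-layer scotoma cutoff is derived.
#'
#' @param cohort A `pp_cohort`.
#' @param layer Layer whose cell thickness classifies scotomas (default
#'   `"GCL"`).
#' @param group Group to pool (default `"ADOA"`).
#' @param eyes `"analysis"` (default) or `"both"`.
#' @return A `pp_roc` object.
#' @export
scotoma_roc <- function(cohort, layer = "GCL", group = "ADOA",
                        eyes = c("analysis", "both")) {
  eyes <- match.arg(eyes)
  li <- match(layer, dimnames(cohort$thickness)[[2]])
  if (is.na(li)) stop("unknown layer: ", layer)
  idx <- which(cohort$eyes$group == group &
                 (eyes == "both" | cohort$eyes$is_analysis))
  th <- cohort$thickness[idx, li, , drop = FALSE]
  dim(th) <- c(length(idx), dim(cohort$thickness)[3])
  lab <- cohort$sensitivity[idx, , drop = FALSE] == 0
  roc_curve(as.vector(th), as.vector(lab))
}

#' Per-patient summary of cutoff capture
#'
#' Cohort-level capture summaries in both units: `"points"` gives the
#' pooled fraction of scotoma points with layer thickness below the cutoff;
#' `"patients"` gives, among patients with at least one absolute scotoma,
#' the fraction in whom at least one scotoma point falls below the cutoff.
#' Published reports mix the two units, so both are exposed.
#'
#' @param cohort A `pp_cohort`.
#' @param cutoff Thickness cutoff (um).
#' @param layer Classifying layer (default `"GCL"`).
#' @param unit `"points"` or `"patients"`.
#' @param group Group (default `"ADOA"`).
#' @return The capture fraction.
#' @export
cohort_capture_rate <- function(cohort, cutoff, layer = "GCL",
                                unit = c("points", "patients"),
                                group = "ADOA") {
  unit <- match.arg(unit)
  li <- match(layer, dimnames(cohort$thickness)[[2]])
  if (is.na(li)) stop("unknown layer: ", layer)
  idx <- which(cohort$eyes$group == group & cohort$eyes$is_analysis)
  th <- cohort$thickness[idx, li, , drop = FALSE]
  dim(th) <- c(length(idx), dim(cohort$thickness)[3])
  lab <- cohort$sensitivity[idx, , drop = FALSE] == 0
  if (unit == "points") return(capture_rate(as.vector(th), as.vector(lab), cutoff))
  has_scot <- rowSums(lab) > 0
  if (!any(has_scot)) stop("no patients with scotomas: rate undefined")
  captured <- vapply(which(has_scot), function(i)
    any(th[i, lab[i, ]] < cutoff), logical(1))
  mean(captured)
}

#' Write a ROC table to CSV
#'
#' @param roc A `pp_roc`.
#' @param file Path to a CSV file.
#' @return The file path, invisibly.
#' @export
write_roc_csv <- function(roc, file) {
  utils::write.csv(
    data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
               specificity = roc$specificity,
               J = roc$sensitivity + roc$specificity - 1),
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
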