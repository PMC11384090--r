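# Quantification statistics, segmentation-evaluation metrics, agreement and
# group comparisons. The SD convention is the sample standard deviation
# (n - 1 denominator) throughout, so volumetric and map-based inhomogeneity
# measures are directly comparable.

.pdffStats <- function(v, source) {
  structure(list(mean = mean(v), min = min(v), max = max(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 n = length(v), source = source),
            class = "PDFFStats")
}

#' @export
print.PDFFStats <- function(x, ...) {
  cat(sprintf("PDFF stats (%s, n = %d): mean %.2f, min %.2f, max %.2f, SD %.2f %%\n",
              x$source, x$n, x$mean, x$min, x$max, x$sd))
  invisible(x)
}

#' Volumetric PDFF statistics of a vertebra
#'
#' Mean, minimum, maximum and sample SD of the PDFF over all masked voxels of
#' the segmented vertebral body; the SD serves as a measure of bone-marrow
#' inhomogeneity.
#'
#' @param roi A [VertebraROI].
#' @return A `PDFFStats` list with `mean`, `min`, `max`, `sd`, `n` and
#'   `source = "volumetric"`.
#' @export
volumetricStats <- function(roi) {
  stopifnot(is(roi, "VertebraROI"))
  if (!any(roi@mask)) stop("empty mask")
  .pdffStats(roi@scalar[roi@mask], "volumetric")
}

#' Map-based PDFF statistics
#'
#' Statistics over the valid pixels of the standardized distribution maps:
#' pooled over all three planes plus per-plane variants.
#'
#' @param maps A [StandardizedMaps].
#' @return List with `pooled` (a `PDFFStats` with
#'   `source = "maps_pooled"`) and `perPlane` (named list of `PDFFStats`).
#' @export
mapStats <- function(maps) {
  stopifnot(is(maps, "StandardizedMaps"))
  planes <- c("transverse", "sagittal", "coronal")
  vals <- lapply(planes, function(p) {
    m <- slot(maps, p)
    m[is.finite(m)]
  })
  names(vals) <- planes
  if (!length(unlist(vals))) stop("maps contain no valid pixels")
  list(pooled = .pdffStats(unlist(vals, use.names = FALSE), "maps_pooled"),
       perPlane = lapply(planes, function(p)
         .pdffStats(vals[[p]], paste0("map_", p))) |>
         stats::setNames(planes))
}

#' Class-wise confusion-matrix metrics for a segmentation
#'
#' Voxel-wise comparison of a predicted against a ground-truth mask:
#' accuracy, Dice similarity coefficient, Jaccard index, precision, recall,
#' true negative rate, negative predictive value, the false discovery /
#' negative / omission / positive rates, and the absolute and relative
#' volumetric errors.
#'
#' @param pred Logical array, predicted mask.
#' @param truth Logical array of identical shape, ground truth.
#' @param voxelVolumeMl Volume of one voxel in ml.
#' @return A `ConfusionMetrics` list. `relVolErrorPercent` is relative to the
#'   ground-truth volume and `NA` (flagged) when the truth is empty.
#' @export
confusionMetrics <- function(pred, truth, voxelVolumeMl) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- length(pred) - tp - fp - fn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  absErr <- abs(sum(pred) - sum(truth)) * voxelVolumeMl
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / length(pred),
    dsc = div(2 * tp, 2 * tp + fp + fn),
    jaccard = div(tp, tp + fp + fn),
    precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    tnr = div(tn, tn + fp),
    npv = div(tn, tn + fn),
    fdr = div(fp, tp + fp),
    fnr = div(fn, tp + fn),
    fpr = div(fp, tn + fp),
    forate = div(fn, tn + fn),
    absVolErrorMl = absErr,
    relVolErrorPercent = if (sum(truth) == 0) NA_real_ else
      100 * absErr / (sum(truth) * voxelVolumeMl)
  ), class = "ConfusionMetrics")
}

#' @export
print.ConfusionMetrics <- function(x, ...) {
  cat(sprintf("Confusion metrics: DSC %.3f, Jaccard %.3f, precision %.3f, recall %.3f\n",
              x$dsc, x$jaccard, x$precision, x$recall))
  cat(sprintf("  volumetric error %.2f ml (%.1f %%)\n",
              x$absVolErrorMl, x$relVolErrorPercent))
  invisible(x)
}

#' Bland--Altman agreement analysis
#'
#' Differences are taken as `b - a`; with `a` the volumetric and `b` the
#' map-derived values this matches the convention in which a negative bias
#' means the standardized maps underestimate the volumetric assessment.
#'
#' @param a Numeric vector, first method (reference, e.g. volumetric).
#' @param b Numeric vector of equal length, second method (e.g. maps).
#' @return A `BlandAltmanResult` list with `bias`, `sdDiff`, `loaLow`,
#'   `loaHigh` (bias -/+ 1.96 SD) and `nPairs`.
#' @export
blandAltman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- b - a
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sdDiff = sdd,
                 loaLow = bias - 1.96 * sdd, loaHigh = bias + 1.96 * sdd,
                 nPairs = length(d)),
            class = "BlandAltmanResult")
}

#' @export
print.BlandAltmanResult <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f]\n",
              x$nPairs, x$bias, x$loaLow, x$loaHigh))
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Applies Shapiro--Wilk to both samples; if both are compatible with
#' normality at level `alpha`, Welch's t-test is used, otherwise the
#' two-sided Mann--Whitney U test. Constant samples, for which normality is
#' undefined, fall back to Mann--Whitney.
#'
#' @param a,b Numeric samples, each of size >= 3.
#' @param alpha Significance level (default 0.05).
#' @return A `GroupTestResult` list with `testName`
#'   (`"welch_t"` or `"mann_whitney_u"`), `statistic`, `pValue`,
#'   `normalityP` (length 2) and `significant`.
#' @export
compareGroups <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  shap <- function(x) {
    if (stats::sd(x) == 0 || length(x) < 3L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  pa <- shap(a); pb <- shap(b)
  useWelch <- !is.na(pa) && !is.na(pb) && pa >= alpha && pb >= alpha
  if (useWelch) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(testName = "welch_t", statistic = unname(tt$statistic),
                pValue = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    res <- list(testName = "mann_whitney_u", statistic = unname(wt$statistic),
                pValue = wt$p.value)
  }
  res$normalityP <- c(pa, pb)
  res$alpha <- alpha
  res$significant <- res$pValue < alpha
  structure(res, class = "GroupTestResult")
}

#' @export
print.GroupTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic %.3f, p = %.4g (%ssignificant at %.2f)\n",
              x$testName, x$statistic, x$pValue,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
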