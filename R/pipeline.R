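# Subject- and cohort-level orchestration of the full workflow:
# segmentation masks -> per-vertebra ROI -> inclination estimate (and
# optional correction) -> standardized maps -> volumetric and map statistics.

.statsRow <- function(subject, vertebra, st, corrected, angle) {
  data.frame(subject = subject, vertebra = vertebra, source = st$source,
             corrected = corrected, mean = st$mean, min = st$min,
             max = st$max, sd = st$sd, n = st$n,
             inclination_deg = angle, stringsAsFactors = FALSE)
}

#' Run the standardized-mapping workflow for one subject
#'
#' For every vertebra present in the label volume: crop the ROI, estimate the
#' inclination from the mid-sagittal inferior edge, build standardized maps
#' both without and (when `correctInclination`) with inclination correction,
#' and compute volumetric as well as pooled and per-plane map statistics.
#' Both the corrected and uncorrected map statistics are always part of one
#' run, so the influence of the correction is a first-class result rather
#' than a re-run.
#'
#' @param scalar A [ScalarVolume3D] (or path to a NIfTI file).
#' @param labels A [LabelVolume3D] (or path; then `labelMapSpec` applies).
#' @param truth Optional ground-truth [LabelVolume3D] (or path) for
#'   segmentation evaluation.
#' @param subjectId Identifier used in output tables.
#' @param geom A [TemplateGeometry].
#' @param correctInclination Also compute inclination-corrected maps?
#' @param houghArgs Arguments passed to [estimateInclination()].
#' @param marginVoxels ROI crop margin.
#' @param labelMapSpec Label naming convention for paths.
#' @param outDir If non-NULL, write `stats.csv`, `metrics.csv` (when `truth`
#'   is given), `manifest.json` and per-vertebra map PNGs there.
#' @return List with `stats` (data frame), `maps` (nested list:
#'   vertebra -> uncorrected/corrected [StandardizedMaps]), `inclination`
#'   (data frame of estimates), `metrics` (data frame or NULL) and
#'   `manifest`.
#' @export
runSubject <- function(scalar, labels, truth = NULL, subjectId = "subject",
                       geom = templateGeometry(), correctInclination = TRUE,
                       houghArgs = list(), marginVoxels = 2L,
                       labelMapSpec = defaultLabelMap(), outDir = NULL) {
  if (is.character(scalar)) scalar <- readScalarVolume(scalar)
  if (is.character(labels)) labels <- readLabelVolume(labels, labelMapSpec)
  if (is.character(truth)) truth <- readLabelVolume(truth, labelMapSpec)
  stopifnot(is(scalar, "ScalarVolume3D"), is(labels, "LabelVolume3D"))

  present <- presentLabels(labels)
  if (!length(present)) stop("label volume contains no vertebrae")
  statsDf <- NULL
  inclDf <- NULL
  metricsDf <- NULL
  mapsList <- list()
  voxMl <- prod(scalar@spacing) / 1000

  for (lb in present) {
    roi <- extractVertebraROI(scalar, labels, lb, marginVoxels)
    vname <- roi@labelName
    est <- do.call(estimateInclination,
                   c(list(detectInferiorEdge(roi)), houghArgs))
    inclDf <- rbind(inclDf, data.frame(
      subject = subjectId, vertebra = vname, angle_deg = est$angleDeg,
      hough_votes = est$houghVotes, n_edge_points = est$nEdgePoints,
      valid = est$valid, stringsAsFactors = FALSE))

    vs <- volumetricStats(roi)
    statsDf <- rbind(statsDf, .statsRow(subjectId, vname, vs, FALSE, est$angleDeg))

    mapsU <- buildStandardizedMaps(roi, geom, correctInclination = FALSE)
    msU <- mapStats(mapsU)
    statsDf <- rbind(statsDf,
                     .statsRow(subjectId, vname, msU$pooled, FALSE, est$angleDeg))
    for (pl in names(msU$perPlane))
      statsDf <- rbind(statsDf, .statsRow(subjectId, vname,
                                          msU$perPlane[[pl]], FALSE,
                                          est$angleDeg))
    vmaps <- list(uncorrected = mapsU)

    if (correctInclination) {
      roiC <- if (est$valid && est$angleDeg != 0)
        rotateVertebra(roi, est$angleDeg) else roi
      mapsC <- buildStandardizedMaps(roiC, geom, correctInclination = FALSE)
      mapsC@inclinationCorrected <- TRUE
      mapsC@angleDeg <- if (est$valid) est$angleDeg else 0
      msC <- mapStats(mapsC)
      statsDf <- rbind(statsDf,
                       .statsRow(subjectId, vname, msC$pooled, TRUE, est$angleDeg))
      for (pl in names(msC$perPlane))
        statsDf <- rbind(statsDf, .statsRow(subjectId, vname,
                                            msC$perPlane[[pl]], TRUE,
                                            est$angleDeg))
      vmaps$corrected <- mapsC
    }
    mapsList[[vname]] <- vmaps

    if (!is.null(truth)) {
      cm <- confusionMetrics(labels@data == lb, truth@data == lb, voxMl)
      metricsDf <- rbind(metricsDf, cbind(
        data.frame(subject = subjectId, vertebra = vname,
                   stringsAsFactors = FALSE),
        as.data.frame(unclass(cm))))
    }
  }

  manifest <- list(subject = subjectId,
                   vertebrae = as.list(statsDf$vertebra[!duplicated(statsDf$vertebra)]),
                   template = list(nMajor = geom@nMajor, nMinor = geom@nMinor,
                                   nLong = geom@nLong),
                   spacing_mm = as.list(scalar@spacing),
                   inclination = split(inclDf$angle_deg, inclDf$vertebra),
                   package_version = as.character(utils::packageVersion("vertemap")))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(statsDf, file.path(outDir, "stats.csv"), row.names = FALSE)
    if (!is.null(metricsDf))
      utils::write.csv(metricsDf, file.path(outDir, "metrics.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (vname in names(mapsList))
      for (variant in names(mapsList[[vname]]))
        writeMapsPNG(mapsList[[vname]][[variant]],
                     file.path(outDir, paste(subjectId, vname, variant, sep = "_")))
  }

  list(stats = statsDf, maps = mapsList, inclination = inclDf,
       metrics = metricsDf, manifest = manifest)
}

#' Run the workflow over a cohort and summarize by group
#'
#' Runs [runSubject()] for every subject, then reports per-group,
#' per-vertebra mean and SD of each statistic, pairwise group comparisons via
#' [compareGroups()] and the Bland--Altman agreement between map-derived and
#' volumetric mean PDFF across all vertebrae.
#'
#' @param subjects List; each element either the output of
#'   [generatePhantom()] or a list with elements `scalar` and `labels`
#'   (optionally `truth`).
#' @param groups Vector of group labels, one per subject.
#' @param statistic Which map statistics enter the group summary:
#'   `"maps_pooled"` (default) or `"volumetric"`.
#' @param corrected Use inclination-corrected map statistics in the summary?
#' @param alpha Significance level for group comparisons.
#' @param ... Passed on to [runSubject()].
#' @return List with `perSubject` (combined stats data frame), `summary`
#'   (group x vertebra x statistic mean/SD, vertebrae ordered L5 to L1),
#'   `comparisons` (pairwise group tests; groups with < 3 subjects are
#'   skipped with a warning) and `agreement` (a `BlandAltmanResult`).
#' @export
runCohort <- function(subjects, groups, statistic = "maps_pooled",
                      corrected = FALSE, alpha = 0.05, ...) {
  stopifnot(length(subjects) >= 1L, length(groups) == length(subjects))
  results <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    runSubject(s$scalar, s$labels, truth = s$truth,
               subjectId = sprintf("S%03d", i), ...)
  })
  allStats <- do.call(rbind, lapply(seq_along(results), function(i) {
    df <- results[[i]]$stats
    df$group <- groups[i]
    df
  }))

  sel <- allStats[allStats$source == statistic &
                    allStats$corrected == corrected, ]
  vertOrder <- rev(sort(unique(sel$vertebra)))     # L5 ... L1
  measures <- c("min", "max", "sd", "mean")
  summary <- do.call(rbind, lapply(unique(groups), function(g) {
    do.call(rbind, lapply(measures, function(m) {
      do.call(rbind, lapply(vertOrder, function(v) {
        x <- sel[sel$group == g & sel$vertebra == v, m]
        data.frame(group = g, statistic = m, vertebra = v,
                   mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
                   n = length(x), stringsAsFactors = FALSE)
      }))
    }))
  }))

  grp <- unique(groups)
  comparisons <- NULL
  if (length(grp) >= 2L) {
    pairs <- utils::combn(grp, 2, simplify = FALSE)
    for (pr in pairs) {
      nA <- sum(groups == pr[1]); nB <- sum(groups == pr[2])
      if (nA < 3L || nB < 3L) {
        warning("skipping comparison ", pr[1], " vs ", pr[2],
                ": a group has fewer than 3 subjects")
        next
      }
      for (v in vertOrder) for (m in measures) {
        xa <- sel[sel$group == pr[1] & sel$vertebra == v, m]
        xb <- sel[sel$group == pr[2] & sel$vertebra == v, m]
        gt <- compareGroups(xa, xb, alpha)
        comparisons <- rbind(comparisons, data.frame(
          group_a = pr[1], group_b = pr[2], vertebra = v, statistic = m,
          test = gt$testName, p_value = gt$pValue,
          significant = gt$significant, stringsAsFactors = FALSE))
      }
    }
  }

  vol <- allStats[allStats$source == "volumetric", ]
  mp <- allStats[allStats$source == "maps_pooled" &
                   allStats$corrected == corrected, ]
  key <- paste(vol$subject, vol$vertebra)
  keyM <- paste(mp$subject, mp$vertebra)
  common <- intersect(key, keyM)
  agreement <- blandAltman(vol$mean[match(common, key)],
                           mp$mean[match(common, keyM)])

  list(perSubject = allStats, summary = summary, comparisons = comparisons,
       agreement = agreement)
}
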