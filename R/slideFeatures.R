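## Per-slide feature engineering: the ~60-column slide feature vector
## combining LTS burden, stain statistics within detected patches, affinity-
## propagation cluster descriptors and validity indices, graph_v1 degree
## features over several neighbourhood graphs, and point-pattern homogeneity
## statistics.

#' Ground-truth patch grid from annotations
#'
#' Marks every 40 x 40 cell containing the centroid of a foreground LTS
#' object positive. This is the oracle detector used for cohort-scale
#' feature runs where per-slide CNN inference is replaced by exact ground
#' truth, and for inference-geometry tests.
#'
#' @param annotations an [AnnotationSet-class].
#' @param cellSize cell edge in pixels, default 40.
#' @return A [PatchGrid-class].
#' @export
annotationPatchGrid <- function(annotations, cellSize = 40L) {
  ctr <- centroids(annotations, class = "foreground")
  cells <- unique(cbind(pmin(floor(ctr[, 1] / cellSize),
                             ceiling(annotations@height / cellSize) - 1L),
                        pmin(floor(ctr[, 2] / cellSize),
                             ceiling(annotations@width / cellSize) - 1L)))
  PatchGrid(cells, slideHeight = annotations@height,
            slideWidth = annotations@width, cellSize = cellSize)
}

.GRAPH_RULES <- list(gr120 = list(rule = "radius", parameter = 120),
                     gr240 = list(rule = "radius", parameter = 240),
                     gk3 = list(rule = "knn", parameter = 3),
                     gk6 = list(rule = "knn", parameter = 6))

#' Names of the slide feature vector
#'
#' @return character vector of the feature columns produced by
#'   [slideFeatures()], in order.
#' @export
slideFeatureNames <- function() {
  c("nLtsPatches", "ltsPatchFraction", "ltsPixelFraction",
    "h_sum", "h_mean", "h_median", "h_sd",
    "dab_sum", "dab_mean", "dab_median", "dab_sd",
    "K", "clusterSizeMean", "clusterSizeSd", "dispersionMean",
    "dispersionSd", "extentMean", "extentSd", "bgss",
    "ballHall", "banfeldRaftery", "logSSRatio", "daviesBouldin",
    "calinskiHarabasz", "cIndex",
    as.vector(t(outer(names(.GRAPH_RULES),
                      c("degMean", "degSd", "degMax", "fracIsolated",
                        "degEntropy", "assortativity", "localClustering"),
                      paste, sep = "_"))),
    "nnMean", "nnSd", "clarkEvans", "quadratDispersion")
}

#' Engineer the feature vector of one slide
#'
#' Combines, for a slide with detector output `grid`:
#' \itemize{
#'   \item burden: number of positive 40 x 40 patches, their fraction among
#'     tissue-covered cells, and the positive-cell pixel area over the
#'     tissue pixel area;
#'   \item stain: sum/mean/median/SD of the hematoxylin and DAB channels
#'     pooled over positive cells (requires `channels`; `NA` otherwise);
#'   \item clustering: [clusterDescriptors()] and [validityIndices()] of the
#'     affinity-propagation clustering of positive-cell centers;
#'   \item graph_v1: [degreeFeatures()] over radius-120, radius-240, 3-nn
#'     and 6-nn graphs on the same centers;
#'   \item homogeneity: [homogeneityFeatures()] in the slide window.
#' }
#' Features whose preconditions fail on sparse slides (e.g. validity indices
#' with fewer than 2 points) are `NA` and are handled downstream by
#' [completeFeatureMatrix()].
#'
#' @param grid a [PatchGrid-class] of detector-positive cells.
#' @param channels optional [StainChannels-class] aligned to the slide.
#' @param tissue optional logical tissue mask (pixel resolution) used for
#'   the fraction denominators; defaults to the whole slide.
#' @param apSeed seed for the clustering jitter.
#' @return named numeric vector, names as in [slideFeatureNames()].
#' @export
slideFeatures <- function(grid, channels = NULL, tissue = NULL, apSeed = 1L) {
  stopIfNot(is(grid, "PatchGrid"), "'grid' must be a PatchGrid")
  cs <- grid@cellSize
  nPos <- sum(grid@positive)
  ncells <- length(grid@positive)
  if (!is.null(tissue)) {
    tissuePx <- sum(tissue)
    ## tissue-covered cells: cells containing at least one tissue pixel
    ri <- ceiling(seq_len(nrow(tissue)) / cs)
    ci <- ceiling(seq_len(ncol(tissue)) / cs)
    cellTissue <- rowsum(t(rowsum(tissue + 0, ri)), ci)
    nTissueCells <- sum(cellTissue > 0)
  } else {
    tissuePx <- as.numeric(grid@slideHeight) * grid@slideWidth
    nTissueCells <- ncells
  }
  burden <- c(nLtsPatches = nPos,
              ltsPatchFraction = if (nTissueCells > 0)
                nPos / nTissueCells else NA_real_,
              ltsPixelFraction = if (tissuePx > 0)
                nPos * cs^2 / tissuePx else NA_real_)
  stain <- if (!is.null(channels)) stainStatistics(channels, grid) else {
    out <- rep(NA_real_, 8L)
    names(out) <- c("h_sum", "h_mean", "h_median", "h_sd",
                    "dab_sum", "dab_mean", "dab_median", "dab_sd")
    out
  }
  pts <- cellCenters(grid)
  cl <- affinityPropagation(pts, seed = apSeed)
  desc <- clusterDescriptors(cl, pts)
  vi <- if (nrow(pts) >= 2L) validityIndices(cl, pts) else {
    out <- rep(NA_real_, 6L)
    names(out) <- c("ballHall", "banfeldRaftery", "logSSRatio",
                    "daviesBouldin", "calinskiHarabasz", "cIndex")
    out
  }
  gfeat <- unlist(lapply(names(.GRAPH_RULES), function(nm) {
    r <- .GRAPH_RULES[[nm]]
    g <- if (r$rule == "knn" && nrow(pts) <= r$parameter)
      buildObjectGraph(pts, "knn",
                       parameter = max(1L, nrow(pts) - 1L))
    else buildObjectGraph(pts, r$rule, r$parameter)
    f <- degreeFeatures(g)
    names(f) <- paste(nm, names(f), sep = "_")
    f
  }))
  hom <- homogeneityFeatures(pts, width = grid@slideWidth,
                             height = grid@slideHeight)
  out <- c(burden, stain, desc, vi, gfeat, hom)
  out[slideFeatureNames()]
}

#' Feature table for a synthetic cohort
#'
#' Runs the feature engineering over every slide of a [generateCohort()]
#' result. With `stain = FALSE` (the default) the detector grid comes from
#' the ground-truth annotations via [annotationPatchGrid()] and the eight
#' stain columns stay `NA`; with `stain = TRUE` each slide is additionally
#' rendered, deconvolved and pooled (slower, same grids).
#'
#' @param cohort result of [generateCohort()].
#' @param stain render slides and compute stain statistics.
#' @param model [StainModel-class] for rendering/deconvolution.
#' @param verbose print progress every 100 slides.
#' @return data.frame: `slideId`, `subjectId`, `stage`, then one column per
#'   [slideFeatureNames()] entry.
#' @export
cohortFeatureTable <- function(cohort, stain = FALSE,
                               model = hdabStainModel(), verbose = FALSE) {
  stopIfNot(!is.null(cohort$annotations),
            "cohort must carry annotations (generateCohort(annotations = TRUE))")
  n <- length(cohort$annotations)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ann <- cohort$annotations[[i]]
    grid <- annotationPatchGrid(ann)
    channels <- NULL; tis <- NULL
    if (stain) {
      sl <- generateSlide(cohort$slideSpecs[[i]], model = model)
      od <- odTransform(sl@image, model@background)
      channels <- deconvolveStains(od, model)
      tis <- sl@tissue
    }
    rows[[i]] <- c(slideFeatures(grid, channels = channels, tissue = tis,
                                 apSeed = cohort$slides$seed[i] %% 100000L))
    if (verbose && i %% 100L == 0L) message("featurized ", i, "/", n)
  }
  feat <- do.call(rbind, rows)
  out <- cbind(cohort$slides[, c("slideId", "subjectId", "stage")],
               as.data.frame(feat))
  rownames(out) <- NULL
  out
}
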