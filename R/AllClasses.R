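#' @import methods
NULL

## ---------------------------------------------------------------------------
## StainModel
## ---------------------------------------------------------------------------

#' Stain model for H-DAB colour deconvolution
#'
#' Holds the optical-density (OD) unit vectors of the hematoxylin counterstain
#' and the DAB chromogen, the derived residual basis vector (normalised cross
#' product), and the per-channel background intensity I0 of the brightfield
#' scanner.
#'
#' @slot hematoxylin unit 3-vector, OD direction of hematoxylin (blue).
#' @slot dab unit 3-vector, OD direction of DAB (brown).
#' @slot residual unit 3-vector orthogonal to both stains.
#' @slot background numeric 3-vector, background (white) intensity per RGB
#'   channel, conventionally 255.
#'
#' @seealso [hdabStainModel()], [deconvolveStains()]
#' @export
setClass("StainModel",
  representation(hematoxylin = "numeric", dab = "numeric",
                 residual = "numeric", background = "numeric"))

setValidity("StainModel", function(object) {
  msg <- character()
  for (s in c("hematoxylin", "dab", "residual", "background"))
    if (length(slot(object, s)) != 3L)
      msg <- c(msg, sprintf("'%s' must have length 3", s))
  if (!length(msg)) {
    if (abs(sqrt(sum(object@hematoxylin^2)) - 1) > 1e-6)
      msg <- c(msg, "hematoxylin OD vector must have unit norm")
    if (abs(sqrt(sum(object@dab^2)) - 1) > 1e-6)
      msg <- c(msg, "dab OD vector must have unit norm")
    cr <- crossProduct3(object@hematoxylin, object@dab)
    if (sqrt(sum(cr^2)) < 1e-8)
      msg <- c(msg, "stain OD vectors are collinear")
    if (any(object@background <= 0))
      msg <- c(msg, "background intensities must be positive")
  }
  if (length(msg)) msg else TRUE
})

crossProduct3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Standard H-DAB stain model
#'
#' The widely used brightfield H-DAB optical-density triplets,
#' hematoxylin (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778),
#' renormalised to unit length, with the residual direction completed as their
#' normalised cross product.
#'
#' @param hematoxylin,dab numeric 3-vectors in OD space (normalised
#'   internally).
#' @param background per-channel background intensity, default 255.
#' @return A [StainModel-class] object.
#' @examples
#' m <- hdabStainModel()
#' sum(m@hematoxylin^2)  # 1
#' @export
hdabStainModel <- function(hematoxylin = c(0.650, 0.704, 0.286),
                           dab = c(0.269, 0.568, 0.778),
                           background = c(255, 255, 255)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- crossProduct3(h, d)
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8) stop("stain OD vectors are collinear", call. = FALSE)
  new("StainModel", hematoxylin = h, dab = d, residual = r / nr,
      background = rep(background, length.out = 3L))
}

setMethod("show", "StainModel", function(object) {
  cat("StainModel (H-DAB optical-density basis)\n")
  cat("  hematoxylin:", sprintf("%.3f", object@hematoxylin), "\n")
  cat("  dab:        ", sprintf("%.3f", object@dab), "\n")
  cat("  background: ", object@background, "\n")
})

## ---------------------------------------------------------------------------
## AnnotationSet
## ---------------------------------------------------------------------------

#' Annotated objects on one slide
#'
#' Container for the polygonal/point objects annotated on a slide. Each object
#' carries a class (`"foreground"` = LTS, `"background"` = other
#' immunopositive structures/artifacts), a confidence rank for foreground
#' objects (`definite` = 3, `probable` = 2, `possible` = 1) and a provenance
#' source (`"human"` or `"false_positive_replay"`).
#'
#' Geometries are stored as n x 2 matrices of (row, col) pixel coordinates,
#' 0-based, row 0 at the top of the slide.
#'
#' @slot objects data.frame with columns `geometry` (list of n x 2 matrices),
#'   `class` (character), `rank` (integer or NA), `source` (character).
#' @slot height,width slide dimensions in pixels.
#' @export
setClass("AnnotationSet",
  representation(objects = "data.frame", height = "integer",
                 width = "integer"))

.RANKS <- c(possible = 1L, probable = 2L, definite = 3L)
.RANK_WEIGHTS <- c(possible = 3L, probable = 4L, definite = 5L)

setValidity("AnnotationSet", function(object) {
  df <- object@objects
  msg <- character()
  need <- c("geometry", "class", "rank", "source")
  if (!all(need %in% names(df)))
    return(paste("objects must have columns", paste(need, collapse = ", ")))
  if (object@height < 1L || object@width < 1L)
    msg <- c(msg, "slide dimensions must be positive")
  if (nrow(df)) {
    if (!all(df$class %in% c("foreground", "background")))
      msg <- c(msg, "class must be 'foreground' or 'background'")
    fg <- df$class == "foreground"
    if (any(fg & (is.na(df$rank) | !(df$rank %in% 1:3))))
      msg <- c(msg, "foreground objects need a rank in 1..3")
    if (any(!fg & !is.na(df$rank)))
      msg <- c(msg, "background objects must not carry a rank")
    if (!all(df$source %in% c("human", "false_positive_replay")))
      msg <- c(msg, "source must be 'human' or 'false_positive_replay'")
    bounds_ok <- vapply(df$geometry, function(g) {
      is.matrix(g) && ncol(g) == 2L && all(is.finite(g)) &&
        all(g[, 1] >= 0) && all(g[, 1] <= object@height - 1L) &&
        all(g[, 2] >= 0) && all(g[, 2] <= object@width - 1L)
    }, logical(1))
    if (!all(bounds_ok))
      msg <- c(msg, "all geometries must lie within the slide bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationSet
#'
#' @param geometry list of n x 2 (row, col) coordinate matrices, 0-based.
#' @param class character vector, `"foreground"` or `"background"`.
#' @param rank integer vector; 3 = definite, 2 = probable, 1 = possible;
#'   `NA` for background objects. Rank names (`"definite"` etc.) are accepted.
#' @param source `"human"` (default) or `"false_positive_replay"`.
#' @param height,width slide dimensions in pixels.
#' @return An [AnnotationSet-class].
#' @examples
#' a <- AnnotationSet(list(cbind(10, 12)), "foreground", "definite", 100, 100)
#' nObjects(a)
#' @export
AnnotationSet <- function(geometry = list(), class = character(),
                          rank = integer(), height, width,
                          source = "human") {
  if (is.character(rank)) rank <- unname(.RANKS[rank])
  n <- length(geometry)
  df <- data.frame(class = as.character(class),
                   rank = as.integer(rep(rank, length.out = max(n, 0L))[seq_len(n)]),
                   source = rep(as.character(source), length.out = n),
                   stringsAsFactors = FALSE)
  if (n == 0L)
    df <- data.frame(class = character(), rank = integer(),
                     source = character(), stringsAsFactors = FALSE)
  df$geometry <- geometry
  df <- df[, c("geometry", "class", "rank", "source")]
  new("AnnotationSet", objects = df, height = as.integer(height),
      width = as.integer(width))
}

#' @describeIn AnnotationSet number of annotated objects
#' @param x an `AnnotationSet`.
#' @export
nObjects <- function(x) nrow(x@objects)

#' Object centroids
#'
#' Mean (row, col) coordinate of every annotated object, 0-based pixels.
#'
#' @param x an [AnnotationSet-class].
#' @param class optionally restrict to `"foreground"` or `"background"`.
#' @return numeric matrix with columns `row`, `col`.
#' @export
centroids <- function(x, class = NULL) {
  df <- x@objects
  if (!is.null(class)) df <- df[df$class == class, , drop = FALSE]
  if (!nrow(df)) return(matrix(numeric(), 0L, 2L,
                               dimnames = list(NULL, c("row", "col"))))
  out <- t(vapply(df$geometry, colMeans, numeric(2)))
  colnames(out) <- c("row", "col")
  out
}

#' @describeIn AnnotationSet object classes
#' @export
objectClasses <- function(x) x@objects$class

#' @describeIn AnnotationSet confidence ranks (NA for background)
#' @export
objectRanks <- function(x) x@objects$rank

setMethod("show", "AnnotationSet", function(object) {
  df <- object@objects
  cat(sprintf("AnnotationSet: %d objects on a %d x %d slide\n",
              nrow(df), object@height, object@width))
  if (nrow(df)) {
    fg <- df$rank[df$class == "foreground"]
    cat(sprintf("  foreground: %d (definite %d, probable %d, possible %d)\n",
                length(fg), sum(fg == 3L), sum(fg == 2L), sum(fg == 1L)))
    cat(sprintf("  background: %d\n", sum(df$class == "background")))
  }
})

## ---------------------------------------------------------------------------
## RatingTable
## ---------------------------------------------------------------------------

#' Multi-rater categorical rating table
#'
#' Items x raters matrix of categorical calls, the input to [fleissKappa()]
#' and [pairwiseAgreement()].
#'
#' @slot ratings character matrix, rows = items, columns = raters; no missing
#'   cells.
#' @slot categories the category set (superset of observed values).
#' @export
setClass("RatingTable",
  representation(ratings = "matrix", categories = "character"))

setValidity("RatingTable", function(object) {
  r <- object@ratings
  msg <- character()
  if (any(is.na(r))) msg <- c(msg, "rating table must have no missing cells")
  if (nrow(r) < 2L) msg <- c(msg, "need at least 2 items")
  if (ncol(r) < 2L) msg <- c(msg, "need at least 2 raters")
  if (!all(r %in% object@categories))
    msg <- c(msg, "all ratings must belong to the category set")
  if (length(msg)) msg else TRUE
})

#' Construct a RatingTable
#'
#' @param ratings matrix (or data.frame) of categorical ratings, rows = items,
#'   columns = raters.
#' @param categories category set; defaults to the sorted observed values.
#' @return A [RatingTable-class].
#' @export
RatingTable <- function(ratings, categories = NULL) {
  m <- as.matrix(ratings)
  storage.mode(m) <- "character"
  if (is.null(categories)) categories <- sort(unique(as.vector(m)))
  new("RatingTable", ratings = m, categories = as.character(categories))
}

setMethod("show", "RatingTable", function(object) {
  cat(sprintf("RatingTable: %d items x %d raters, %d categories (%s)\n",
              nrow(object@ratings), ncol(object@ratings),
              length(object@categories),
              paste(head(object@categories, 6), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## PatchGrid
## ---------------------------------------------------------------------------

#' Grid of detector-positive 40 x 40 cells
#'
#' Binary occupancy grid over 40 x 40-pixel cells of a slide; a cell is
#' positive when the sliding-window detector assigns a probability above
#' threshold somewhere inside it. Cell (i, j) (0-based) covers the half-open
#' pixel rectangle `[40i, 40i+40) x [40j, 40j+40)`.
#'
#' @slot positive logical matrix, `ceiling(height/cell) x ceiling(width/cell)`.
#' @slot cellSize cell edge in pixels (40).
#' @slot slideHeight,slideWidth slide dimensions in pixels.
#' @export
setClass("PatchGrid",
  representation(positive = "matrix", cellSize = "integer",
                 slideHeight = "integer", slideWidth = "integer"))

setValidity("PatchGrid", function(object) {
  msg <- character()
  if (object@cellSize < 1L) msg <- c(msg, "cellSize must be positive")
  if (!is.logical(object@positive)) msg <- c(msg, "positive must be logical")
  if (nrow(object@positive) != ceiling(object@slideHeight / object@cellSize) ||
      ncol(object@positive) != ceiling(object@slideWidth / object@cellSize))
    msg <- c(msg, "grid dimensions must equal ceiling(slide dims / cellSize)")
  if (length(msg)) msg else TRUE
})

#' Construct a PatchGrid
#'
#' @param positive logical matrix of positive cells, or a 2-column matrix of
#'   0-based positive (row, col) cell indices.
#' @param slideHeight,slideWidth slide dimensions in pixels.
#' @param cellSize cell edge in pixels, default 40.
#' @return A [PatchGrid-class].
#' @export
PatchGrid <- function(positive, slideHeight, slideWidth, cellSize = 40L) {
  cellSize <- as.integer(cellSize)
  nr <- as.integer(ceiling(slideHeight / cellSize))
  nc <- as.integer(ceiling(slideWidth / cellSize))
  if (is.matrix(positive) && !is.logical(positive) && ncol(positive) == 2L) {
    m <- matrix(FALSE, nr, nc)
    if (nrow(positive)) m[cbind(positive[, 1] + 1L, positive[, 2] + 1L)] <- TRUE
    positive <- m
  }
  new("PatchGrid", positive = positive, cellSize = cellSize,
      slideHeight = as.integer(slideHeight), slideWidth = as.integer(slideWidth))
}

#' Positive cell indices of a PatchGrid
#'
#' @param x a [PatchGrid-class].
#' @return integer matrix of 0-based (row, col) cell indices, one row per
#'   positive cell.
#' @export
positiveCells <- function(x) {
  idx <- which(x@positive, arr.ind = TRUE)
  out <- cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Pixel-coordinate centers of positive cells
#'
#' @param x a [PatchGrid-class].
#' @return numeric matrix (row, col) of positive-cell centers in pixels.
#' @export
cellCenters <- function(x) {
  pc <- positiveCells(x)
  out <- cbind(row = pc[, 1] * x@cellSize + x@cellSize / 2,
               col = pc[, 2] * x@cellSize + x@cellSize / 2)
  out
}

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d x %d cells of %d px (%d positive) on %d x %d slide\n",
              nrow(object@positive), ncol(object@positive), object@cellSize,
              sum(object@positive), object@slideHeight, object@slideWidth))
})

## ---------------------------------------------------------------------------
## StainChannels
## ---------------------------------------------------------------------------

#' Deconvolved stain concentration maps
#'
#' @slot hematoxylin,dab,residual per-pixel concentration matrices in OD
#'   units, all of identical dimension.
#' @slot negativeClamped number of pixel-channel entries clamped at zero.
#' @export
setClass("StainChannels",
  representation(hematoxylin = "matrix", dab = "matrix", residual = "matrix",
                 negativeClamped = "integer"))

setValidity("StainChannels", function(object) {
  d <- dim(object@hematoxylin)
  if (!identical(d, dim(object@dab)) || !identical(d, dim(object@residual)))
    "channel maps must share dimensions" else TRUE
})

setMethod("show", "StainChannels", function(object) {
  cat(sprintf("StainChannels: %d x %d px (mean H %.3f, mean DAB %.3f, %d clamped)\n",
              nrow(object@hematoxylin), ncol(object@hematoxylin),
              mean(object@hematoxylin), mean(object@dab),
              object@negativeClamped))
})

## ---------------------------------------------------------------------------
## APClustering
## ---------------------------------------------------------------------------

#' Affinity-propagation clustering result
#'
#' @slot labels integer cluster id (1..K) per point.
#' @slot exemplars indices of the exemplar point of each cluster.
#' @slot K number of clusters.
#' @slot converged whether the exemplar set was stable for
#'   `convergenceIter` iterations.
#' @slot iterations message-passing iterations run.
#' @export
setClass("APClustering",
  representation(labels = "integer", exemplars = "integer", K = "integer",
                 converged = "logical", iterations = "integer"))

setValidity("APClustering", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (n > 0L) {
    if (object@K < 1L) msg <- c(msg, "K must be >= 1 for non-empty input")
    if (length(object@exemplars) != object@K)
      msg <- c(msg, "need one exemplar per cluster")
    if (any(object@labels < 1L | object@labels > object@K))
      msg <- c(msg, "labels must be in 1..K")
    if (length(object@exemplars) &&
        any(object@labels[object@exemplars] != seq_len(object@K)))
      msg <- c(msg, "exemplars must belong to their clusters")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn APClustering cluster label per point
#' @param x an `APClustering`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn APClustering number of clusters
#' @export
nClusters <- function(x) x@K

setMethod("show", "APClustering", function(object) {
  cat(sprintf("APClustering: %d points in %d clusters (%s, %d iterations)\n",
              length(object@labels), object@K,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

## ---------------------------------------------------------------------------
## ObjectGraph
## ---------------------------------------------------------------------------

#' Spatial graph over detected objects
#'
#' Undirected simple graph whose nodes are detected LTS patch centers and
#' whose edges follow a neighbourhood rule (fixed radius, symmetrized
#' k-nearest-neighbour, or Delaunay).
#'
#' @slot points n x 2 matrix of (row, col) coordinates.
#' @slot edges m x 2 integer matrix of node indices, each row i < j.
#' @slot rule `"radius"`, `"knn"` or `"delaunay"`.
#' @slot parameter the radius in pixels or k, as applicable.
#' @export
setClass("ObjectGraph",
  representation(points = "matrix", edges = "matrix", rule = "character",
                 parameter = "numeric"))

setValidity("ObjectGraph", function(object) {
  msg <- character()
  e <- object@edges
  n <- nrow(object@points)
  if (nrow(e)) {
    if (any(e[, 1] >= e[, 2])) msg <- c(msg, "edges must be stored with i < j")
    if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge endpoints out of range")
    if (anyDuplicated(e)) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ObjectGraph number of nodes
#' @param x an `ObjectGraph`.
#' @export
nNodes <- function(x) nrow(x@points)

#' @describeIn ObjectGraph edge matrix (i < j, 1-based)
#' @export
graphEdges <- function(x) x@edges

#' Node degrees of an ObjectGraph
#'
#' @param x an [ObjectGraph-class].
#' @return integer degree per node.
#' @export
nodeDegrees <- function(x) {
  n <- nrow(x@points)
  tabulate(c(x@edges[, 1], x@edges[, 2]), nbins = n)
}

setMethod("show", "ObjectGraph", function(object) {
  cat(sprintf("ObjectGraph: %d nodes, %d edges (rule %s, parameter %g)\n",
              nrow(object@points), nrow(object@edges), object@rule,
              object@parameter))
})
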