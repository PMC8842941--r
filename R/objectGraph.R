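## Spatial object graphs over detected LTS patch centers and the degree /
## point-pattern homogeneity features derived from them. The proprietary
## per-object graph features reported alongside the original pipeline are
## unpublished; this module ships an open, versioned analogue set
## ("graph_v1"): degree-distribution summaries over parameterized
## neighbourhood graphs plus nearest-neighbour / quadrat homogeneity
## statistics.

#' Build a spatial graph over object centers
#'
#' Edge rules: `"radius"` connects every pair at Euclidean distance
#' `<= parameter`; `"knn"` connects each node to its `parameter` nearest
#' neighbours (symmetrized to an undirected union); `"delaunay"` uses the
#' edges of the Delaunay triangulation (computed by the empty-circumcircle
#' definition, intended for small point sets). The graph is undirected and
#' simple.
#'
#' @param points n x 2 coordinate matrix (n >= 0).
#' @param rule `"radius"`, `"knn"` or `"delaunay"`.
#' @param parameter radius in pixels (default 120 = three 40-px cells) or k
#'   for `"knn"`; ignored for `"delaunay"`. `k >= n` is clamped to `n - 1`
#'   with a warning.
#' @return An [ObjectGraph-class].
#' @examples
#' g <- buildObjectGraph(rbind(c(0, 0), c(0, 5)), "radius", 10)
#' nrow(graphEdges(g))  # 1
#' @export
buildObjectGraph <- function(points, rule = c("radius", "knn", "delaunay"),
                             parameter = 120) {
  rule <- match.arg(rule)
  points <- as.matrix(points)
  n <- nrow(points)
  emptyE <- matrix(integer(), 0L, 2L)
  if (n < 2L)
    return(new("ObjectGraph", points = points, edges = emptyE, rule = rule,
               parameter = as.numeric(parameter)))
  D <- pointDist(points)
  edges <- switch(rule,
    radius = {
      idx <- which(D <= parameter & upper.tri(D), arr.ind = TRUE)
      unname(idx)
    },
    knn = {
      k <- as.integer(parameter)
      if (k >= n) {
        warning("k >= n; clamped to n - 1")
        k <- n - 1L
      }
      stopIfNot(k >= 1L, "k must be >= 1")
      pairs <- matrix(integer(), 0L, 2L)
      for (i in seq_len(n)) {
        d <- D[i, ]; d[i] <- Inf
        nb <- order(d)[seq_len(k)]
        pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
      }
      unique(pairs)
    },
    delaunay = .delaunayEdges(points, D))
  if (nrow(edges))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  new("ObjectGraph", points = points, edges = edges, rule = rule,
      parameter = as.numeric(parameter))
}

## Delaunay edges by the empty-circumcircle criterion (brute force; O(n^4),
## fine for the small per-cluster point sets it is offered for). Collinear
## triples are skipped; for n = 2 the single edge is returned.
.delaunayEdges <- function(points, D) {
  n <- nrow(points)
  if (n == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  if (n > 200L)
    stop("brute-force Delaunay is limited to n <= 200 points", call. = FALSE)
  inEdge <- matrix(FALSE, n, n)
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    p1 <- points[i, ]; p2 <- points[j, ]; p3 <- points[k, ]
    d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
                p3[1] * (p1[2] - p2[2]))
    if (abs(d) < 1e-12) next
    u1 <- sum(p1^2); u2 <- sum(p2^2); u3 <- sum(p3^2)
    cx <- (u1 * (p2[2] - p3[2]) + u2 * (p3[2] - p1[2]) +
             u3 * (p1[2] - p2[2])) / d
    cy <- (u1 * (p3[1] - p2[1]) + u2 * (p1[1] - p3[1]) +
             u3 * (p2[1] - p1[1])) / d
    r2 <- sum((p1 - c(cx, cy))^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    cc2 <- (points[others, 1] - cx)^2 + (points[others, 2] - cy)^2
    if (all(cc2 > r2 * (1 + 1e-12))) {
      inEdge[i, j] <- inEdge[j, k] <- inEdge[i, k] <- TRUE
    }
  }
  idx <- which(inEdge & upper.tri(inEdge), arr.ind = TRUE)
  unname(idx)
}

#' Degree-based graph features (graph_v1)
#'
#' Summaries of the node-degree distribution of an object graph: mean,
#' population SD and maximum degree, fraction of isolated nodes, Shannon
#' entropy (bits) of the empirical degree distribution, degree
#' assortativity, and the mean local clustering coefficient (nodes of degree
#' < 2 counted as 0).
#'
#' @param graph an [ObjectGraph-class].
#' @return named numeric vector `degMean, degSd, degMax, fracIsolated,
#'   degEntropy, assortativity, localClustering`; all `NA` for an empty
#'   graph (no nodes). Assortativity is `NA` when degenerate (e.g. regular
#'   graphs).
#' @export
degreeFeatures <- function(graph) {
  stopIfNot(is(graph, "ObjectGraph"), "'graph' must be an ObjectGraph")
  n <- nrow(graph@points)
  nm <- c("degMean", "degSd", "degMax", "fracIsolated", "degEntropy",
          "assortativity", "localClustering")
  if (n == 0L) {
    out <- rep(NA_real_, length(nm)); names(out) <- nm
    return(out)
  }
  deg <- nodeDegrees(graph)
  p <- table(deg) / n
  entropy <- -sum(p * log2(p))
  if (nrow(graph@edges)) {
    ig <- igraph::make_empty_graph(n, directed = FALSE)
    ig <- igraph::add_edges(ig, t(graph@edges))
    assort <- suppressWarnings(igraph::assortativity_degree(ig))
    if (is.nan(assort)) assort <- NA_real_
    lc <- igraph::transitivity(ig, type = "local", isolates = "zero")
    localCC <- mean(lc)
  } else {
    assort <- NA_real_
    localCC <- 0
  }
  out <- c(mean(deg), popSd(deg), max(deg), mean(deg == 0L), entropy,
           assort, localCC)
  names(out) <- nm
  out
}

#' Point-pattern homogeneity features
#'
#' Descriptions of how evenly the detected objects occupy the tissue:
#' mean and population SD of the nearest-neighbour distance, the
#' Clark-Evans ratio `R = mean NN distance / (0.5 sqrt(area / n))`
#' (1 for complete spatial randomness, > 1 regular, < 1 clustered), and the
#' quadrat-count dispersion index (variance/mean of counts over a grid of
#' quadrats; 1 under CSR).
#'
#' @param points n x 2 coordinates (n >= 2 for the NN statistics).
#' @param width,height extent of the observation window in pixels (area =
#'   `width * height` must be positive).
#' @param quadrats quadrat grid as `c(rows, cols)`, default `c(8, 8)`.
#' @return named numeric vector `nnMean, nnSd, clarkEvans,
#'   quadratDispersion`.
#' @export
homogeneityFeatures <- function(points, width, height, quadrats = c(8L, 8L)) {
  points <- as.matrix(points)
  n <- nrow(points)
  area <- as.numeric(width) * as.numeric(height)
  stopIfNot(area > 0, "window area must be positive")
  nm <- c("nnMean", "nnSd", "clarkEvans", "quadratDispersion")
  if (n < 2L) {
    out <- rep(NA_real_, 4L); names(out) <- nm
    return(out)
  }
  D <- pointDist(points)
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  ce <- mean(nn) / (0.5 * sqrt(area / n))
  ri <- pmin(floor(points[, 1] / height * quadrats[1]), quadrats[1] - 1L)
  ci <- pmin(floor(points[, 2] / width * quadrats[2]), quadrats[2] - 1L)
  cnt <- tabulate(ri * quadrats[2] + ci + 1L, quadrats[1] * quadrats[2])
  qd <- if (mean(cnt) > 0) stats::var(cnt) / mean(cnt) else NA_real_
  out <- c(mean(nn), popSd(nn), ce, qd)
  names(out) <- nm
  out
}
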