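## Cluster descriptors and validity indices over a clustering of detected
## LTS patch centers. All distances are Euclidean in pixel units; SDs use
## the population denominator.

.clusterPrep <- function(clustering, points) {
  stopIfNot(is(clustering, "APClustering"),
            "'clustering' must be an APClustering")
  points <- as.matrix(points)
  stopIfNot(nrow(points) == length(clustering@labels),
            "points and labels must align")
  lab <- clustering@labels
  K <- clustering@K
  list(points = points, lab = lab, K = K, n = nrow(points))
}

#' Cluster descriptors
#'
#' Per-cluster size, dispersion (mean distance to the cluster centroid),
#' extent (maximum within-cluster pairwise distance) summarized by their
#' mean and population SD over clusters, plus the between-cluster scatter
#' `BGSS = sum_k n_k ||mu_k - mu||^2`.
#'
#' @param clustering an [APClustering-class].
#' @param points the clustered n x 2 coordinates.
#' @return named numeric vector `K, clusterSizeMean, clusterSizeSd,
#'   dispersionMean, dispersionSd, extentMean, extentSd, bgss`; all `NA`
#'   (except `K = 0`) for an empty clustering.
#' @export
clusterDescriptors <- function(clustering, points) {
  p <- .clusterPrep(clustering, points)
  nm <- c("K", "clusterSizeMean", "clusterSizeSd", "dispersionMean",
          "dispersionSd", "extentMean", "extentSd", "bgss")
  if (p$n == 0L) {
    out <- c(0, rep(NA_real_, 7L)); names(out) <- nm
    return(out)
  }
  sizes <- dispersion <- extent <- numeric(p$K)
  mu <- colMeans(p$points)
  bgss <- 0
  for (k in seq_len(p$K)) {
    pts <- p$points[p$lab == k, , drop = FALSE]
    sizes[k] <- nrow(pts)
    ck <- colMeans(pts)
    dispersion[k] <- mean(sqrt(rowSums(sweep(pts, 2L, ck)^2)))
    extent[k] <- if (nrow(pts) > 1L) max(dist(pts)) else 0
    bgss <- bgss + nrow(pts) * sum((ck - mu)^2)
  }
  out <- c(p$K, mean(sizes), popSd(sizes), mean(dispersion),
           popSd(dispersion), mean(extent), popSd(extent), bgss)
  names(out) <- nm
  out
}

#' Cluster validity indices
#'
#' The six indices scoring compactness and separation of a clustering:
#' \describe{
#'   \item{ballHall}{`(1/K) sum_k WGSS_k / n_k` (mean within-cluster mean
#'     squared centroid distance).}
#'   \item{banfeldRaftery}{`sum_k n_k log(WGSS_k / n_k)`, with the variance
#'     term floored at `eps` to guard `log(0)` for singleton or coincident
#'     clusters.}
#'   \item{logSSRatio}{`log(BGSS / WGSS)`.}
#'   \item{daviesBouldin}{`(1/K) sum_k max_{l != k} (d_k + d_l) /
#'     ||mu_k - mu_l||`, `d` = mean centroid distance.}
#'   \item{calinskiHarabasz}{`(BGSS / (K - 1)) / (WGSS / (n - K))`;
#'     `Inf` when WGSS = 0.}
#'   \item{cIndex}{`(S_W - S_min) / (S_max - S_min)` where `S_W` sums the
#'     within-cluster pairwise distances and `S_min`/`S_max` sum the same
#'     number of smallest/largest distances over all pairs; in `[0, 1]`
#'     whenever defined.}
#' }
#' Indices requiring `K >= 2` (`logSSRatio`, `daviesBouldin`,
#' `calinskiHarabasz`, `cIndex`) are `NA` for a single cluster.
#'
#' @param clustering an [APClustering-class].
#' @param points the clustered n x 2 coordinates (n >= 2).
#' @param eps variance floor for the Banfeld-Raftery log, default 1e-12.
#' @return named numeric vector of the six indices.
#' @export
validityIndices <- function(clustering, points, eps = 1e-12) {
  p <- .clusterPrep(clustering, points)
  stopIfNot(p$n >= 2L, "need at least 2 points")
  K <- p$K; n <- p$n
  wgssK <- sizes <- delta <- numeric(K)
  cents <- matrix(0, K, 2L)
  for (k in seq_len(K)) {
    pts <- p$points[p$lab == k, , drop = FALSE]
    sizes[k] <- nrow(pts)
    cents[k, ] <- colMeans(pts)
    d2 <- rowSums(sweep(pts, 2L, cents[k, ])^2)
    wgssK[k] <- sum(d2)
    delta[k] <- mean(sqrt(d2))
  }
  wgss <- sum(wgssK)
  mu <- colMeans(p$points)
  bgss <- sum(sizes * rowSums(sweep(cents, 2L, mu)^2))
  ballHall <- mean(wgssK / sizes)
  banfeldRaftery <- sum(sizes * log(pmax(wgssK / sizes, eps)))
  if (K < 2L) {
    logSS <- db <- ch <- cidx <- NA_real_
  } else {
    logSS <- if (wgss > 0) log(bgss / wgss) else Inf
    cd <- as.matrix(dist(cents))
    ratio <- outer(delta, delta, "+") / cd
    diag(ratio) <- -Inf
    db <- mean(apply(ratio, 1L, max))
    ch <- if (wgss > 0) (bgss / (K - 1)) / (wgss / (n - K)) else Inf
    dAll <- as.matrix(dist(p$points))
    same <- outer(p$lab, p$lab, "==") & upper.tri(dAll)
    sW <- sum(dAll[same])
    nW <- sum(same)
    if (nW == 0L) {
      cidx <- 0
    } else {
      allD <- sort(dAll[upper.tri(dAll)])
      sMin <- sum(allD[seq_len(nW)])
      sMax <- sum(allD[seq(length(allD) - nW + 1L, length(allD))])
      cidx <- if (sMax > sMin) (sW - sMin) / (sMax - sMin) else 0
    }
  }
  c(ballHall = ballHall, banfeldRaftery = banfeldRaftery,
    logSSRatio = logSS, daviesBouldin = db, calinskiHarabasz = ch,
    cIndex = cidx)
}
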