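## Exemplar-based clustering of detected LTS patch centers by affinity
## propagation: responsibility/availability message passing on the negative
## squared Euclidean distance similarity, with a shared preference on the
## diagonal controlling the number of exemplars.

.apMessagePassing <- function(S, damping, maxIter, convergenceIter) {
  n <- nrow(S)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  exOld <- rep(FALSE, n)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    ## responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    comp <- matrix(max1, n, n)
    comp[cbind(seq_len(n), which1)] <- max2
    R <- damping * R + (1 - damping) * (S - comp)
    ## availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    ex <- (diag(A) + diag(R)) > 0
    if (identical(ex, exOld) && any(ex)) {
      stable <- stable + 1L
      if (stable >= convergenceIter) { converged <- TRUE; break }
    } else stable <- 0L
    exOld <- ex
  }
  list(A = A, R = R, iterations = it, converged = converged)
}

#' Affinity-propagation clustering
#'
#' Clusters points by passing responsibility and availability messages on
#' the similarity `s(i, k) = -||x_i - x_k||^2`, with `s(k, k)` set to
#' `preference` (default: the median off-diagonal similarity). Damped
#' updates run until the exemplar set is stable for `convergenceIter`
#' consecutive iterations or `maxIter` is reached; a non-converged run is
#' returned with `converged = FALSE` and the labels of the last iteration.
#' A tiny seed-controlled jitter is added to the similarities to break the
#' degeneracies of exactly symmetric configurations, so results are
#' deterministic given `seed`.
#'
#' Very negative preferences yield a single cluster; preferences near the
#' maximum similarity make every point its own exemplar.
#'
#' @param points n x 2 numeric matrix of coordinates (n >= 0).
#' @param preference shared diagonal similarity; default median of the
#'   off-diagonal similarities.
#' @param damping message damping factor in `[0.5, 1)`, default 0.5.
#' @param maxIter maximum iterations, default 200.
#' @param convergenceIter iterations of exemplar stability required,
#'   default 15.
#' @param retryDamping damping values tried in order when the run at
#'   `damping` oscillates without converging (the standard remedy for
#'   message oscillation); set to `numeric()` to disable.
#' @param seed RNG seed for the degeneracy-breaking jitter.
#' @return An [APClustering-class]; an empty clustering (`K = 0`) for
#'   `n = 0`.
#' @examples
#' pts <- rbind(c(0, 0), c(1, 0), c(100, 0), c(101, 0))
#' nClusters(affinityPropagation(pts))
#' @export
affinityPropagation <- function(points, preference = NULL, damping = 0.5,
                                maxIter = 200L, convergenceIter = 15L,
                                retryDamping = c(0.7, 0.9), seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopIfNot(all(c(damping, retryDamping) >= 0.5 & c(damping, retryDamping) < 1),
            "damping must be in [0.5, 1)")
  if (n == 0L)
    return(new("APClustering", labels = integer(), exemplars = integer(),
               K = 0L, converged = TRUE, iterations = 0L))
  if (n == 1L)
    return(new("APClustering", labels = 1L, exemplars = 1L, K = 1L,
               converged = TRUE, iterations = 0L))
  S <- -pointDist(points)^2
  if (is.null(preference)) {
    off <- S[upper.tri(S) | lower.tri(S)]
    preference <- median(off)
  }
  diag(S) <- preference
  ## break ties/degeneracies as the reference implementations do
  scale <- max(abs(S)); if (scale == 0) scale <- 1
  S <- S + withSeed(seed, matrix(rnorm(n * n), n, n)) * 1e-12 * scale

  dampings <- c(damping, retryDamping)
  for (dmp in dampings) {
    res <- .apMessagePassing(S, dmp, maxIter, convergenceIter)
    if (res$converged) break
  }
  A <- res$A; R <- res$R; it <- res$iterations; converged <- res$converged
  exemplars <- which((diag(A) + diag(R)) > 0)
  if (!length(exemplars))            # degenerate non-convergence
    exemplars <- which.max(diag(A) + diag(R))
  ## assign each point to its best exemplar, then refine exemplars as the
  ## similarity-maximizing member of each cluster (standard final step)
  assign <- exemplars[max.col(S[, exemplars, drop = FALSE],
                              ties.method = "first")]
  assign[exemplars] <- exemplars
  for (k in seq_along(exemplars)) {
    members <- which(assign == exemplars[k])
    if (length(members) > 1L) {
      within <- S[members, members, drop = FALSE]
      best <- members[which.max(colSums(within))]
      assign[members] <- best
      exemplars[k] <- best
    }
  }
  exemplars <- sort(unique(assign))
  labels <- match(assign, exemplars)
  new("APClustering", labels = as.integer(labels),
      exemplars = as.integer(exemplars), K = length(exemplars),
      converged = converged, iterations = it)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same points.
#'
#' @param a,b integer label vectors of equal length.
#' @return ARI in `[-1, 1]`, 1 for identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  stopIfNot(length(a) == length(b), "label vectors must align")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sumij <- sum(ch2(tab))
  ai <- sum(ch2(rowSums(tab)))
  bj <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- ai * bj / ch2(n)
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (sumij - expected) / (maxi - expected)
}
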