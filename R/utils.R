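#' @importFrom methods new validObject is slot
#' @importFrom stats median sd rnorm runif rpois rnbinom rbinom quantile
#'   pt pnorm pchisq cor kruskal.test cor.test dist predict coef
#' @importFrom utils head read.csv write.csv combn
NULL

## Run an expression under a fixed RNG state and restore the caller's state
## afterwards, so generators are pure functions of (spec, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

## Derive a stream of child seeds (< 2^31) from a master seed.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## Population standard deviation (denominator n), the convention used for all
## feature SDs in this package.
popSd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

## Fast 3x3 median filter on a matrix via a compare-exchange network
## (19 min/max operations give the median of 9); edges use replicated padding.
medianFilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  pad[1L, ] <- pad[2L, ]; pad[nr + 2L, ] <- pad[nr + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, nc + 2L] <- pad[, nc + 1L]
  sh <- function(dr, dc) pad[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  p <- list(sh(0L,0L), sh(0L,1L), sh(0L,2L),
            sh(1L,0L), sh(1L,1L), sh(1L,2L),
            sh(2L,0L), sh(2L,1L), sh(2L,2L))
  cx <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  ## Paeth's 9-element median network
  cx(2,3); cx(5,6); cx(8,9); cx(1,2); cx(4,5); cx(7,8); cx(2,3); cx(5,6)
  cx(8,9); cx(1,4); cx(6,9); cx(5,8); cx(4,7); cx(2,5); cx(3,6); cx(5,8)
  cx(3,5); cx(7,5); cx(3,5)
  p[[5]]
}

## Euclidean distance matrix for an n x 2 coordinate matrix.
pointDist <- function(points) {
  as.matrix(dist(points))
}

isFiniteScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
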