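## Inter-rater reliability statistics qualifying the annotated ground truth:
## Fleiss' kappa over an items x raters categorical table, raw pairwise
## percent agreement, and rank-based filtering (e.g. excluding ambiguous
## "possible" objects improves concordance).

.categoryCounts <- function(table) {
  r <- table@ratings
  cats <- table@categories
  ## drop categories never used so empty marginals cannot distort P_e
  cats <- cats[cats %in% as.vector(r)]
  counts <- vapply(cats, function(ct) rowSums(r == ct),
                   numeric(nrow(r)))
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = nrow(r))
  colnames(counts) <- cats
  counts
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement `kappa = (Pbar - Pe) / (1 - Pe)` with `Pbar`
#' the mean per-item agreement over rater pairs and `Pe = sum_j p_j^2` over
#' the category marginals. Categories never used by any rater are dropped
#' before the marginals are formed. A table on which all raters agree on all
#' items returns exactly 1; `Pe = 1` with imperfect agreement (all ratings a
#' single category yet somehow disagreeing is impossible, but degenerate
#' marginals can arise through filtering) raises an error.
#'
#' @param table a [RatingTable-class].
#' @return kappa in `[-1, 1]`.
#' @examples
#' t <- RatingTable(matrix("a", 10, 5))
#' fleissKappa(t)  # 1
#' @export
fleissKappa <- function(table) {
  stopIfNot(is(table, "RatingTable"), "'table' must be a RatingTable")
  validObject(table)
  counts <- .categoryCounts(table)
  n <- nrow(counts); m <- ncol(table@ratings)
  Pi <- (rowSums(counts^2) - m) / (m * (m - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (n * m)
  Pe <- sum(pj^2)
  if (Pe >= 1 - 1e-15) {
    if (Pbar >= 1 - 1e-15) return(1)
    stop("degenerate category marginals: chance agreement is 1 ",
         "with imperfect observed agreement", call. = FALSE)
  }
  if (Pbar >= 1 - 1e-15) return(1)
  (Pbar - Pe) / (1 - Pe)
}

#' Pairwise rater agreement and kappa
#'
#' For every pair of raters, the raw fraction of items with identical
#' category (not chance-corrected) and the two-rater Fleiss' kappa computed
#' on that pair's subtable. Both matrices are symmetric with unit diagonal.
#'
#' @param table a [RatingTable-class].
#' @return list with elements `agreement` and `kappa`, raters x raters
#'   matrices.
#' @export
pairwiseAgreement <- function(table) {
  stopIfNot(is(table, "RatingTable"), "'table' must be a RatingTable")
  validObject(table)
  r <- table@ratings
  m <- ncol(r)
  agree <- diag(1, m); kap <- diag(1, m)
  nm <- colnames(r)
  if (!is.null(nm)) dimnames(agree) <- dimnames(kap) <- list(nm, nm)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    agree[a, b] <- agree[b, a] <- mean(r[, a] == r[, b])
    sub <- RatingTable(r[, c(a, b)], categories = table@categories)
    kap[a, b] <- kap[b, a] <- fleissKappa(sub)
  }
  list(agreement = agree, kappa = kap)
}

#' Exclude a confidence rank from annotations or a rating table
#'
#' Removes all objects (or rating items) of the named confidence rank,
#' mirroring the sensitivity analysis in which ambiguous `"possible"`
#' objects are excluded before recomputing concordance.
#'
#' @param x an [AnnotationSet-class] or [RatingTable-class].
#' @param rank rank to remove: `"definite"`, `"probable"`, `"possible"`
#'   (or 3/2/1); for rating tables any category name is accepted.
#' @param ... unused.
#' @return the filtered object of the same class.
#' @export
setGeneric("excludeRank", function(x, rank, ...) standardGeneric("excludeRank"))

#' @describeIn excludeRank drop foreground objects of the given rank;
#'   background objects and other ranks are conserved.
#' @export
setMethod("excludeRank", "AnnotationSet", function(x, rank, ...) {
  if (is.character(rank)) {
    stopIfNot(rank %in% names(.RANKS), sprintf("unknown rank '%s'", rank))
    rank <- .RANKS[[rank]]
  }
  stopIfNot(rank %in% 1:3, "rank must be 1, 2 or 3")
  keep <- !(x@objects$class == "foreground" &
              !is.na(x@objects$rank) & x@objects$rank == rank)
  out <- x
  out@objects <- x@objects[keep, , drop = FALSE]
  rownames(out@objects) <- NULL
  out
})

#' @describeIn excludeRank drop items for which any rater used the excluded
#'   category, and drop the category from the category set.
#' @export
setMethod("excludeRank", "RatingTable", function(x, rank, ...) {
  stopIfNot(is.character(rank) && length(rank) == 1L,
            "rank must be a single category name")
  stopIfNot(rank %in% x@categories,
            sprintf("unknown category '%s'", rank))
  keep <- rowSums(x@ratings == rank) == 0L
  if (sum(keep) < 2L)
    stop("excluding this rank leaves fewer than 2 items", call. = FALSE)
  RatingTable(x@ratings[keep, , drop = FALSE],
              categories = setdiff(x@categories, rank))
})
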