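## Rank-based evaluation statistics used at cohort level: Spearman and
## Pearson correlations of features against expert scores and clinical
## measures, Mann-Whitney U between disease groups, Kruskal-Wallis across
## stages. All tests are two-sided.

.dropMissingPairs <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Spearman rank correlation
#'
#' Rho as the Pearson correlation of mid-ranked data (ties averaged), with
#' a two-sided p-value from the t-approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (pairs with missing values dropped; n >= 3
#'   after dropping).
#' @return list `rho`, `p`, `n`.
#' @export
spearmanRho <- function(x, y) {
  d <- .dropMissingPairs(x, y)
  stopIfNot(d$n >= 3L, "need at least 3 complete pairs")
  rx <- rank(d$x); ry <- rank(d$y)
  if (popSd(rx) == 0 || popSd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = d$n))
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((d$n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = d$n - 2)
  }
  list(rho = rho, p = p, n = d$n)
}

#' Pearson product-moment correlation
#'
#' Standard r with a two-sided t-distribution p-value (via
#' [stats::cor.test()]). Zero variance in either vector yields a flagged
#' missing result.
#'
#' @param x,y numeric vectors (n >= 3 complete pairs).
#' @return list `r`, `p`, `n`.
#' @export
pearsonR <- function(x, y) {
  d <- .dropMissingPairs(x, y)
  stopIfNot(d$n >= 3L, "need at least 3 complete pairs")
  if (popSd(d$x) == 0 || popSd(d$y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = d$n))
  ct <- cor.test(d$x, d$y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = d$n)
}

## Exact two-sided Mann-Whitney p by full enumeration of the
## choose(n, na) group assignments of the pooled mid-ranks:
## p = P(|U - na*nb/2| >= |U_obs - na*nb/2|).
.mwExactP <- function(ranks, na, Uobs) {
  n <- length(ranks)
  nb <- n - na
  mu <- na * nb / 2
  dev <- abs(Uobs - mu)
  combos <- combn(n, na)
  hits <- 0L
  for (i in seq_len(ncol(combos))) {
    Ua <- sum(ranks[combos[, i]]) - na * (na + 1) / 2
    if (abs(Ua - mu) >= dev - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combos)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two groups. `U` is reported as
#' `min(U_a, U_b)` (the SPSS convention). For `n_a + n_b <= exactLimit` the
#' p-value is computed by full enumeration of all group assignments of the
#' pooled mid-ranks (ties handled exactly); otherwise by the tie-corrected
#' normal approximation without continuity correction.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exactLimit total sample size up to which enumeration is used,
#'   default 12.
#' @return list `U`, `p`, `n` = c(n_a, n_b), `method`.
#' @export
mannWhitneyU <- function(a, b, exactLimit = 12L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  stopIfNot(na >= 1L && nb >= 1L, "both groups must be non-empty")
  pooled <- c(a, b)
  rk <- rank(pooled)
  Ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  if (na + nb <= exactLimit) {
    p <- .mwExactP(rk, na, Ua)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(rk)
    tieTerm <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tieTerm)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (Ua - na * nb / 2) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, n = c(na, nb), method = method)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square p-value on `k - 1` degrees of freedom
#' (delegates to [stats::kruskal.test()]). When every observation is
#' identical the statistic is returned as `H = 0` with a flagged missing
#' p-value (`allTies = TRUE`).
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list `H`, `p`, `df`, `allTies`.
#' @export
kruskalWallis <- function(groups) {
  stopIfNot(is.list(groups) && length(groups) >= 2L,
            "need a list of >= 2 groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  stopIfNot(all(vapply(groups, length, integer(1)) >= 1L),
            "all groups must be non-empty")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = NA_real_, df = length(groups) - 1L,
                allTies = TRUE))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), allTies = FALSE)
}

#' Feature-wise group comparisons of a subject table
#'
#' Convenience wrapper producing the per-feature Mann-Whitney (disease vs
#' control) and Kruskal-Wallis (across PD stages 1-3) tables for an
#' aggregated subject feature data.frame.
#'
#' @param subjectFeatures data.frame with `subjectId` plus feature columns.
#' @param status binary status vector aligned to rows.
#' @param stage integer stages aligned to rows.
#' @param features feature columns to test; default all numeric columns.
#' @return data.frame: feature, U, pMW (status comparison), H, pKW (stage
#'   1-3 comparison).
#' @export
cohortStatTable <- function(subjectFeatures, status, stage,
                            features = NULL) {
  num <- vapply(subjectFeatures, is.numeric, logical(1))
  if (is.null(features)) features <- names(subjectFeatures)[num]
  rows <- lapply(features, function(f) {
    v <- subjectFeatures[[f]]
    mw <- tryCatch(mannWhitneyU(v[status == 1], v[status == 0]),
                   error = function(e) list(U = NA_real_, p = NA_real_))
    pdStages <- stage[stage > 0]
    kw <- tryCatch(kruskalWallis(split(v[stage > 0], pdStages)),
                   error = function(e) list(H = NA_real_, p = NA_real_))
    data.frame(feature = f, U = mw$U, pMW = mw$p, H = kw$H, pKW = kw$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
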