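## Subject-level modeling: max-aggregation of slide features, repeated-LASSO
## feature selection over stratified train/test splits, and elastic-net
## logistic prediction of disease status and stage with mean +/- SD metrics
## over repeated splits. glmnet provides the penalized fits; the protocol
## (stratification, train-only standardization, internal lambda selection,
## per-repeat metric bookkeeping) is implemented here.

#' Aggregate slide features to subjects
#'
#' One feature vector per subject, taking for every feature the chosen
#' statistic over the subject's slides (default the maximum, which
#' outperformed mean/median/min in the study this package models). Missing
#' slide values are skipped; a feature missing on all slides stays `NA`.
#'
#' @param features data.frame from [cohortFeatureTable()] (needs
#'   `subjectId` plus numeric feature columns).
#' @param statistic `"max"` (default), `"mean"`, `"median"` or `"min"`.
#' @return data.frame with one row per subject: `subjectId` + aggregated
#'   features.
#' @export
aggregateSubjects <- function(features,
                              statistic = c("max", "mean", "median", "min")) {
  statistic <- match.arg(statistic)
  stopIfNot("subjectId" %in% names(features), "need a 'subjectId' column")
  fun <- switch(statistic, max = max, mean = mean, median = median,
                min = min)
  num <- vapply(features, is.numeric, logical(1))
  num[names(num) %in% c("stage", "score", "seed")] <- FALSE
  cols <- names(features)[num]
  ids <- unique(features$subjectId)
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else fun(v)
  }
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- features[features$subjectId == id, cols, drop = FALSE]
    if (!nrow(sub)) stop("subject with zero slides: ", id, call. = FALSE)
    vapply(sub, agg, numeric(1))
  }))
  data.frame(subjectId = ids, as.data.frame(out), row.names = NULL)
}

#' Complete a feature matrix for penalized modeling
#'
#' Replaces missing entries by `fill` (default 0: on these features the
#' absence of detected LTS carries no spatial signal) and drops constant
#' columns, which are uninformative for penalized fits.
#'
#' @param X numeric matrix or data.frame of features.
#' @param fill imputation value.
#' @param dropConstant drop zero-variance columns (default TRUE).
#' @return numeric matrix.
#' @export
completeFeatureMatrix <- function(X, fill = 0, dropConstant = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X[!is.finite(X)] <- fill
  if (dropConstant) {
    keep <- apply(X, 2L, function(v) popSd(v) > 0)
    X <- X[, keep, drop = FALSE]
  }
  X
}

## Stratified train/test split indices; per-class train counts are capped
## so the test set is never empty, and degenerate draws are resampled.
.stratifiedSplit <- function(y, trainFrac, maxTries = 100L) {
  classes <- unique(y)
  nTrain <- vapply(classes, function(cls) {
    n <- sum(y == cls)
    as.integer(max(1L, min(n, round(trainFrac * n))))
  }, integer(1))
  if (sum(nTrain) == length(y))  # tiny cohorts: free one slot for testing
    nTrain[which.max(nTrain)] <- nTrain[which.max(nTrain)] - 1L
  for (t in seq_len(maxTries)) {
    trainIdx <- unlist(lapply(seq_along(classes), function(i)
      sample(which(y == classes[i]), nTrain[i])))
    if (length(unique(y[trainIdx])) >= 2L) return(sort(trainIdx))
  }
  stop("could not draw a stratified split with both classes", call. = FALSE)
}

## z-score X by train-split statistics only (leakage-free).
.standardizeByTrain <- function(X, trainIdx) {
  mu <- colMeans(X[trainIdx, , drop = FALSE])
  sg <- apply(X[trainIdx, , drop = FALSE], 2L, stats::sd)
  sg[sg < 1e-12] <- 1
  sweep(sweep(X, 2L, mu), 2L, sg, "/")
}

## Unpenalized fallback for splits glmnet cannot fit (a class with fewer
## than 2 training observations, as in micro-cohorts): plain logistic /
## multinomial regression.
.smallSampleFit <- function(Xtr, ytr, family) {
  p <- ncol(Xtr)
  cn <- paste0("V", seq_len(p))
  df <- as.data.frame(Xtr)
  names(df) <- cn
  if (family == "binomial") {
    df$.y <- ytr
    g <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                     family = stats::binomial()))
    beta <- coef(g)[-1L]
    beta[is.na(beta)] <- 0
    list(beta = unname(beta),
         response = function(X) {
           nd <- as.data.frame(X); names(nd) <- cn
           suppressWarnings(as.numeric(predict(g, newdata = nd,
                                               type = "response")))
         })
  } else {
    df$.y <- factor(ytr)
    m <- suppressWarnings(nnet::multinom(.y ~ ., data = df, trace = FALSE))
    cf <- coef(m)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L)
    absBeta <- colMeans(abs(cf[, -1L, drop = FALSE]))
    list(beta = unname(absBeta),
         class = function(X) {
           nd <- as.data.frame(X); names(nd) <- cn
           as.character(suppressWarnings(predict(m, newdata = nd)))
         })
  }
}

## Penalized fit on the training split with lambda chosen by internal
## cross-validation on the train split only. `rule` picks the CV lambda:
## "1se" (parsimonious; used for feature selection) or "min" (accuracy;
## used for prediction). Splits glmnet cannot handle fall back to the
## unpenalized fit.
.penalizedFit <- function(Xtr, ytr, alpha, family = "binomial",
                          rule = c("min", "1se"), nfolds = 5L) {
  rule <- match.arg(rule)
  tab <- table(ytr)
  if (min(tab) < 2L) return(.smallSampleFit(Xtr, ytr, family))
  nfolds <- min(nfolds, max(3L, min(tab)))
  foldid <- sample(rep_len(seq_len(nfolds), length(ytr)))
  yfit <- if (family == "multinomial") factor(ytr) else ytr
  ## small-cohort folds routinely trip glmnet's small-class warnings;
  ## they are expected at n ~ 50 and not actionable
  cv <- try(suppressWarnings(
    glmnet::cv.glmnet(Xtr, yfit, family = family, alpha = alpha,
                      foldid = foldid, standardize = FALSE,
                      nlambda = 50L)), silent = TRUE)
  if (inherits(cv, "try-error")) return(.smallSampleFit(Xtr, ytr, family))
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  fit <- cv$glmnet.fit
  if (family == "binomial") {
    list(beta = as.numeric(coef(fit, s = lam))[-1L],
         response = function(X)
           as.numeric(predict(fit, X, s = lam, type = "response")))
  } else {
    cf <- coef(fit, s = lam)
    absBeta <- rowMeans(vapply(cf, function(b) abs(as.numeric(b)[-1L]),
                               numeric(ncol(Xtr))))
    list(beta = absBeta,
         class = function(X)
           as.character(predict(fit, X, s = lam, type = "class")))
  }
}

#' Repeated-LASSO feature selection
#'
#' Repeats `nRepeats` times: draw a stratified `trainFrac` train split,
#' z-score features on the training split, fit an L1-penalized logistic
#' model (lambda by internal cross-validation on the training split), and
#' record which features receive non-zero coefficients (lambda at the
#' parsimonious one-standard-error rule of the internal CV, so pure-noise
#' features are selected only sporadically). Reported per feature: the
#' selection frequency across repeats and the mean absolute standardized
#' coefficient over the repeats that selected it.
#'
#' @param X subjects x features numeric matrix (complete; see
#'   [completeFeatureMatrix()]).
#' @param y binary outcome (0/1), at least 2 subjects per class.
#' @param nRepeats number of random splits, default 1000.
#' @param trainFrac training fraction, default 0.8.
#' @param seed master seed; results are a pure function of (data, seed).
#' @param family `"binomial"` (default) for a binary outcome or
#'   `"multinomial"` for stage labels; under `"multinomial"` a feature
#'   counts as selected when any class coefficient is non-zero and the
#'   importance averages the absolute class coefficients.
#' @return data.frame `feature, frequency, meanImportance`, sorted by
#'   decreasing frequency then importance.
#' @export
repeatedLassoSelection <- function(X, y, nRepeats = 1000L, trainFrac = 0.8,
                                   seed = 1L,
                                   family = c("binomial", "multinomial")) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopIfNot(all(table(y) >= 2L) && length(unique(y)) >= 2L,
            "need >= 2 subjects per class and >= 2 classes")
  if (family == "binomial")
    stopIfNot(length(unique(y)) == 2L, "binomial needs a binary outcome")
  stopIfNot(all(is.finite(X)), "X must be complete (completeFeatureMatrix)")
  p <- ncol(X)
  selCount <- numeric(p)
  impSum <- numeric(p)
  seeds <- childSeeds(seed, nRepeats)
  for (r in seq_len(nRepeats)) {
    withSeed(seeds[r], {
      tr <- .stratifiedSplit(y, trainFrac)
      Xs <- .standardizeByTrain(X, tr)
      fam <- if (family == "binomial") "binomial" else "multinomial"
      f <- .penalizedFit(Xs[tr, , drop = FALSE], y[tr], alpha = 1,
                         family = fam, rule = "1se")
      absBeta <- abs(f$beta)
      sel <- absBeta > 0
      selCount <- selCount + sel
      impSum <- impSum + absBeta
    })
  }
  freq <- selCount / nRepeats
  meanImp <- ifelse(selCount > 0, impSum / selCount, 0)
  out <- data.frame(feature = colnames(X), frequency = freq,
                    meanImportance = meanImp)
  out[order(-out$frequency, -out$meanImportance), , drop = FALSE]
}

.binaryMetrics <- function(pred, truth) {
  tp <- sum(pred == 1L & truth == 1L); tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L); fn <- sum(pred == 0L & truth == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec,
    f1 = f1Score(prec, sens), accuracy = (tp + tn) / length(truth))
}

.summarizeRepeats <- function(perRepeat) {
  means <- colMeans(perRepeat, na.rm = TRUE)
  sds <- apply(perRepeat, 2L, popSd)
  excluded <- colSums(is.na(perRepeat))
  data.frame(metric = colnames(perRepeat), mean = means, sd = sds,
             nExcluded = excluded, row.names = NULL)
}

#' Repeated elastic-net prediction of disease status
#'
#' Trains and validates `nRepeats` elastic-net logistic models
#' (`l1Ratio` is the elastic-net mixing parameter, default 0.01) on random
#' stratified train/test splits of the selected-feature matrix, reporting
#' sensitivity, specificity, precision, F1 and accuracy on each test split
#' (positive class = disease) and their mean and population SD over
#' repeats. Repeats whose test split lacks a class leave the undefined
#' metrics `NA`; those repeats are excluded from that metric's mean/SD and
#' counted in `nExcluded`.
#'
#' @param X subjects x selected-features matrix (complete).
#' @param y binary outcome (1 = disease).
#' @param l1Ratio elastic-net mixing parameter (glmnet alpha), default
#'   0.01.
#' @param nRepeats number of random splits, default 1000.
#' @param trainFrac training fraction, default 0.8.
#' @param seed master seed.
#' @return list: `perRepeat` (nRepeats x 5 matrix), `summary` (data.frame
#'   metric/mean/sd/nExcluded).
#' @export
fitPredictElasticnet <- function(X, y, l1Ratio = 0.01, nRepeats = 1000L,
                                 trainFrac = 0.8, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopIfNot(all(table(y) >= 2L) && length(unique(y)) == 2L,
            "need a binary outcome with >= 2 subjects per class")
  stopIfNot(all(is.finite(X)), "X must be complete (completeFeatureMatrix)")
  perRepeat <- matrix(NA_real_, nRepeats, 5L,
                      dimnames = list(NULL, c("sensitivity", "specificity",
                                              "precision", "f1",
                                              "accuracy")))
  seeds <- childSeeds(seed, nRepeats)
  for (r in seq_len(nRepeats)) {
    withSeed(seeds[r], {
      tr <- .stratifiedSplit(y, trainFrac)
      te <- setdiff(seq_along(y), tr)
      Xs <- .standardizeByTrain(X, tr)
      f <- .penalizedFit(Xs[tr, , drop = FALSE], y[tr], alpha = l1Ratio)
      prob <- f$response(Xs[te, , drop = FALSE])
      perRepeat[r, ] <- .binaryMetrics(as.integer(prob >= 0.5), y[te])
    })
  }
  list(perRepeat = perRepeat, summary = .summarizeRepeats(perRepeat))
}

#' Repeated multinomial prediction of disease stage
#'
#' The same repeated-split protocol as [fitPredictElasticnet()] with a
#' multinomial elastic-net logistic model, reporting test accuracy
#' (fraction of correctly predicted stages) per variant: `"0-3"` uses all
#' subjects, `"1-3"` excludes stage-0 controls.
#'
#' @param X subjects x features matrix (complete).
#' @param stage integer stages 0-3.
#' @param variants subset of `c("0-3", "1-3")`.
#' @param l1Ratio elastic-net mixing parameter, default 0.01.
#' @param nRepeats,trainFrac,seed as in [fitPredictElasticnet()].
#' @return named list per variant: `perRepeat` accuracy vector, `mean`,
#'   `sd` (population), `n` subjects used.
#' @export
predictStage <- function(X, stage, variants = c("0-3", "1-3"),
                         l1Ratio = 0.01, nRepeats = 1000L, trainFrac = 0.8,
                         seed = 1L) {
  X <- as.matrix(X)
  stage <- as.integer(stage)
  stopIfNot(all(is.finite(X)), "X must be complete (completeFeatureMatrix)")
  variants <- match.arg(variants, several.ok = TRUE)
  out <- list()
  for (v in variants) {
    keep <- if (v == "1-3") which(stage > 0L) else seq_along(stage)
    Xv <- X[keep, , drop = FALSE]
    yv <- stage[keep]
    stopIfNot(length(unique(yv)) >= 2L, "need >= 2 stages present")
    acc <- rep(NA_real_, nRepeats)
    seeds <- childSeeds(seed, nRepeats)
    for (r in seq_len(nRepeats)) {
      withSeed(seeds[r], {
        tr <- .stratifiedSplit(yv, trainFrac)
        te <- setdiff(seq_along(yv), tr)
        Xs <- .standardizeByTrain(Xv, tr)
        f <- tryCatch(.penalizedFit(Xs[tr, , drop = FALSE], yv[tr],
                                    alpha = l1Ratio,
                                    family = "multinomial"),
                      error = function(e) NULL)
        if (!is.null(f)) {
          cls <- f$class(Xs[te, , drop = FALSE])
          acc[r] <- mean(cls == as.character(yv[te]))
        }
      })
    }
    out[[v]] <- list(perRepeat = acc, mean = mean(acc, na.rm = TRUE),
                     sd = popSd(acc), n = length(keep))
  }
  out
}

#' Expert-score derivative features per subject
#'
#' Subject-level summaries of the per-slide expert scores (0-3) used as the
#' human baseline: maximum score, mean score, count of positive slides
#' (score > 0) and an any-positive flag.
#'
#' @param scores data.frame with columns `subjectId` and `score` (one row
#'   per slide; scores must be in 0-3).
#' @return data.frame: `subjectId, maxScore, meanScore, nPositive,
#'   anyPositive`.
#' @export
expertScoreBaseline <- function(scores) {
  stopIfNot(all(c("subjectId", "score") %in% names(scores)),
            "need 'subjectId' and 'score' columns")
  if (!all(scores$score %in% 0:3))
    stop("scores must lie in {0, 1, 2, 3}", call. = FALSE)
  ids <- unique(scores$subjectId)
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- scores$score[scores$subjectId == id]
    stopIfNot(length(s) >= 1L, "subject without scores")
    data.frame(subjectId = id, maxScore = max(s), meanScore = mean(s),
               nPositive = sum(s > 0), anyPositive = any(s > 0))
  }))
  rownames(out) <- NULL
  out
}
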