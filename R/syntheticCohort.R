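## Synthetic study cohort: subjects across disease stages, slides per
## subject, expert scores, and clinical covariates coupled to the true LTS
## burden. Defaults mirror the submandibular-gland study design this package
## models: 14 controls and 42 PD subjects (15 early / 13 moderate / 14
## advanced) with 13 slides each.

#' Specification of a synthetic cohort
#'
#' @slot nControl,nEarly,nModerate,nAdvanced subject counts per stage.
#' @slot slidesPerSubject slides per subject (default 13).
#' @slot stageBurdenMeans non-decreasing mean foreground LTS objects per
#'   slide for stages 0 (control) to 3 (advanced).
#' @slot stageClustering spatial clustering parameter per stage (passed to
#'   [slideSpec()]).
#' @slot burdenSize negative-binomial size (overdispersion) of per-slide
#'   object counts.
#' @slot rankMix probabilities of definite/probable/possible ranks.
#' @slot scoreThresholds object-count thresholds for expert scores 1, 2, 3.
#' @slot slideHeight,slideWidth,dabRange,noiseSd forwarded to [slideSpec()].
#' @slot clinicalCoupling named list: `updrsStage`, `updrsBurden`,
#'   `datStage`, `datBurden`, `csfBurden` coupling coefficients.
#' @slot clinicalNoise named list of Gaussian noise SDs: `updrs3`,
#'   `updrsTotal`, `dat`, `csf`.
#' @slot seed master RNG seed.
#' @export
setClass("CohortSpec",
  representation(nControl = "integer", nEarly = "integer",
                 nModerate = "integer", nAdvanced = "integer",
                 slidesPerSubject = "integer", stageBurdenMeans = "numeric",
                 stageClustering = "numeric", burdenSize = "numeric",
                 rankMix = "numeric", scoreThresholds = "numeric",
                 slideHeight = "integer", slideWidth = "integer",
                 dabRange = "numeric", noiseSd = "numeric",
                 clinicalCoupling = "list", clinicalNoise = "list",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (min(object@nControl, object@nEarly, object@nModerate,
          object@nAdvanced) < 0L)
    msg <- c(msg, "subject counts must be non-negative")
  if (object@slidesPerSubject < 1L)
    msg <- c(msg, "slidesPerSubject must be >= 1")
  if (length(object@stageBurdenMeans) != 4L ||
      any(diff(object@stageBurdenMeans) < 0))
    msg <- c(msg, "stageBurdenMeans must be non-decreasing over 4 stages")
  if (length(object@stageClustering) != 4L ||
      any(object@stageClustering < 0))
    msg <- c(msg, "stageClustering must be 4 non-negative values")
  if (length(object@rankMix) != 3L || any(object@rankMix < 0) ||
      abs(sum(object@rankMix) - 1) > 1e-8)
    msg <- c(msg, "rankMix must be 3 probabilities summing to 1")
  if (length(object@scoreThresholds) != 3L ||
      any(diff(object@scoreThresholds) <= 0))
    msg <- c(msg, "scoreThresholds must be 3 increasing counts")
  if (length(msg)) msg else TRUE
})

#' Create a CohortSpec
#'
#' Defaults encode the study conditions this generator emulates: 56 subjects
#' (14 controls, 15 early, 13 moderate, 14 advanced PD), 13 slides per
#' subject, a monotone LTS burden gradient over stages, stage-increasing
#' spatial clustering, and clinical covariates (MDS-UPDRS, DAT-SBR, CSF
#' alpha-synuclein) coupled to the true burden (UPDRS positively, DAT-SBR
#' negatively).
#'
#' @param nControl,nEarly,nModerate,nAdvanced subject counts per stage.
#' @param slidesPerSubject slides per subject.
#' @param stageBurdenMeans mean foreground objects per slide by stage,
#'   non-decreasing.
#' @param stageClustering spatial clustering by stage.
#' @param burdenSize negative-binomial size of slide counts.
#' @param rankMix definite/probable/possible mixing probabilities.
#' @param scoreThresholds counts at which expert scores 1/2/3 start.
#' @param slideHeight,slideWidth,dabRange,noiseSd slide rendering parameters.
#' @param clinicalCoupling,clinicalNoise clinical simulation parameters; see
#'   [CohortSpec-class].
#' @param seed master seed.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nControl = 14L, nEarly = 15L, nModerate = 13L,
                       nAdvanced = 14L, slidesPerSubject = 13L,
                       stageBurdenMeans = c(0.2, 6, 18, 45),
                       stageClustering = c(0, 1, 2, 3),
                       burdenSize = 4,
                       rankMix = c(0.40, 0.35, 0.25),
                       scoreThresholds = c(1, 10, 50),
                       slideHeight = 604L, slideWidth = 604L,
                       dabRange = c(0.4, 0.9), noiseSd = 0,
                       clinicalCoupling = list(updrsStage = 7.5,
                                               updrsBurden = 0.15,
                                               datStage = -0.35,
                                               datBurden = -0.012,
                                               csfBurden = -3),
                       clinicalNoise = list(updrs3 = 4, updrsTotal = 5,
                                            dat = 0.25, csf = 280),
                       seed = 1L) {
  obj <- new("CohortSpec", nControl = as.integer(nControl),
             nEarly = as.integer(nEarly), nModerate = as.integer(nModerate),
             nAdvanced = as.integer(nAdvanced),
             slidesPerSubject = as.integer(slidesPerSubject),
             stageBurdenMeans = as.numeric(stageBurdenMeans),
             stageClustering = as.numeric(stageClustering),
             burdenSize = as.numeric(burdenSize),
             rankMix = as.numeric(rankMix),
             scoreThresholds = as.numeric(scoreThresholds),
             slideHeight = as.integer(slideHeight),
             slideWidth = as.integer(slideWidth),
             dabRange = as.numeric(dabRange), noiseSd = as.numeric(noiseSd),
             clinicalCoupling = clinicalCoupling,
             clinicalNoise = clinicalNoise, seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d control / %d early / %d moderate / ",
                     "%d advanced subjects, %d slides each, seed %d\n"),
              object@nControl, object@nEarly, object@nModerate,
              object@nAdvanced, object@slidesPerSubject, object@seed))
})

#' Generate a synthetic cohort
#'
#' Draws, for every subject, per-slide foreground LTS object counts around
#' the subject's stage burden mean (negative binomial), builds a [SlideSpec]
#' per slide (stage-dependent spatial clustering), assigns each slide an
#' expert score 0-3 by thresholding the true object count, and simulates
#' subject-level clinical covariates coupled to the true mean burden:
#' MDS-UPDRS increases and DAT-SBR decreases with stage and burden.
#'
#' Slide images are not rendered here (a cohort of rendered whole-slide
#' arrays would be prohibitively large); each returned `slideSpecs[[i]]` can
#' be rendered on demand with [generateSlide()], and `annotations[[i]]`
#' holds the exact object-level ground truth used by the feature pipeline.
#'
#' @param spec a [CohortSpec-class].
#' @param annotations generate per-slide [AnnotationSet-class]s
#'   (default TRUE; set FALSE to return only tables and slide specs).
#' @return list with elements
#'   \describe{
#'     \item{subjects}{data.frame: subjectId, status (0 control / 1 PD),
#'       stage (0-3), trueBurden (mean objects/slide), UPDRS3, UPDRSTotal,
#'       DAT_SBR, CSF_asyn.}
#'     \item{slides}{data.frame: slideId, subjectId, stage, nForeground,
#'       nDefinite, nProbable, nPossible, nBackground, score, seed.}
#'     \item{scores}{data.frame: slideId, subjectId, score (the per-slide
#'       expert-score table).}
#'     \item{slideSpecs}{list of [SlideSpec-class], one per slide.}
#'     \item{annotations}{list of [AnnotationSet-class] (if requested).}
#'   }
#' @export
generateCohort <- function(spec, annotations = TRUE) {
  stopIfNot(is(spec, "CohortSpec"), "'spec' must be a CohortSpec")
  validObject(spec)
  counts <- c(spec@nControl, spec@nEarly, spec@nModerate, spec@nAdvanced)
  nSub <- sum(counts)
  stages <- rep(0:3, counts)
  withSeed(spec@seed, {
    slideSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                    nSub * spec@slidesPerSubject),
                         nSub, spec@slidesPerSubject)
    subjects <- data.frame(subjectId = sprintf("S%03d", seq_len(nSub)),
                           status = as.integer(stages > 0), stage = stages)
    slideRows <- vector("list", nSub)
    specs <- vector("list", nSub * spec@slidesPerSubject)
    k <- 0L
    for (i in seq_len(nSub)) {
      st <- stages[i]
      mu <- spec@stageBurdenMeans[st + 1L]
      nFg <- if (mu <= 0) rep(0L, spec@slidesPerSubject) else
        rnbinom(spec@slidesPerSubject, size = spec@burdenSize, mu = mu)
      nBg <- rpois(spec@slidesPerSubject, 15)
      rows <- vector("list", spec@slidesPerSubject)
      for (j in seq_len(spec@slidesPerSubject)) {
        split <- if (nFg[j] > 0)
          as.vector(stats::rmultinom(1, nFg[j], spec@rankMix)) else c(0L, 0L, 0L)
        score <- findInterval(nFg[j], spec@scoreThresholds)
        k <- k + 1L
        specs[[k]] <- slideSpec(height = spec@slideHeight,
                                width = spec@slideWidth,
                                nDefinite = split[1], nProbable = split[2],
                                nPossible = split[3], nBackground = nBg[j],
                                spatialClustering = spec@stageClustering[st + 1L],
                                dabRange = spec@dabRange,
                                noiseSd = spec@noiseSd,
                                seed = slideSeeds[i, j])
        rows[[j]] <- data.frame(slideId = sprintf("%s_W%02d",
                                                  subjects$subjectId[i], j),
                                subjectId = subjects$subjectId[i],
                                stage = st, nForeground = nFg[j],
                                nDefinite = split[1], nProbable = split[2],
                                nPossible = split[3], nBackground = nBg[j],
                                score = score, seed = slideSeeds[i, j])
      }
      slideRows[[i]] <- do.call(rbind, rows)
    }
    slides <- do.call(rbind, slideRows)
    rownames(slides) <- NULL

    burden <- tapply(slides$nForeground, slides$subjectId, mean)
    subjects$trueBurden <- as.numeric(burden[subjects$subjectId])
    cc <- spec@clinicalCoupling; cn <- spec@clinicalNoise
    u3 <- 1 + cc$updrsStage * subjects$stage +
      cc$updrsBurden * subjects$trueBurden + rnorm(nSub, 0, cn$updrs3)
    subjects$UPDRS3 <- pmax(u3, 0)
    subjects$UPDRSTotal <- pmax(1.7 * subjects$UPDRS3 +
                                  rnorm(nSub, 0, cn$updrsTotal), 0)
    subjects$DAT_SBR <- pmax(2.7 + cc$datStage * subjects$stage +
                               cc$datBurden * subjects$trueBurden +
                               rnorm(nSub, 0, cn$dat), 0.3)
    subjects$CSF_asyn <- pmax(1500 + cc$csfBurden * subjects$trueBurden +
                                rnorm(nSub, 0, cn$csf), 200)

    ann <- NULL
    if (annotations)
      ann <- lapply(specs, function(s) generateSlide(s, render = FALSE)@annotations)
    list(subjects = subjects, slides = slides,
         scores = slides[, c("slideId", "subjectId", "score")],
         slideSpecs = specs, annotations = ann)
  })
}

#' True object categories of an AnnotationSet
#'
#' Maps foreground ranks to `"definite"`/`"probable"`/`"possible"` and
#' background objects to `"background"`, the 4-way category set used in the
#' concordance study.
#'
#' @param annotations an [AnnotationSet-class].
#' @return character vector, one category per object.
#' @export
annotationCategories <- function(annotations) {
  df <- annotations@objects
  ifelse(df$class == "background", "background",
         names(.RANKS)[df$rank])
}

#' Simulate a multi-rater concordance study
#'
#' Each rater independently relabels every item according to a per-category
#' confusion matrix: given true category `t`, the assigned category is drawn
#' from `confusion[t, ]`. The identity matrix reproduces the truth for all
#' raters.
#'
#' @param truth character vector of true categories, or an
#'   [AnnotationSet-class] (categories via [annotationCategories()]).
#' @param nRaters number of raters (>= 2).
#' @param confusion square stochastic matrix with dimnames covering the true
#'   categories; rows must be probability vectors.
#' @param seed RNG seed.
#' @return A [RatingTable-class], items x raters.
#' @examples
#' conf <- diag(2); dimnames(conf) <- list(c("a","b"), c("a","b"))
#' simulateRaters(c("a","b","a"), 3, conf, seed = 1)
#' @export
simulateRaters <- function(truth, nRaters, confusion, seed = 1L) {
  if (is(truth, "AnnotationSet")) truth <- annotationCategories(truth)
  stopIfNot(length(truth) >= 2L, "need at least 2 items")
  stopIfNot(nRaters >= 2L, "need at least 2 raters")
  stopIfNot(is.matrix(confusion) && nrow(confusion) == ncol(confusion),
            "'confusion' must be a square matrix")
  if (any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion rows must be probability vectors", call. = FALSE)
  cats <- colnames(confusion)
  stopIfNot(!is.null(cats) && all(truth %in% rownames(confusion)),
            "'confusion' needs dimnames covering all true categories")
  n <- length(truth)
  withSeed(seed, {
    m <- matrix("", n, nRaters)
    for (r in seq_len(nRaters)) {
      for (ct in unique(truth)) {
        idx <- which(truth == ct)
        m[idx, r] <- cats[sample.int(length(cats), length(idx),
                                     replace = TRUE,
                                     prob = confusion[ct, ])]
      }
    }
    colnames(m) <- sprintf("rater%d", seq_len(nRaters))
    RatingTable(m, categories = cats)
  })
}
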