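## End-to-end orchestration: simulate -> detect -> features -> aggregate ->
## predict -> stats, writing every stage artifact under a run directory
## with a manifest sufficient to re-derive each output. All stage seeds
## derive deterministically from the single master seed, so a rerun with an
## identical config reproduces identical CSVs.

.requireField <- function(config, field) {
  if (is.null(config[[field]]))
    stop(sprintf("config field '%s' is required", field), call. = FALSE)
  config[[field]]
}

.pipelineDefaults <- function(config) {
  defaults <- list(
    detector = list(mode = "oracle", nNegatives = 25L, epochs = 100L,
                    learningRate = 0.01, threshold = 0.5),
    features = list(stain = FALSE),
    prediction = list(nRepeats = 200L, trainFrac = 0.8, l1Ratio = 0.01,
                      nStatusFeatures = 13L, nStageFeatures = 5L),
    writeAnnotations = FALSE)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in setdiff(names(defaults[[nm]]), names(config[[nm]])))
        config[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate, detect, features, aggregate, predict and
#' stats on a synthetic cohort, writing each stage's artifacts under
#' `config$outDir` and a `manifest.json` recording the configuration, the
#' derived stage seeds, the package version and the MD5 checksum of every
#' output. Rerunning with an identical config reproduces identical outputs.
#'
#' Config fields: `outDir` and `seed` (required; a missing seed is a
#' validation error); `cohort` (arguments of [cohortSpec()]); `detector`
#' (`mode = "oracle"` uses the ground-truth [annotationPatchGrid()];
#' `mode = "cnn"` renders slides, trains the reference classifier and runs
#' [inferSlide()] per slide — desk scale only); `features` (`stain`:
#' render + deconvolve each slide); `prediction` (`nRepeats`, `trainFrac`,
#' `l1Ratio`, `nStatusFeatures`, `nStageFeatures`);
#' `writeAnnotations` (GeoJSON per slide).
#'
#' @param config named list, or path to a YAML file of one.
#' @return invisibly, a list with the run artifacts (`features`,
#'   `subjects`, `selection`, `status`, `stage`, `stats`, `manifest`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outDir <- .requireField(config, "outDir")
  seed <- .requireField(config, "seed")
  config <- .pipelineDefaults(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stageSeeds <- childSeeds(seed, 4L)
  names(stageSeeds) <- c("cohort", "detector", "prediction", "stats")

  ## --- simulate ------------------------------------------------------------
  cohortArgs <- config$cohort
  cohortArgs$seed <- stageSeeds[["cohort"]]
  cspec <- do.call(cohortSpec, as.list(cohortArgs))
  cohort <- generateCohort(cspec)
  write.csv(cohort$subjects, file.path(outDir, "subjects.csv"),
            row.names = FALSE)
  write.csv(cohort$slides, file.path(outDir, "slides.csv"),
            row.names = FALSE)
  write.csv(cohort$scores, file.path(outDir, "scores.csv"),
            row.names = FALSE)
  if (isTRUE(config$writeAnnotations)) {
    annDir <- file.path(outDir, "annotations")
    dir.create(annDir, showWarnings = FALSE)
    for (i in seq_along(cohort$annotations))
      writeAnnotationsGeoJSON(cohort$annotations[[i]],
                              file.path(annDir,
                                        paste0(cohort$slides$slideId[i],
                                               ".geojson")))
  }

  ## --- detect + features ---------------------------------------------------
  det <- config$detector
  if (identical(det$mode, "cnn")) {
    model <- .pipelineTrainDetector(cohort, det, stageSeeds[["detector"]])
    feat <- .pipelineCnnFeatures(cohort, model, det,
                                 stain = isTRUE(config$features$stain))
  } else {
    feat <- cohortFeatureTable(cohort,
                               stain = isTRUE(config$features$stain))
  }
  write.csv(feat, file.path(outDir, "features.csv"), row.names = FALSE)

  ## --- aggregate -----------------------------------------------------------
  subj <- aggregateSubjects(feat)
  subj <- merge(cohort$subjects[, c("subjectId", "status", "stage")], subj,
                by = "subjectId", sort = TRUE)
  write.csv(subj, file.path(outDir, "subject_features.csv"),
            row.names = FALSE)

  ## --- predict -------------------------------------------------------------
  pr <- config$prediction
  Xfull <- completeFeatureMatrix(subj[, setdiff(names(subj),
                                                c("subjectId", "status",
                                                  "stage"))])
  sel <- repeatedLassoSelection(Xfull, subj$status,
                                nRepeats = pr$nRepeats,
                                trainFrac = pr$trainFrac,
                                seed = stageSeeds[["prediction"]])
  write.csv(sel, file.path(outDir, "selection_status.csv"),
            row.names = FALSE)
  topStatus <- head(sel$feature, pr$nStatusFeatures)
  status <- fitPredictElasticnet(Xfull[, topStatus, drop = FALSE],
                                 subj$status, l1Ratio = pr$l1Ratio,
                                 nRepeats = pr$nRepeats,
                                 trainFrac = pr$trainFrac,
                                 seed = stageSeeds[["prediction"]])
  write.csv(status$summary, file.path(outDir, "status_metrics.csv"),
            row.names = FALSE)
  if (min(table(subj$stage)) >= 2L) {
    selStage <- repeatedLassoSelection(Xfull, subj$stage,
                                       nRepeats = pr$nRepeats,
                                       trainFrac = pr$trainFrac,
                                       seed = stageSeeds[["prediction"]],
                                       family = "multinomial")
    topStage <- head(selStage$feature, pr$nStageFeatures)
  } else {
    ## micro-cohorts with singleton stages: reuse the status ranking
    message("stage classes too small for stage-specific selection; ",
            "reusing status-selected features")
    selStage <- sel
    topStage <- head(sel$feature, pr$nStageFeatures)
  }
  write.csv(selStage, file.path(outDir, "selection_stage.csv"),
            row.names = FALSE)
  pd <- subj$stage[subj$stage > 0]
  variants <- c("0-3", if (length(unique(pd)) >= 2L && length(pd) >= 3L)
    "1-3")
  stage <- predictStage(Xfull[, topStage, drop = FALSE], subj$stage,
                        variants = variants,
                        l1Ratio = pr$l1Ratio, nRepeats = pr$nRepeats,
                        trainFrac = pr$trainFrac,
                        seed = stageSeeds[["prediction"]])
  stageDf <- data.frame(variant = names(stage),
                        accuracyMean = vapply(stage, `[[`, numeric(1), "mean"),
                        accuracySd = vapply(stage, `[[`, numeric(1), "sd"),
                        n = vapply(stage, `[[`, numeric(1), "n"))
  write.csv(stageDf, file.path(outDir, "stage_metrics.csv"),
            row.names = FALSE)

  ## --- stats ---------------------------------------------------------------
  stats <- cohortStatTable(subj, subj$status, subj$stage,
                           features = topStatus)
  write.csv(stats, file.path(outDir, "stats.csv"), row.names = FALSE)

  ## --- manifest ------------------------------------------------------------
  outputs <- list.files(outDir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package = "LTSquant",
    version = as.character(utils::packageVersion("LTSquant")),
    seed = seed,
    stageSeeds = as.list(stageSeeds),
    config = config,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = feat, subjects = subj, selection = sel,
                 status = status, stage = stage, stats = stats,
                 manifest = manifest))
}

## Train the reference classifier on patches from the first few slides with
## both classes available.
.pipelineTrainDetector <- function(cohort, det, seed) {
  seeds <- childSeeds(seed, length(cohort$slideSpecs) + 1L)
  patches <- list()
  for (i in order(-cohort$slides$nForeground)[seq_len(min(4L,
                                             length(cohort$slideSpecs)))]) {
    sl <- generateSlide(cohort$slideSpecs[[i]])
    patches[[length(patches) + 1L]] <-
      extractPatches(sl@image, sl@annotations, nNegatives = det$nNegatives,
                     seed = seeds[i])
  }
  patches <- do.call(rbind, patches)
  trainPatchClassifier(patches,
                       trainConfig(learningRate = det$learningRate,
                                   epochs = det$epochs,
                                   seed = seeds[length(seeds)]))
}

.pipelineCnnFeatures <- function(cohort, model, det, stain = FALSE) {
  smodel <- hdabStainModel()
  n <- length(cohort$slideSpecs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sl <- generateSlide(cohort$slideSpecs[[i]])
    inf <- inferSlide(model, sl@image, threshold = det$threshold)
    channels <- NULL; tis <- NULL
    if (stain) {
      od <- odTransform(sl@image, smodel@background)
      channels <- deconvolveStains(od, smodel)
      tis <- sl@tissue
    }
    rows[[i]] <- slideFeatures(inf$grid, channels = channels, tissue = tis,
                               apSeed = cohort$slides$seed[i] %% 100000L)
  }
  feat <- do.call(rbind, rows)
  out <- cbind(cohort$slides[, c("slideId", "subjectId", "stage")],
               as.data.frame(feat))
  rownames(out) <- NULL
  out
}
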