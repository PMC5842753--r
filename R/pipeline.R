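#' @include classify.R io.R
NULL

#' Assemble a pipeline run configuration
#'
#' Returns the full configuration driving [runPipeline()], with every
#' default made explicit. Any field can be overridden through `...` using
#' nested lists, e.g. `runConfig(cohort = list(effectSize = 0.4))`. The
#' defaults describe the standard strong-effect study: 35 controls and
#' 20 + 20 patients, 60 one-second epochs at 250 Hz over the 14-region set,
#' outflow from the ipsilateral hub regions reduced by 80%.
#'
#' @param ... nested overrides (see Details in the vignette).
#' @param seed master seed; every stochastic stage derives its seed from
#'   it.
#' @return a validated configuration list of class `pdcnetConfig`.
#' @export
runConfig <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(nControl = 35L, nLtle = 20L, nRtle = 20L,
                  effectSize = 0.8, baseCoupling = 0.25, order = 2L,
                  nEpochs = 60L, epochSeconds = 1, fs = 250,
                  subjectJitterSd = NULL, obsNoiseSd = 0),
    connectivity = list(order = 5L, freqs = 1:30,
                        bands = list(theta = c(4, 8), alpha = c(8, 12),
                                     beta = c(12, 30))),
    selection = list(alpha = 0.05, nRepeats = 20L, sdFactor = 1,
                     cap = NULL),
    forest = list(nTrees = 1000L),
    interaction = list(nRepeats = 20L, impRepeats = 20L, enabled = TRUE))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown config section '%s'", nm))
    if (is.list(cfg[[nm]])) cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  with(cfg$cohort, {
    if (any(c(nControl, nLtle, nRtle) < 0)) stop("group sizes must be >= 0")
    if (nEpochs < 1 || fs <= 0 || epochSeconds <= 0)
      stop("invalid epoch layout")
  })
  bs <- do.call(bandSpec, cfg$connectivity$bands)  # validates bands
  stopifnot(is(bs, "BandSpec"))
  class(cfg) <- "pdcnetConfig"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [runConfig()] sections.
#' @param seed optional master-seed override.
#' @return a validated configuration list.
#' @export
readConfig <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  sd <- if (!is.null(raw$seed)) raw$seed else 1L
  raw$seed <- NULL
  do.call(runConfig, c(raw, list(seed = sd)))
}

# Table-3-style CSV: feature, importance (x 10^-2 scale), p-value
.writeSelectionCsv <- function(sel, path) {
  df <- data.frame(feature = selectedFeatures(sel),
                   importance_x100 = round(100 * sel@importances, 2),
                   p_value = signif(sel@mwwP, 3), row.names = NULL)
  write.csv(df, path, row.names = FALSE)
}

.reportAsList <- function(report) {
  m <- report@metrics
  list(metrics_percent = as.list(round(100 * m[c("accuracy", "sensitivity",
                                                 "specificity", "ppv",
                                                 "npv")], 1)),
       auc = round(unname(m["auc"]), 3),
       confusion = list(labels = rownames(report@confusion),
                        counts = unname(apply(report@confusion, 1, as.list))))
}

#' Run the full analysis pipeline
#'
#' Orchestrates one end-to-end study from a single configuration: simulate
#' the three-group cohort, estimate per-subject band-averaged wPDC
#' connectivity, build the 14-region feature table, run leave-one-out
#' cross-validation with per-fold feature selection for the diagnosis
#' (TLE vs CONTROL) and lateralization (LTLE vs RTLE) classifiers, compute
#' full-cohort selections and pairwise feature-interaction matrices, and
#' assemble the sequential three-class system with its confusion matrix.
#' All randomness derives from the master seed, so a re-run with the same
#' configuration reproduces every output exactly.
#'
#' @param config a `pdcnetConfig` from [runConfig()] / [readConfig()].
#' @param outdir optional directory; when given, all artifacts (cohort
#'   manifest, feature table, per-fold selections, selection and
#'   interaction CSVs, classifier reports, three-class confusion) are
#'   written there as plain text.
#' @param stages which stages to run: the full pipeline (default) or
#'   everything up to the feature table (`"features"`), e.g. for building
#'   fixtures.
#' @return a list with elements `cohort`, `features`, `diagLoocv`,
#'   `latLoocv`, `diagSelection`, `latSelection`, `diagInteraction`,
#'   `latInteraction`, `sequential` (per-subject three-class labels),
#'   `confusion` (3 x 3), `overallAccuracy`, `config`.
#' @export
runPipeline <- function(config = runConfig(), outdir = NULL,
                        stages = c("all", "features")) {
  stages <- match.arg(stages)
  stopifnot(inherits(config, "pdcnetConfig"))
  set.seed(config$seed)
  stageSeeds <- sample.int(.Machine$integer.max, 8L)

  co <- config$cohort
  cohort <- simulateCohort(
    nControl = co$nControl, nLtle = co$nLtle, nRtle = co$nRtle,
    templateParams = list(effectSize = co$effectSize,
                          baseCoupling = co$baseCoupling, order = co$order),
    nEpochs = co$nEpochs, epochSeconds = co$epochSeconds, fs = co$fs,
    subjectJitterSd = co$subjectJitterSd, obsNoiseSd = co$obsNoiseSd,
    seed = stageSeeds[1])

  bands <- do.call(bandSpec, config$connectivity$bands)
  features <- cohortFeatureTable(cohort, bands = bands,
                                 freqs = config$connectivity$freqs,
                                 order = config$connectivity$order)
  out <- list(cohort = cohort, features = features, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(cohortManifest(cohort),
                         file.path(outdir, "cohort_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeFeatureTable(features, file.path(outdir, "features.csv"))
  }
  if (stages == "features") return(out)

  labels <- classLabels(features)
  diagLabels <- ifelse(labels == "CONTROL", "CONTROL", "TLE")
  mat <- featureMatrix(features)
  selCfg <- config$selection
  nTrees <- config$forest$nTrees

  diagLoocv <- loocv(mat, diagLabels, spec = forestSpec(nTrees),
                     nRepeats = selCfg$nRepeats, alpha = selCfg$alpha,
                     cap = selCfg$cap, sdFactor = selCfg$sdFactor,
                     positiveClass = "TLE", seed = stageSeeds[2])

  pat <- labels != "CONTROL"
  latLoocv <- loocv(mat[pat, , drop = FALSE], labels[pat],
                    spec = forestSpec(nTrees), nRepeats = selCfg$nRepeats,
                    alpha = selCfg$alpha, cap = selCfg$cap,
                    sdFactor = selCfg$sdFactor, positiveClass = "LTLE",
                    seed = stageSeeds[3])

  # full-cohort selections (Table-3-style summaries + interaction input)
  diagSel <- selectFeatures(mat, diagLabels,
                            spec = forestSpec(nTrees, seed = stageSeeds[4]),
                            nRepeats = selCfg$nRepeats, alpha = selCfg$alpha,
                            cap = selCfg$cap, sdFactor = selCfg$sdFactor,
                            seed = stageSeeds[4])
  latSel <- selectFeatures(mat[pat, , drop = FALSE], labels[pat],
                           spec = forestSpec(nTrees, seed = stageSeeds[5]),
                           nRepeats = selCfg$nRepeats, alpha = selCfg$alpha,
                           cap = selCfg$cap, sdFactor = selCfg$sdFactor,
                           seed = stageSeeds[5])

  iCfg <- config$interaction
  diagInter <- latInter <- NULL
  if (isTRUE(iCfg$enabled)) {
    if (length(selectedFeatures(diagSel)) >= 2)
      diagInter <- interactionMatrix(
        mat[, selectedFeatures(diagSel), drop = FALSE], diagLabels,
        spec = forestSpec(nTrees, seed = stageSeeds[6]),
        nRepeats = iCfg$nRepeats, impRepeats = iCfg$impRepeats,
        seed = stageSeeds[6])
    if (length(selectedFeatures(latSel)) >= 2)
      latInter <- interactionMatrix(
        mat[pat, selectedFeatures(latSel), drop = FALSE], labels[pat],
        spec = forestSpec(nTrees, seed = stageSeeds[7]),
        nRepeats = iCfg$nRepeats, impRepeats = iCfg$impRepeats,
        seed = stageSeeds[7])
  }

  # sequential three-class system: per-subject diagnosis from the LOOCV
  # folds; lateralization from the LOOCV folds for patients, and from a
  # full-patient model for controls the diagnosis stage mislabels as TLE.
  diagPred <- as.character(diagLoocv@report@predicted)
  seqPred <- rep("CONTROL", length(labels))
  names(seqPred) <- rownames(mat)
  latByCohortIdx <- setNames(as.character(latLoocv@report@predicted),
                             latLoocv@subjectIds)
  tleIdx <- which(diagPred == "TLE")
  fullLatForest <- NULL
  for (i in tleIdx) {
    id <- rownames(mat)[i]
    if (pat[i]) {
      seqPred[i] <- latByCohortIdx[[id]]
    } else {
      if (is.null(fullLatForest))
        fullLatForest <- trainBalancedRF(
          mat[pat, selectedFeatures(latSel), drop = FALSE], labels[pat],
          forestSpec(nTrees, seed = stageSeeds[8]), positiveClass = "LTLE")
      seqPred[i] <- as.character(
        predictForest(fullLatForest,
                      mat[i, selectedFeatures(latSel), drop = FALSE])$predicted)
    }
  }
  conf3 <- threeClassConfusion(labels, seqPred)
  out <- c(out, list(diagLoocv = diagLoocv, latLoocv = latLoocv,
                     diagSelection = diagSel, latSelection = latSel,
                     diagInteraction = diagInter, latInteraction = latInter,
                     sequential = seqPred, confusion = conf3,
                     overallAccuracy = sum(diag(conf3)) / sum(conf3)))

  if (!is.null(outdir)) {
    .writeSelectionCsv(diagSel, file.path(outdir, "selection_diagnosis.csv"))
    .writeSelectionCsv(latSel, file.path(outdir, "selection_lateralization.csv"))
    if (!is.null(diagInter))
      writeInteractionMatrix(diagInter,
                             file.path(outdir, "interaction_diagnosis.csv"))
    if (!is.null(latInter))
      writeInteractionMatrix(latInter,
                             file.path(outdir, "interaction_lateralization.csv"))
    foldSel <- lapply(diagLoocv@foldSelections, selectedFeatures)
    jsonlite::write_json(
      list(diagnosis = foldSel,
           lateralization = lapply(latLoocv@foldSelections,
                                   selectedFeatures)),
      file.path(outdir, "fold_selections.json"), auto_unbox = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           diagnosis = .reportAsList(diagLoocv@report),
           lateralization = .reportAsList(latLoocv@report),
           overall_accuracy_percent = round(100 * out$overallAccuracy, 1)),
      file.path(outdir, "reports.json"), auto_unbox = TRUE, digits = NA)
    confDf <- data.frame(actual = rownames(conf3), conf3,
                         check.names = FALSE)
    write.csv(confDf, file.path(outdir, "confusion_three_class.csv"),
              row.names = FALSE)
  }
  out
}
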