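#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("roiNames", "MVARModel", function(object) object@roiNames)
#' @rdname accessors
setMethod("roiNames", "SubjectEpochs", function(object) object@roiNames)
#' @rdname accessors
setMethod("roiNames", "ConnectivityTensor", function(object) object@roiNames)

#' @rdname accessors
setMethod("groupLabel", "NetworkTemplate", function(object) object@groupLabel)
#' @rdname accessors
setMethod("groupLabel", "SubjectEpochs", function(object) object@groupLabel)

#' @rdname accessors
setMethod("samplingRate", "MVARModel", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "SubjectEpochs", function(object) object@fs)

#' @rdname accessors
setMethod("modelOrder", "MVARModel", function(object) dim(object@coeffs)[3])
#' @rdname accessors
setMethod("mvarCoefficients", "MVARModel", function(object) object@coeffs)
#' @rdname accessors
setMethod("noiseCovariance", "MVARModel", function(object) object@noiseCov)
#' @rdname accessors
setMethod("effectSpec", "NetworkTemplate", function(object) object@effectSpec)

#' @rdname accessors
setMethod("nEpochs", "SubjectEpochs", function(object) dim(object@epochs)[1])

#' @rdname accessors
setMethod("bandNames", "BandSpec", function(object) object@labels)
#' @rdname accessors
setMethod("bandNames", "ConnectivityTensor", function(object) {
  if (object@axisKind != "bands") stop("tensor is on a frequency grid, not bands")
  object@bands@labels
})

#' @rdname accessors
setMethod("connValues", "ConnectivityTensor", function(object) object@values)

#' @rdname accessors
setMethod("subjectIds", "EpochCohort", function(object)
  vapply(object@subjects, function(s) s@subjectId, character(1)))
#' @rdname accessors
setMethod("subjectIds", "ConnectivityFeatures", function(object) colnames(object))

#' @rdname accessors
setMethod("classLabels", "EpochCohort", function(object)
  vapply(object@subjects, function(s) s@groupLabel, character(1)))
#' @rdname accessors
setMethod("classLabels", "ConnectivityFeatures", function(object)
  as.character(SummarizedExperiment::colData(object)$label))

#' @rdname accessors
setMethod("featureNames", "ConnectivityFeatures", function(object) rownames(object))
#' @rdname accessors
setMethod("featureNames", "ImportanceReport", function(object) object@featureNames)

#' @rdname accessors
setMethod("featureMatrix", "ConnectivityFeatures", function(object)
  t(SummarizedExperiment::assay(object, "conn")))

#' @rdname accessors
setMethod("selectedFeatures", "SelectionResult", function(object) object@selected)

#' @rdname accessors
setMethod("importanceValues", "ImportanceReport", function(object)
  setNames(object@meanImportance, object@featureNames))
#' @rdname accessors
setMethod("importanceValues", "SelectionResult", function(object) object@importances)

#' @rdname accessors
setMethod("effectsMatrix", "InteractionMatrix", function(object) object@effects)

#' @rdname accessors
setMethod("metricTable", "ClassifierReport", function(object) {
  m <- object@metrics
  data.frame(
    measure = c("Accuracy (%)", "Sensitivity (%)", "Specificity (%)",
                "Positive predictive val. (%)", "Negative predictive val. (%)",
                "AUC"),
    value = c(round(100 * m[c("accuracy", "sensitivity", "specificity",
                              "ppv", "npv")], 1),
              round(m["auc"], 3)),
    row.names = NULL)
})

#' @rdname accessors
setMethod("confusionCounts", "ClassifierReport", function(object) object@confusion)

#' Subjects in a cohort
#'
#' @param x an [EpochCohort-class].
#' @return the list of [SubjectEpochs-class] objects.
#' @export
cohortSubjects <- function(x) {
  stopifnot(is(x, "EpochCohort"))
  x@subjects
}

#' Cohort manifest
#'
#' @param x an [EpochCohort-class].
#' @return the manifest list (group labels, seeds, generator parameters).
#' @export
cohortManifest <- function(x) {
  stopifnot(is(x, "EpochCohort"))
  x@manifest
}

setMethod("show", "MVARModel", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("%s: %d channels, order %d, fs %g Hz\n",
              class(object), d[1], d[3], object@fs))
  if (is(object, "NetworkTemplate"))
    cat(sprintf("  group %s, %d planted edge modification(s)\n",
                object@groupLabel, nrow(object@effectSpec)))
})

setMethod("show", "SubjectEpochs", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("SubjectEpochs %s (%s): %d epochs x %d ROIs x %d samples @ %g Hz\n",
              object@subjectId, object@groupLabel, d[1], d[2], d[3], object@fs))
})

setMethod("show", "EpochCohort", function(object) {
  tab <- table(factor(classLabels(object), levels = GROUP_LEVELS))
  cat(sprintf("EpochCohort: %d subjects (%s)\n", length(object@subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ConnectivityTensor", function(object) {
  d <- dim(object@values)
  ax <- if (object@axisKind == "bands")
    paste(object@bands@labels, collapse = "/") else
    sprintf("%d frequencies", d[3])
  cat(sprintf("ConnectivityTensor: %d x %d ROIs x %s\n", d[1], d[2], ax))
})

setMethod("show", "ImportanceReport", function(object) {
  cat(sprintf("ImportanceReport: %d features, %d repeats, OOB accuracy %.3f\n",
              length(object@featureNames), object@nRepeats, object@baseAcc))
  cat(sprintf("  %d significant at alpha = %g\n",
              sum(object@significant), object@alpha))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d feature(s) selected (cap %d)\n",
              length(object@selected), object@cap))
  if (length(object@selected)) {
    df <- data.frame(feature = object@selected,
                     importance.1e2 = round(100 * object@importances, 2),
                     p.value = signif(object@mwwP, 3), row.names = NULL)
    print(df)
  }
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(sprintf("InteractionMatrix: %d x %d\n",
              nrow(object@effects), ncol(object@effects)))
  print(round(object@effects, 4))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport (positive class: %s)\n", object@positiveClass))
  print(metricTable(object))
  cat("Confusion (actual x predicted):\n")
  print(object@confusion)
})

setMethod("show", "LoocvResult", function(object) {
  cat(sprintf("LoocvResult: %d folds\n", length(object@subjectIds)))
  show(object@report)
})
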