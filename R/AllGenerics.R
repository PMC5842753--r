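#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: `roiNames()` returns
#' channel labels, `groupLabel()` the group of a template or subject,
#' `samplingRate()` the sampling rate in Hz, `modelOrder()` the MVAR lag
#' count, `mvarCoefficients()` the lag coefficient array,
#' `noiseCovariance()` the innovation covariance, `effectSpec()` the planted
#' edge table of a template, `nEpochs()` the epoch count, `bandNames()` band
#' labels, `connValues()` the raw connectivity array, `subjectIds()` subject
#' identifiers, `classLabels()` per-subject labels, `featureNames()` feature
#' identifiers, `featureMatrix()` a subjects x features matrix,
#' `selectedFeatures()` the chosen feature set, `importanceValues()`
#' per-feature importances, `effectsMatrix()` the pairwise interaction
#' matrix, `metricTable()` the rounded percentage metric panel and
#' `confusionCounts()` the actual x predicted count matrix.
#'
#' @param object an object of the documented class.
#' @return the accessed component (see description).
#' @name accessors
#' @aliases roiNames groupLabel samplingRate modelOrder mvarCoefficients
#'   noiseCovariance effectSpec nEpochs bandNames connValues subjectIds
#'   classLabels featureNames featureMatrix selectedFeatures
#'   importanceValues effectsMatrix metricTable confusionCounts
NULL

#' @rdname accessors
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))
#' @rdname accessors
#' @export
setGeneric("mvarCoefficients", function(object) standardGeneric("mvarCoefficients"))
#' @rdname accessors
#' @export
setGeneric("noiseCovariance", function(object) standardGeneric("noiseCovariance"))
#' @rdname accessors
#' @export
setGeneric("effectSpec", function(object) standardGeneric("effectSpec"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("bandNames", function(object) standardGeneric("bandNames"))
#' @rdname accessors
#' @export
setGeneric("connValues", function(object) standardGeneric("connValues"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("importanceValues", function(object) standardGeneric("importanceValues"))
#' @rdname accessors
#' @export
setGeneric("effectsMatrix", function(object) standardGeneric("effectsMatrix"))
#' @rdname accessors
#' @export
setGeneric("metricTable", function(object) standardGeneric("metricTable"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))
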