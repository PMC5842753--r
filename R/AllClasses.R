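#' @include pdcnet-package.R
NULL

GROUP_LEVELS <- c("CONTROL", "LTLE", "RTLE")

#' Frequency band specification
#'
#' Named closed-open frequency intervals in Hz. The default bands are
#' theta \[4, 8), alpha \[8, 12) and beta \[12, 30); a grid frequency belongs
#' to exactly one band because shared edges are assigned to the upper band.
#'
#' @slot labels band names, ordered.
#' @slot lower,upper interval bounds in Hz; intervals are \[lower, upper).
#' @export
setClass("BandSpec",
  representation(labels = "character", lower = "numeric", upper = "numeric"))

setValidity("BandSpec", function(object) {
  n <- length(object@labels)
  if (length(object@lower) != n || length(object@upper) != n)
    return("labels, lower and upper must have equal length")
  if (anyDuplicated(object@labels)) return("duplicate band labels")
  if (any(object@lower >= object@upper)) return("need lower < upper for every band")
  if (n > 1) {
    o <- order(object@lower)
    if (any(object@upper[o][-n] > object@lower[o][-1] + 1e-12))
      return("bands overlap")
  }
  TRUE
})

#' Multivariate autoregressive model
#'
#' An order-p MVAR process over R channels:
#' x_t = sum_r A_r x_{t-r} + e_t, with e_t ~ N(0, noiseCov).
#' Entry \code{coeffs[i, j, r]} is the influence of channel j at lag r on
#' channel i.
#'
#' @slot coeffs R x R x p array of lag coefficient matrices.
#' @slot noiseCov R x R innovation covariance.
#' @slot fs sampling rate in Hz.
#' @slot roiNames channel labels, length R.
#' @export
setClass("MVARModel",
  representation(coeffs = "array", noiseCov = "matrix", fs = "numeric",
                 roiNames = "character"))

setValidity("MVARModel", function(object) {
  d <- dim(object@coeffs)
  if (length(d) != 3 || d[1] != d[2]) return("coeffs must be an R x R x p array")
  if (d[3] < 1) return("order must be >= 1")
  if (!all(is.finite(object@coeffs))) return("coefficients must be finite")
  if (!isTRUE(all.equal(object@noiseCov, t(object@noiseCov), tolerance = 1e-8)))
    return("noiseCov must be symmetric")
  if (length(object@roiNames) != d[1]) return("roiNames length must equal R")
  if (length(object@fs) != 1 || object@fs <= 0) return("fs must be a positive scalar")
  TRUE
})

#' Group network template
#'
#' A stable MVAR generator for one subject group, together with the planted
#' edge modifications (\code{effectSpec}) that distinguish the group from the
#' control network. \code{effectSpec} has columns sender, receiver, lag and
#' delta (additive change applied to the control coefficient).
#'
#' @slot groupLabel one of CONTROL, LTLE, RTLE.
#' @slot effectSpec data.frame of planted edge modifications.
#' @slot baseCoupling base inter-regional coupling strength.
#' @export
setClass("NetworkTemplate", contains = "MVARModel",
  representation(groupLabel = "character", effectSpec = "data.frame",
                 baseCoupling = "numeric"))

setValidity("NetworkTemplate", function(object) {
  if (!object@groupLabel %in% GROUP_LEVELS)
    return(sprintf("groupLabel must be one of %s", paste(GROUP_LEVELS, collapse = ", ")))
  es <- object@effectSpec
  need <- c("sender", "receiver", "lag", "delta")
  if (!all(need %in% names(es))) return("effectSpec needs sender/receiver/lag/delta")
  if (nrow(es) > 0 &&
      !all(c(es$sender, es$receiver) %in% object@roiNames))
    return("effectSpec sender/receiver must be valid ROI names")
  if (.companionRadius(object@coeffs) >= 1)
    return("template process is not stable (spectral radius >= 1)")
  TRUE
})

#' Epoch-segmented subject recording
#'
#' One subject's ROI time series, segmented into epochs of equal length.
#'
#' @slot subjectId subject identifier.
#' @slot groupLabel group membership.
#' @slot fs sampling rate in Hz.
#' @slot roiNames channel labels.
#' @slot epochs nEpochs x R x nSamples array.
#' @export
setClass("SubjectEpochs",
  representation(subjectId = "character", groupLabel = "character",
                 fs = "numeric", roiNames = "character", epochs = "array"))

setValidity("SubjectEpochs", function(object) {
  d <- dim(object@epochs)
  if (length(d) != 3) return("epochs must be an nEpochs x R x nSamples array")
  if (d[2] != length(object@roiNames)) return("second dimension must match roiNames")
  if (!all(is.finite(object@epochs))) return("epoch values must be finite")
  if (!object@groupLabel %in% GROUP_LEVELS) return("invalid groupLabel")
  TRUE
})

#' Simulated cohort
#'
#' A list of [SubjectEpochs-class] objects plus a manifest recording all
#' generator parameters and seeds needed for exact reproduction.
#'
#' @slot subjects list of SubjectEpochs.
#' @slot manifest named list of generator metadata.
#' @export
setClass("EpochCohort",
  representation(subjects = "list", manifest = "list"))

setValidity("EpochCohort", function(object) {
  if (!all(vapply(object@subjects, is, logical(1), class2 = "SubjectEpochs")))
    return("all cohort elements must be SubjectEpochs")
  ids <- vapply(object@subjects, function(s) s@subjectId, character(1))
  if (anyDuplicated(ids)) return("duplicate subject ids")
  TRUE
})

#' Directed connectivity tensor
#'
#' Nonnegative directed connectivity values; entry \code{values[i, j, k]} is
#' the connectivity from sender j to receiver i at the k-th frequency (when
#' \code{axisKind == "frequency_grid"}) or band (\code{axisKind == "bands"}).
#'
#' @slot values R x R x F array, finite and nonnegative.
#' @slot axisKind "frequency_grid" or "bands".
#' @slot freqs frequency grid in Hz (frequency_grid tensors).
#' @slot bands [BandSpec-class] (band tensors).
#' @slot roiNames channel labels.
#' @export
setClass("ConnectivityTensor",
  representation(values = "array", axisKind = "character", freqs = "numeric",
                 bands = "ANY", roiNames = "character"))

setValidity("ConnectivityTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3 || d[1] != d[2]) return("values must be R x R x F")
  if (!all(is.finite(object@values)) || any(object@values < -1e-12))
    return("connectivity values must be finite and nonnegative")
  if (!object@axisKind %in% c("frequency_grid", "bands"))
    return("axisKind must be 'frequency_grid' or 'bands'")
  if (object@axisKind == "frequency_grid" && length(object@freqs) != d[3])
    return("freqs length must match third dimension")
  if (object@axisKind == "bands") {
    if (!is(object@bands, "BandSpec")) return("bands must be a BandSpec")
    if (length(object@bands@labels) != d[3])
      return("number of bands must match third dimension")
  }
  if (length(object@roiNames) != d[1]) return("roiNames must have length R")
  TRUE
})

#' Subjects-by-features connectivity table
#'
#' A [SummarizedExperiment-class] with features as rows (one per directed
#' band-specific connection, rowData columns band/sender/receiver) and
#' subjects as columns (colData column \code{label}). The single assay
#' \code{"conn"} holds wPDC band means.
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("ConnectivityFeatures", contains = "SummarizedExperiment")

setValidity("ConnectivityFeatures", function(object) {
  if (!"conn" %in% SummarizedExperiment::assayNames(object))
    return("assay 'conn' is required")
  if (!"label" %in% names(SummarizedExperiment::colData(object)))
    return("colData column 'label' is required")
  if (anyDuplicated(rownames(object))) return("duplicate feature names")
  if (!all(is.finite(SummarizedExperiment::assay(object, "conn"))))
    return("feature values must be finite")
  TRUE
})

#' Balanced random forest specification
#'
#' @slot nTrees number of trees (default 1000).
#' @slot seed RNG seed for bootstraps and split sampling.
#'
#' Each tree is grown on a balanced with-replacement bootstrap holding an
#' equal number of subjects from both classes (the minority class count from
#' each); splits are chosen among floor(log2(M)) randomly drawn features,
#' where M is the number of features in the table.
#' @export
setClass("BalancedForestSpec",
  representation(nTrees = "integer", seed = "integer"))

setValidity("BalancedForestSpec", function(object) {
  if (object@nTrees < 1L) return("nTrees must be >= 1")
  TRUE
})

#' Trained balanced random forest
#'
#' @slot fit underlying ranger fit.
#' @slot flat flattened tree arrays used by the C++ traversal kernel.
#' @slot x training feature matrix (subjects x features).
#' @slot y training labels.
#' @slot inbag per-tree bootstrap counts (subjects x trees).
#' @slot spec the [BalancedForestSpec-class] used.
#' @slot positiveClass label treated as positive for votes and metrics.
#' @export
setClass("BalancedForest",
  representation(fit = "ANY", flat = "list", x = "matrix", y = "factor",
                 inbag = "matrix", spec = "BalancedForestSpec",
                 positiveClass = "character"))

#' Permutation importance report
#'
#' Per-feature mean decrease in out-of-bag accuracy when the feature's values
#' are permuted, with spread across permutation repeats and a significance
#' flag.
#'
#' @slot featureNames feature names.
#' @slot meanImportance mean OOB accuracy drop over repeats.
#' @slot importanceSD standard deviation over repeats.
#' @slot pValue one-sided p-value that the importance exceeds zero.
#' @slot significant logical flag at level alpha.
#' @slot alpha significance level used.
#' @slot nRepeats number of permutation repeats.
#' @slot baseAcc baseline out-of-bag accuracy of the forest.
#' @slot repeats feature x repeat matrix of raw accuracy drops.
#' @export
setClass("ImportanceReport",
  representation(featureNames = "character", meanImportance = "numeric",
                 importanceSD = "numeric", pValue = "numeric",
                 significant = "logical", alpha = "numeric",
                 nRepeats = "integer", baseAcc = "numeric",
                 repeats = "matrix"))

setValidity("ImportanceReport", function(object) {
  if (any(object@importanceSD < 0)) return("importanceSD must be >= 0")
  if (any(object@significant & object@meanImportance <= 0))
    return("significant features must have positive importance")
  TRUE
})

#' Feature selection result
#'
#' @slot selected selected feature names, most to least important.
#' @slot importances named importances of the selected features.
#' @slot mwwP named two-sided Mann-Whitney-Wilcoxon p-values.
#' @slot cap maximum number of features allowed (one per ten subjects).
#' @slot trace data.frame of candidate subset sizes and their OOB errors.
#' @export
setClass("SelectionResult",
  representation(selected = "character", importances = "numeric",
                 mwwP = "numeric", cap = "integer", trace = "data.frame"))

setValidity("SelectionResult", function(object) {
  if (length(object@selected) > object@cap) return("more features than cap")
  imp <- object@importances
  if (length(imp) > 1 && any(diff(imp) > 1e-12))
    return("selected features must be ordered by descending importance")
  TRUE
})

#' Pairwise feature interaction matrix
#'
#' Entry (r, c) is the change in permutation importance of feature c when
#' feature r is removed from the design by permuting its values (negative =
#' c loses relevance without r). The diagonal is fixed at 0.
#'
#' @slot effects square interaction matrix, features x features.
#' @slot baseline baseline importances of the features.
#' @slot permSD permutation-repeat standard deviation of the baseline
#'   importances.
#' @slot effectSD per-entry standard deviation of the re-measured
#'   importances across the removal permutations (noise scale for deciding
#'   whether an interaction entry differs from zero).
#' @export
setClass("InteractionMatrix",
  representation(effects = "matrix", baseline = "numeric",
                 permSD = "numeric", effectSD = "matrix"))

setValidity("InteractionMatrix", function(object) {
  e <- object@effects
  if (nrow(e) != ncol(e)) return("effects must be square")
  if (any(abs(diag(e)) > 1e-12)) return("diagonal must be zero")
  if (!all(is.finite(e))) return("effects must be finite")
  TRUE
})

#' Two-class classifier evaluation report
#'
#' Holds per-subject predictions and vote-fraction scores plus the standard
#' diagnostic metric panel. Metrics are stored at full precision as
#' fractions; [metricTable()] renders them as percentages rounded to one
#' decimal.
#'
#' @slot actual,predicted factors over the two class labels.
#' @slot scores positive-class vote fraction per subject.
#' @slot positiveClass the positive class label.
#' @slot metrics named fractions: accuracy, sensitivity, specificity, ppv,
#'   npv, auc.
#' @slot confusion actual x predicted count matrix.
#' @export
setClass("ClassifierReport",
  representation(actual = "factor", predicted = "factor", scores = "numeric",
                 positiveClass = "character", metrics = "numeric",
                 confusion = "matrix"))

setValidity("ClassifierReport", function(object) {
  cm <- object@confusion
  if (sum(cm) != length(object@actual)) return("confusion counts must sum to n")
  if (!all(rowSums(cm) == as.vector(table(object@actual)[rownames(cm)])))
    return("confusion rows must sum to actual class counts")
  if (!is.na(object@metrics["auc"]) &&
      (object@metrics["auc"] < 0 || object@metrics["auc"] > 1))
    return("auc must lie in [0, 1]")
  TRUE
})

#' Leave-one-out cross-validation result
#'
#' @slot report pooled [ClassifierReport-class] over all folds.
#' @slot foldSelections per-fold [SelectionResult-class] objects, named by
#'   the held-out subject.
#' @slot subjectIds held-out subject order.
#' @export
setClass("LoocvResult",
  representation(report = "ClassifierReport", foldSelections = "list",
                 subjectIds = "character"))
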