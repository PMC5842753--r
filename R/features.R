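#' @include pdc.R
NULL

#' Flatten a band connectivity tensor into a named feature vector
#'
#' Emits one value per ordered (sender, receiver) pair within the requested
#' ROI subset -- self-pairs included -- per band, so a subset of size S with
#' B bands yields S^2 x B features. Names follow
#' \code{"band:SENDER->RECEIVER"} and are ordered band-major, then sender,
#' then receiver (in the order of `rois`), which makes the name-to-index map
#' deterministic and locale-independent.
#'
#' @param tensor a band-axis [ConnectivityTensor-class].
#' @param rois ROI subset (default: all ROIs of the tensor).
#' @return a named numeric vector of connectivity features.
#' @export
flattenConnectivity <- function(tensor, rois = NULL) {
  stopifnot(is(tensor, "ConnectivityTensor"))
  if (tensor@axisKind != "bands")
    stop("flattening expects a band-axis tensor")
  if (is.null(rois)) rois <- tensor@roiNames
  idx <- match(rois, tensor@roiNames)
  if (anyNA(idx))
    stop(sprintf("unknown ROI name(s): %s",
                 paste(rois[is.na(idx)], collapse = ", ")))
  bands <- tensor@bands@labels
  S <- length(rois)
  grid <- expand.grid(receiver = seq_len(S), sender = seq_len(S),
                      band = seq_along(bands))
  vals <- tensor@values[cbind(idx[grid$receiver], idx[grid$sender], grid$band)]
  names(vals) <- paste0(bands[grid$band], ":", rois[grid$sender], "->",
                        rois[grid$receiver])
  vals
}

#' Build a subjects-by-features connectivity table
#'
#' Flattens one band tensor per subject (restricted to `rois`) and assembles
#' a [ConnectivityFeatures-class] table (a SummarizedExperiment with
#' features as rows and subjects as columns). All tensors must share ROI
#' names and band definitions.
#'
#' @param tensors named list of band-axis [ConnectivityTensor-class]
#'   objects, one per subject (names = subject ids).
#' @param labels per-subject class labels, same length/order as `tensors`.
#' @param rois ROI subset (default [defaultRoiNames()] intersected with the
#'   tensors' ROIs; pass the tensors' full ROI set for no restriction).
#' @return a [ConnectivityFeatures-class].
#' @export
buildFeatureTable <- function(tensors, labels, rois = NULL) {
  if (length(tensors) == 0) stop("no tensors supplied")
  if (length(labels) != length(tensors))
    stop("labels must match the number of subjects")
  ids <- names(tensors)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(tensors))
  ref <- tensors[[1]]
  for (i in seq_along(tensors)) {
    t_i <- tensors[[i]]
    if (!identical(t_i@roiNames, ref@roiNames) ||
        !identical(dim(t_i@values), dim(ref@values)) ||
        !identical(t_i@bands@labels, ref@bands@labels))
      stop(sprintf("tensor shape mismatch between subjects %s and %s",
                   ids[1], ids[i]))
  }
  if (is.null(rois)) {
    rois <- intersect(defaultRoiNames(), ref@roiNames)
    if (length(rois) == 0) rois <- ref@roiNames
  }
  rows <- lapply(tensors, flattenConnectivity, rois = rois)
  mat <- do.call(cbind, rows)           # features x subjects
  colnames(mat) <- ids
  featNames <- names(rows[[1]])
  rownames(mat) <- featNames
  parts <- do.call(rbind, strsplit(featNames, ":|->"))
  rowData <- S4Vectors::DataFrame(band = parts[, 1], sender = parts[, 2],
                                  receiver = parts[, 3])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(conn = mat), rowData = rowData,
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   row.names = ids))
  new("ConnectivityFeatures", se)
}

#' Build the feature table straight from a cohort
#'
#' Convenience wrapper: runs [subjectConnectivity()] for every subject and
#' assembles the table with [buildFeatureTable()].
#'
#' @param cohort an [EpochCohort-class].
#' @param rois ROI subset (see [buildFeatureTable()]).
#' @param ... passed to [subjectConnectivity()].
#' @return a [ConnectivityFeatures-class].
#' @export
cohortFeatureTable <- function(cohort, rois = NULL, ...) {
  stopifnot(is(cohort, "EpochCohort"))
  tensors <- lapply(cohort@subjects, subjectConnectivity, ...)
  names(tensors) <- subjectIds(cohort)
  buildFeatureTable(tensors, labels = classLabels(cohort), rois = rois)
}

#' Construct a feature table from a plain matrix
#'
#' Mostly used in tests and examples: wraps a subjects x features matrix
#' into the same container [buildFeatureTable()] produces.
#'
#' @param x subjects x features numeric matrix with dimnames.
#' @param labels per-subject class labels.
#' @return a [ConnectivityFeatures-class].
#' @export
featureTableFromMatrix <- function(x, labels) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(conn = t(x)),
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   row.names = rownames(x)))
  new("ConnectivityFeatures", se)
}
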