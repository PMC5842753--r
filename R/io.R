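#' @include cohort.R features.R
NULL

#' Write / read a cohort as delimited text plus a JSON manifest
#'
#' `writeCohort()` stores one CSV per subject (column `epoch`, then one
#' column per ROI; rows are samples, epochs stacked) and a
#' `manifest.json` holding group labels, file paths, epoch layout and every
#' generator seed, so the cohort can be reloaded (`readCohort()`) or
#' re-simulated ([reproduceCohort()]) exactly.
#'
#' @param cohort an [EpochCohort-class].
#' @param dir output directory (created if missing).
#' @return `writeCohort()` the directory path, invisibly; `readCohort()` an
#'   [EpochCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "EpochCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort@subjects))
  for (i in seq_along(cohort@subjects)) {
    s <- cohort@subjects[[i]]
    d <- dim(s@epochs)
    # samples x ROIs with epoch index, epochs stacked; %.17g keeps the
    # round trip lossless
    flat <- do.call(rbind, lapply(seq_len(d[1]), function(ep)
      cbind(ep, t(matrix(s@epochs[ep, , ], d[2], d[3])))))
    files[i] <- paste0(s@subjectId, ".csv")
    con <- file(file.path(dir, files[i]), "w")
    writeLines(paste(c("epoch", s@roiNames), collapse = ","), con)
    writeLines(paste(sprintf("%d", flat[, 1]),
                     apply(flat[, -1, drop = FALSE], 1, function(v)
                       paste(sprintf("%.17g", v), collapse = ",")),
                     sep = ","), con)
    close(con)
  }
  manifest <- cohort@manifest
  manifest$files <- files
  manifest$roiNames <- if (length(cohort@subjects))
    cohort@subjects[[1]]@roiNames else character(0)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ids <- manifest$subjectIds
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    df <- read.csv(file.path(dir, manifest$files[i]), check.names = FALSE)
    epIdx <- df$epoch
    rois <- setdiff(colnames(df), "epoch")
    nEp <- max(epIdx)
    nSamples <- sum(epIdx == 1L)
    epochs <- array(0, c(nEp, length(rois), nSamples))
    m <- as.matrix(df[, rois, drop = FALSE])
    for (ep in seq_len(nEp))
      epochs[ep, , ] <- t(m[epIdx == ep, , drop = FALSE])
    subjects[[i]] <- new("SubjectEpochs", subjectId = ids[i],
                         groupLabel = manifest$groups[i], fs = manifest$fs,
                         roiNames = rois, epochs = epochs)
  }
  keep <- setdiff(names(manifest), c("files", "roiNames"))
  new("EpochCohort", subjects = subjects, manifest = manifest[keep])
}

#' Write / read a connectivity tensor as long-format CSV
#'
#' Columns: sender, receiver, band (or freq), value.
#'
#' @param tensor a [ConnectivityTensor-class].
#' @param path CSV path.
#' @return `writeConnectivity()` the path, invisibly; `readConnectivity()`
#'   is not provided (tensors are cheap to recompute); use the CSV for
#'   inspection and plotting.
#' @export
writeConnectivity <- function(tensor, path) {
  stopifnot(is(tensor, "ConnectivityTensor"))
  R <- length(tensor@roiNames)
  axis <- if (tensor@axisKind == "bands") tensor@bands@labels
          else tensor@freqs
  grid <- expand.grid(receiver = seq_len(R), sender = seq_len(R),
                      axis = seq_along(axis))
  df <- data.frame(sender = tensor@roiNames[grid$sender],
                   receiver = tensor@roiNames[grid$receiver],
                   band_or_freq = axis[grid$axis],
                   value = tensor@values[cbind(grid$receiver, grid$sender,
                                               grid$axis)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature table as CSV
#'
#' First column `subject_id`, second `label`, then one column per feature
#' (arrows rendered as `->`). The round trip through
#' `readFeatureTable(writeFeatureTable(x))` is lossless.
#'
#' @param table a [ConnectivityFeatures-class].
#' @param path CSV path.
#' @return `writeFeatureTable()` the path invisibly; `readFeatureTable()` a
#'   [ConnectivityFeatures-class].
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "ConnectivityFeatures"))
  mat <- featureMatrix(table)
  df <- data.frame(subject_id = rownames(mat), label = classLabels(table),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  # full precision round trip
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("subject_id", "label", colnames(mat)), collapse = ","), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(c(df$subject_id[i], df$label[i],
                       sprintf("%.17g", as.numeric(mat[i, ]))), collapse = ","),
               con)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(mat) <- df$subject_id
  featureTableFromMatrix(mat, labels = df$label)
}
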