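#' @include interaction.R
NULL

#' Diagnostic metric panel for two-class predictions
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value (stored as fractions; rendered as percentages rounded
#' to one decimal by [metricTable()]) and the area under the ROC curve of
#' the continuous scores via the rank (Mann-Whitney) statistic with
#' midranks for ties.
#'
#' @param actual true labels.
#' @param predicted predicted labels.
#' @param scores positive-class score per subject (e.g. vote fraction).
#' @param positiveClass label treated as positive.
#' @return a [ClassifierReport-class].
#' @examples
#' act <- rep(c("TLE", "CONTROL"), c(40, 35))
#' prd <- c(rep("TLE", 38), rep("CONTROL", 2), rep("TLE", 5), rep("CONTROL", 30))
#' sc <- ifelse(prd == "TLE", 0.9, 0.1)
#' metricTable(metricPanel(act, prd, sc, "TLE"))
#' @export
metricPanel <- function(actual, predicted, scores, positiveClass) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted) ||
      length(actual) != length(scores))
    stop("actual, predicted and scores must have equal length")
  classes <- sort(unique(c(actual, predicted)))
  if (!positiveClass %in% classes) stop("positiveClass not present")
  if (length(classes) > 2) stop("metricPanel is two-class only")
  negativeClass <- setdiff(classes, positiveClass)
  if (length(negativeClass) == 0)
    stop("only one class present; metrics undefined")
  lev <- c(positiveClass, negativeClass)
  af <- factor(actual, levels = lev); pf <- factor(predicted, levels = lev)
  conf <- table(actual = af, predicted = pf)
  conf <- matrix(conf, 2, 2, dimnames = dimnames(conf))
  TP <- conf[1, 1]; FN <- conf[1, 2]; FP <- conf[2, 1]; TN <- conf[2, 2]
  if (TP + FN == 0 || TN + FP == 0)
    stop("a class is absent from the actual labels; metrics undefined")
  isPos <- actual == positiveClass
  r <- rank(scores)
  n1 <- sum(isPos); n0 <- sum(!isPos)
  auc <- (sum(r[isPos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  metrics <- c(accuracy = (TP + TN) / sum(conf),
               sensitivity = TP / (TP + FN),
               specificity = TN / (TN + FP),
               ppv = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
               npv = if (TN + FN > 0) TN / (TN + FN) else NA_real_,
               auc = auc)
  new("ClassifierReport", actual = af, predicted = pf,
      scores = as.numeric(scores), positiveClass = positiveClass,
      metrics = metrics, confusion = conf)
}

#' Leave-one-out cross-validation with per-fold feature selection
#'
#' Every subject is held out once; the full selection pipeline
#' ([selectFeatures()]: permutation-importance screening, then minimal
#' subset) runs on the remaining subjects only, a balanced forest is
#' trained on the selected features, and the held-out subject is predicted.
#' The held-out subject never influences its own fold's selection or
#' training. Per-fold selections are recorded; they may differ across folds
#' because of the intrinsic randomness of the procedure.
#'
#' @param x a [ConnectivityFeatures-class] or subjects x features matrix.
#' @param labels two-class labels.
#' @param spec a [BalancedForestSpec-class].
#' @param nRepeats permutation repeats for screening importances.
#' @param alpha screening significance level.
#' @param cap maximum selected features per fold; default one per ten
#'   cohort subjects ([selectionCap()] of the full cohort size).
#' @param sdFactor one-standard-error rule width for [minimalSubset()].
#' @param positiveClass label treated as positive.
#' @param seed master seed; per-fold seeds are derived from it.
#' @return a [LoocvResult-class].
#' @export
loocv <- function(x, labels = NULL, spec = forestSpec(), nRepeats = 50L,
                  alpha = 0.05, cap = NULL, sdFactor = 1,
                  positiveClass = NULL, seed = spec@seed) {
  d <- .asXY(x, labels)
  n <- nrow(d$x)
  if (n < 3) stop("LOOCV needs at least 3 subjects")
  if (min(table(d$y)) < 2) stop("both classes need at least 2 subjects")
  if (is.null(cap)) cap <- selectionCap(n)
  if (is.null(positiveClass)) {
    nonCtrl <- setdiff(levels(d$y), "CONTROL")
    positiveClass <- if (length(nonCtrl) == 1) nonCtrl else levels(d$y)[1]
  }
  ids <- rownames(d$x)
  set.seed(seed)
  foldSeeds <- sample.int(.Machine$integer.max, n)

  predicted <- character(n); score <- numeric(n)
  foldSelections <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- d$x[-i, , drop = FALSE]; yi <- droplevels(d$y[-i])
    if (nlevels(yi) < 2)
      stop(sprintf("fold %d: training set is single-class", i))
    sub <- forestSpec(spec@nTrees, seed = foldSeeds[i])
    sel <- selectFeatures(xi, yi, spec = sub, nRepeats = nRepeats,
                          alpha = alpha, cap = cap, sdFactor = sdFactor,
                          seed = foldSeeds[i])
    feats <- selectedFeatures(sel)
    forest <- trainBalancedRF(xi[, feats, drop = FALSE], yi, sub,
                              positiveClass = positiveClass)
    pr <- predictForest(forest, d$x[i, feats, drop = FALSE])
    predicted[i] <- pr$predicted; score[i] <- pr$score
    foldSelections[[i]] <- sel
  }
  names(foldSelections) <- ids
  report <- metricPanel(as.character(d$y), predicted, score, positiveClass)
  new("LoocvResult", report = report, foldSelections = foldSelections,
      subjectIds = ids)
}

#' Sequential two-stage classification (diagnosis, then lateralization)
#'
#' Mirrors the clinical workflow: a subject is first diagnosed (TLE vs
#' CONTROL); only if diagnosed TLE is the lateralization stage invoked to
#' assign LTLE or RTLE. The lateralization stage is therefore never
#' evaluated for subjects the diagnosis stage labels CONTROL.
#'
#' @param diagStage a [BalancedForest-class] for TLE vs CONTROL, or a
#'   function(rows) returning labels.
#' @param latStage a [BalancedForest-class] for LTLE vs RTLE, or a
#'   function(rows) returning labels. May be NULL as long as no subject is
#'   diagnosed TLE.
#' @param newdata subjects x features matrix (or
#'   [ConnectivityFeatures-class]) holding the features both stages need.
#' @return character vector of labels in CONTROL / LTLE / RTLE.
#' @export
sequentialSystem <- function(diagStage, latStage, newdata) {
  if (is(newdata, "ConnectivityFeatures")) newdata <- featureMatrix(newdata)
  newdata <- as.matrix(newdata)
  applyStage <- function(stage, rows) {
    if (is.function(stage)) stage(rows)
    else as.character(predictForest(stage, rows)$predicted)
  }
  diagPred <- applyStage(diagStage, newdata)
  out <- rep("CONTROL", nrow(newdata))
  tle <- diagPred != "CONTROL"
  if (any(tle)) {
    if (is.null(latStage))
      stop("lateralization stage required: some subjects were diagnosed TLE")
    out[tle] <- applyStage(latStage, newdata[tle, , drop = FALSE])
  }
  names(out) <- rownames(newdata)
  out
}

#' Three-class confusion matrix
#'
#' @param actual,predicted labels over CONTROL / LTLE / RTLE.
#' @return 3 x 3 count matrix, rows actual, columns predicted, in
#'   LTLE / RTLE / CONTROL order.
#' @export
threeClassConfusion <- function(actual, predicted) {
  lev <- c("LTLE", "RTLE", "CONTROL")
  tab <- table(actual = factor(as.character(actual), levels = lev),
               predicted = factor(as.character(predicted), levels = lev))
  matrix(tab, 3, 3, dimnames = dimnames(tab))
}

#' Collapse a three-class confusion matrix to TLE vs CONTROL
#'
#' Merges the LTLE and RTLE rows/columns into a single TLE class.
#'
#' @param conf 3 x 3 matrix from [threeClassConfusion()].
#' @return 2 x 2 matrix with rows/columns TLE, CONTROL.
#' @export
collapseConfusion <- function(conf) {
  stopifnot(all(dim(conf) == c(3, 3)))
  tle <- c("LTLE", "RTLE")
  out <- matrix(0, 2, 2, dimnames = list(actual = c("TLE", "CONTROL"),
                                         predicted = c("TLE", "CONTROL")))
  out["TLE", "TLE"] <- sum(conf[tle, tle])
  out["TLE", "CONTROL"] <- sum(conf[tle, "CONTROL"])
  out["CONTROL", "TLE"] <- sum(conf["CONTROL", tle])
  out["CONTROL", "CONTROL"] <- conf["CONTROL", "CONTROL"]
  out
}

#' Metric panel from 2x2 counts
#'
#' Convenience wrapper reconstructing a [ClassifierReport-class] from
#' explicit TP/FN/FP/TN counts (scores are set to the predicted class, so
#' the AUC is the balanced accuracy of the hard predictions).
#'
#' @param TP,FN,FP,TN confusion counts with the positive class first.
#' @param positiveClass,negativeClass class labels.
#' @return a [ClassifierReport-class].
#' @export
metricPanelFromCounts <- function(TP, FN, FP, TN, positiveClass = "TLE",
                                  negativeClass = "CONTROL") {
  actual <- rep(c(positiveClass, negativeClass), c(TP + FN, FP + TN))
  predicted <- c(rep(positiveClass, TP), rep(negativeClass, FN),
                 rep(positiveClass, FP), rep(negativeClass, TN))
  scores <- as.numeric(predicted == positiveClass)
  metricPanel(actual, predicted, scores, positiveClass)
}
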