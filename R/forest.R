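#' @include features.R
NULL

#' Balanced random forest specification
#'
#' @param nTrees number of trees (default 1000).
#' @param seed RNG seed driving bootstraps and split sampling.
#' @return a [BalancedForestSpec-class].
#' @export
forestSpec <- function(nTrees = 1000L, seed = 1L) {
  new("BalancedForestSpec", nTrees = as.integer(nTrees),
      seed = as.integer(seed))
}

#' Number of split candidates for a feature count
#'
#' The number of features drawn at each split is floor(log2(M)) (at least
#' 1), where M is the number of features in the table.
#'
#' @param M number of features.
#' @return integer split-candidate count.
#' @examples
#' splitCandidates(588)   # 9
#' @export
splitCandidates <- function(M) {
  max(1L, as.integer(floor(log2(M))))
}

# coerce input to (matrix, factor) pair
.asXY <- function(x, labels = NULL) {
  if (is(x, "ConnectivityFeatures")) {
    if (is.null(labels)) labels <- classLabels(x)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  list(x = x, y = factor(as.character(labels)))
}

# balanced with-replacement bootstrap counts: min-class count from each class
.balancedInbag <- function(y, nTrees) {
  counts <- table(y)
  if (length(counts) != 2) stop("balanced bootstrap needs exactly 2 classes")
  if (any(counts < 2))
    stop("balanced bootstrap undefined: a class has fewer than 2 subjects")
  k <- min(counts)
  n <- length(y)
  idx1 <- which(y == levels(y)[1]); idx2 <- which(y == levels(y)[2])
  ib <- matrix(0L, n, nTrees)
  for (t in seq_len(nTrees)) {
    draw <- c(sample(idx1, k, replace = TRUE), sample(idx2, k, replace = TRUE))
    ib[, t] <- tabulate(draw, n)
  }
  ib
}

# flatten a ranger classification forest into arrays for the C++ kernel
.flattenForest <- function(fit) {
  fo <- fit$forest
  nTrees <- fo$num.trees
  left <- vector("list", nTrees); right <- vector("list", nTrees)
  svar <- vector("list", nTrees); sval <- vector("list", nTrees)
  pred <- vector("list", nTrees)
  for (t in seq_len(nTrees)) {
    lc <- as.integer(fo$child.nodeIDs[[t]][[1]])
    rc <- as.integer(fo$child.nodeIDs[[t]][[2]])
    sv <- fo$split.values[[t]]
    terminal <- lc == 0L & rc == 0L
    pl <- integer(length(lc))
    # terminal split.values hold 1-based class level indices (verified
    # against ranger's own predict in the test suite)
    pl[terminal] <- as.integer(sv[terminal])
    left[[t]] <- lc; right[[t]] <- rc
    svar[[t]] <- as.integer(fo$split.varIDs[[t]])
    sval[[t]] <- as.numeric(sv)
    pred[[t]] <- pl
  }
  list(nTrees = as.integer(nTrees), left = left, right = right,
       splitVar = svar, splitVal = sval, predLevel = pred,
       levels = fo$levels,
       featureNames = fo$independent.variable.names)
}

#' Train a balanced random forest
#'
#' Grows `spec@nTrees` classification trees, each on a balanced
#' with-replacement bootstrap that draws the minority-class count from both
#' classes, with floor(log2(M)) split candidates per node. Prediction is by
#' majority vote over trees; vote ties go to the positive class.
#'
#' @param x a [ConnectivityFeatures-class] or subjects x features matrix.
#' @param labels two-class labels (taken from `x` when it is a feature
#'   table).
#' @param spec a [BalancedForestSpec-class].
#' @param positiveClass label treated as positive (default: the non-CONTROL
#'   label if present, else the first level).
#' @return a [BalancedForest-class].
#' @export
trainBalancedRF <- function(x, labels = NULL, spec = forestSpec(),
                            positiveClass = NULL) {
  d <- .asXY(x, labels)
  if (ncol(d$x) == 0) stop("empty feature table")
  if (nlevels(d$y) != 2)
    stop(sprintf("need exactly 2 classes, got %d", nlevels(d$y)))
  if (is.null(positiveClass)) {
    nonCtrl <- setdiff(levels(d$y), "CONTROL")
    positiveClass <- if (length(nonCtrl) == 1) nonCtrl else levels(d$y)[1]
  }
  if (!positiveClass %in% levels(d$y)) stop("positiveClass not among labels")
  set.seed(spec@seed)
  inbag <- .balancedInbag(d$y, spec@nTrees)
  fit <- ranger::ranger(
    x = as.data.frame(d$x), y = d$y, num.trees = spec@nTrees,
    mtry = splitCandidates(ncol(d$x)),
    inbag = lapply(seq_len(ncol(inbag)), function(t) inbag[, t]),
    keep.inbag = TRUE, num.threads = 1L, seed = spec@seed,
    respect.unordered.factors = FALSE)
  new("BalancedForest", fit = fit, flat = .flattenForest(fit), x = d$x,
      y = d$y, inbag = inbag, spec = spec, positiveClass = positiveClass)
}

#' Predict with a balanced random forest
#'
#' @param object a [BalancedForest-class].
#' @param newdata subjects x features matrix (or
#'   [ConnectivityFeatures-class]) containing at least the training
#'   features.
#' @param ... unused.
#' @return a data.frame with columns `predicted` (majority vote; ties to
#'   the positive class) and `score` (fraction of trees voting for the
#'   positive class).
#' @export
predictForest <- function(object, newdata, ...) {
  stopifnot(is(object, "BalancedForest"))
  if (is(newdata, "ConnectivityFeatures")) newdata <- featureMatrix(newdata)
  newdata <- as.matrix(newdata)
  need <- colnames(object@x)
  miss <- setdiff(need, colnames(newdata))
  if (length(miss))
    stop(sprintf("newdata lacks required feature(s): %s",
                 paste(miss, collapse = ", ")))
  X <- newdata[, need, drop = FALSE]
  P <- .cppForestPredict(object@flat, X)      # n x nTrees level indices
  lev <- levels(object@y)
  posIdx <- match(object@positiveClass, lev)
  score <- rowMeans(P == posIdx)
  predicted <- ifelse(score >= 0.5, object@positiveClass,
                      setdiff(lev, object@positiveClass))
  data.frame(predicted = predicted, score = score,
             row.names = rownames(newdata))
}

#' Out-of-bag accuracy of a balanced forest
#'
#' Majority vote per training subject over the trees for which the subject
#' was out of bag (ties to the lowest class index).
#'
#' @param object a [BalancedForest-class].
#' @return OOB accuracy in \[0, 1\].
#' @export
oobAccuracy <- function(object) {
  stopifnot(is(object, "BalancedForest"))
  P <- .cppForestPredict(object@flat, object@x)
  oob <- object@inbag == 0L
  K <- nlevels(object@y)
  yInt <- as.integer(object@y)
  hasOob <- rowSums(oob) > 0
  correct <- vapply(which(hasOob), function(i) {
    votes <- tabulate(P[i, oob[i, ]], K)
    which.max(votes) == yInt[i]
  }, logical(1))
  mean(correct)
}
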