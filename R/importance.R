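#' @include forest.R
NULL

# One-sided importance z-test (Breiman): each feature's mean per-tree OOB
# accuracy drop is studentized by its across-tree standard error
# sd(drops) / sqrt(nTrees), computed within each permutation repeat and
# averaged over repeats (repeats reuse the same trees, so they do not add
# independent information to the denominator). Unused features have
# importance exactly 0 with zero spread -> z = 0 -> p = 1.
.importancePValues <- function(imp, impSq, nTrees) {
  m <- rowMeans(imp)
  seMat <- sqrt(pmax(impSq - nTrees * imp^2, 0) / max(nTrees - 1, 1) / nTrees)
  seBar <- rowMeans(seMat)
  z <- ifelse(seBar > 0, m / seBar, ifelse(m > 0, Inf, 0))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Out-of-bag permutation importance
#'
#' Trains one balanced forest on the full table, then measures, for every
#' feature, the decrease in out-of-bag classification accuracy when that
#' feature's values are permuted: per permutation repeat, each tree's OOB
#' accuracy drop is computed and averaged over all trees of the forest
#' (`nRepeats` independent permutations; only the trees that
#' actually split on the feature are re-evaluated, so a feature the forest
#' never uses has importance exactly 0 in every repeat). A feature is
#' flagged significant when a one-sided test that its importance exceeds
#' zero falls below `alpha` and its mean importance is positive. The test
#' is the classical importance z-score: the mean per-tree accuracy drop
#' divided by its across-tree standard error (the spread of the drop over
#' the trees of the forest), so a feature must degrade the trees that use
#' it consistently, not just on average.
#'
#' @param x a [ConnectivityFeatures-class] or subjects x features matrix.
#' @param labels two-class labels (taken from `x` if a feature table).
#' @param spec a [BalancedForestSpec-class] for the screening forest.
#' @param nRepeats number of permutation repeats (default 50).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param forest optionally, an already-trained [BalancedForest-class] on
#'   exactly this table (skips retraining).
#' @return an [ImportanceReport-class].
#' @export
permutationImportance <- function(x, labels = NULL, spec = forestSpec(),
                                  nRepeats = 50L, alpha = 0.05,
                                  seed = spec@seed, forest = NULL) {
  nRepeats <- as.integer(nRepeats)
  if (nRepeats < 1) stop("nRepeats must be >= 1")
  if (is.null(forest)) forest <- trainBalancedRF(x, labels, spec)
  n <- nrow(forest@x)
  set.seed(seed)
  perms <- vapply(seq_len(nRepeats), function(r) sample.int(n),
                  integer(n))
  res <- .cppPermImportance(forest@flat, forest@x, as.integer(forest@y),
                            forest@inbag, perms, nlevels(forest@y))
  imp <- res$importance
  rownames(imp) <- colnames(forest@x)
  meanImp <- rowMeans(imp)
  sdImp <- apply(imp, 1, sd)
  pv <- .importancePValues(imp, res$importanceSq, forest@spec@nTrees)
  new("ImportanceReport", featureNames = colnames(forest@x),
      meanImportance = unname(meanImp), importanceSD = unname(sdImp),
      pValue = unname(pv), significant = unname(pv < alpha & meanImp > 0),
      alpha = alpha, nRepeats = nRepeats, baseAcc = res$baseAcc,
      repeats = imp)
}

#' Drop features with non-significant importance
#'
#' Returns exactly the features flagged significant by the screening
#' report, in their original order. Features with a non-significant
#' importance carry no reliable class information and are removed from the
#' design before subset selection.
#'
#' @param report an [ImportanceReport-class].
#' @return character vector of surviving feature names (possibly empty).
#' @export
dropInsignificant <- function(report) {
  stopifnot(is(report, "ImportanceReport"))
  report@featureNames[report@significant]
}
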