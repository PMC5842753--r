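#' @include importance.R
NULL

#' Two-sided Mann-Whitney-Wilcoxon test between two classes
#'
#' Exact-distribution p-value when both classes have at most 20
#' observations and there are no ties; normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param values numeric feature values.
#' @param labels two-class labels aligned with `values`.
#' @return the two-sided p-value.
#' @examples
#' mwwTest(c(1, 2, 3, 4), c("a", "a", "b", "b"))   # 1/3
#' @export
mwwTest <- function(values, labels) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2)
    stop(sprintf("need exactly 2 classes, got %d", nlevels(labels)))
  xs <- split(values, labels)
  exact <- all(lengths(xs) <= 20) && !anyDuplicated(values)
  stats::wilcox.test(xs[[1]], xs[[2]], exact = exact, correct = TRUE)$p.value
}

#' Default selection cap: one feature per ten subjects
#'
#' @param nSubjects number of subjects available for selection.
#' @return floor(nSubjects / 10), at least 1.
#' @examples
#' selectionCap(75)   # 7
#' selectionCap(40)   # 4
#' @export
selectionCap <- function(nSubjects) {
  max(1L, as.integer(nSubjects %/% 10L))
}

# OOB error of a balanced forest on a feature subset
.subsetOobError <- function(x, y, feats, spec) {
  f <- trainBalancedRF(x[, feats, drop = FALSE], y, spec)
  1 - oobAccuracy(f)
}

#' Minimal discriminative feature subset
#'
#' Selects the minimal subset of screened features carrying the maximum
#' discriminant information. Candidates are ranked by descending importance
#' and nested prefix sets (top-1, top-2, ... up to `cap`) are scored by the
#' out-of-bag error of a balanced forest (all prefix forests share one seed
#' so error differences reflect the feature sets, not bootstrap redraws);
#' the smallest prefix whose error is within `sdFactor` standard errors of
#' the best prefix error is retained and then pruned by backward
#' elimination (a feature is dropped, least important first, when removing
#' it keeps the error within the same tolerance). Scoring whole prefixes
#' rather than greedily testing one feature at a time keeps
#' jointly-informative feature pairs (useless individually) selectable,
#' while the backward pass cuts redundant duplicates. Two-sided
#' Mann-Whitney-Wilcoxon p-values are attached to the final set.
#'
#' @param x a [ConnectivityFeatures-class] or subjects x features matrix,
#'   restricted to the screened features.
#' @param labels two-class labels.
#' @param importance named importances used for the ranking (e.g. from
#'   [permutationImportance()] on the screened table). If NULL they are
#'   recomputed. Ties in importance break lexicographically by feature
#'   name.
#' @param cap maximum number of features; default one per ten subjects
#'   ([selectionCap()]).
#' @param spec a [BalancedForestSpec-class] for the scoring forests.
#' @param sdFactor width of the one-standard-error rule (default 1).
#' @param nRepeats permutation repeats if importances are recomputed.
#' @param seed RNG seed.
#' @return a [SelectionResult-class].
#' @export
minimalSubset <- function(x, labels = NULL, importance = NULL,
                          cap = NULL, spec = forestSpec(), sdFactor = 1,
                          nRepeats = 20L, seed = spec@seed) {
  d <- .asXY(x, labels)
  if (ncol(d$x) == 0) stop("screened feature set is empty")
  n <- nrow(d$x)
  if (is.null(cap)) cap <- selectionCap(n)
  cap <- as.integer(cap)
  if (cap < 1) stop("cap must be >= 1")
  if (is.null(importance)) {
    rep_ <- permutationImportance(d$x, d$y, spec, nRepeats = nRepeats,
                                  seed = seed)
    importance <- importanceValues(rep_)
  }
  importance <- importance[colnames(d$x)]
  if (anyNA(importance)) stop("importance must cover every feature in x")
  ord <- order(-importance, names(importance), method = "radix")
  ranked <- names(importance)[ord]
  kMax <- min(cap, length(ranked))

  # common random numbers: every prefix forest reuses the same seed, so
  # prefix-error differences reflect the feature sets, not bootstrap noise
  errs <- numeric(kMax)
  for (k in seq_len(kMax))
    errs[k] <- .subsetOobError(d$x, d$y, ranked[seq_len(k)], spec)
  eMin <- min(errs)
  # binomial SE of the best OOB error, floored at one misclassification so
  # a zero-error prefix does not force exact ties
  seOf <- function(e) max(sqrt(e * (1 - e) / n), 1 / n)
  kStar <- which(errs <= eMin + sdFactor * seOf(eMin))[1]
  selected <- ranked[seq_len(kStar)]

  # backward elimination: drop any feature (least important first) whose
  # removal keeps the OOB error within the tolerance -- this is what cuts
  # redundant duplicates while leaving jointly-informative pairs intact
  for (f in rev(selected)) {
    if (length(selected) == 1) break
    cand <- setdiff(selected, f)
    eC <- .subsetOobError(d$x, d$y, cand, spec)
    if (eC <= eMin + sdFactor * seOf(min(eMin, eC))) {
      selected <- cand
      eMin <- min(eMin, eC)
    }
  }

  mww <- vapply(selected, function(f) mwwTest(d$x[, f], d$y), numeric(1))
  new("SelectionResult", selected = selected,
      importances = importance[selected], mwwP = mww, cap = cap,
      trace = data.frame(k = seq_len(kMax), oobError = errs))
}

#' Full two-step selection: screen, then minimal subset
#'
#' Runs [permutationImportance()] on the full table, removes
#' non-significant features ([dropInsignificant()]) and picks the minimal
#' subset among the survivors ([minimalSubset()]). When no feature survives
#' screening the single most important feature is used, so downstream
#' classifiers always have at least one input.
#'
#' @inheritParams permutationImportance
#' @param cap maximum number of selected features (default
#'   [selectionCap()] of the subject count).
#' @param sdFactor see [minimalSubset()].
#' @return a [SelectionResult-class].
#' @export
selectFeatures <- function(x, labels = NULL, spec = forestSpec(),
                           nRepeats = 50L, alpha = 0.05, cap = NULL,
                           sdFactor = 1, seed = spec@seed) {
  d <- .asXY(x, labels)
  rep_ <- permutationImportance(d$x, d$y, spec, nRepeats = nRepeats,
                                alpha = alpha, seed = seed)
  keep <- dropInsignificant(rep_)
  if (length(keep) == 0) {
    imp <- importanceValues(rep_)
    keep <- names(imp)[order(-imp, names(imp), method = "radix")][1]
  }
  imp <- importanceValues(rep_)[keep]
  minimalSubset(d$x[, keep, drop = FALSE], d$y, importance = imp, cap = cap,
                spec = spec, sdFactor = sdFactor, seed = seed)
}
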