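#' @include selection.R
NULL

#' Pairwise feature interaction effects
#'
#' For every ordered pair of selected features, measures how the
#' permutation importance of feature c changes when feature r is removed
#' from the design: a balanced forest is retrained without access to
#' feature r (importance is forest-dependent, so removal requires
#' retraining) and the importances of the remaining features are
#' re-measured, averaging over `nRepeats` retraining replicates. Entry
#' (r, c) is the mean re-measured importance of c minus its baseline
#' importance. Negative entries mean the discriminative information in c is
#' only relevant while r is in the design; the diagonal is fixed at 0.
#'
#' @param x a [ConnectivityFeatures-class] or subjects x features matrix
#'   restricted to the selected features (>= 2 of them).
#' @param labels two-class labels.
#' @param spec a [BalancedForestSpec-class].
#' @param nRepeats retraining replicates per removed feature (default 20).
#' @param impRepeats permutation repeats inside each importance estimate
#'   (default 20).
#' @param seed RNG seed.
#' @return an [InteractionMatrix-class].
#' @export
interactionMatrix <- function(x, labels = NULL, spec = forestSpec(),
                              nRepeats = 20L, impRepeats = 20L,
                              seed = spec@seed) {
  d <- .asXY(x, labels)
  k <- ncol(d$x)
  if (k < 2) stop("interaction analysis needs at least 2 features")

  base <- permutationImportance(d$x, d$y, spec, nRepeats = impRepeats,
                                seed = seed)
  baseImp <- importanceValues(base)

  nm <- colnames(d$x)
  effects <- matrix(0, k, k, dimnames = list(nm, nm))
  effectSD <- matrix(0, k, k, dimnames = list(nm, nm))
  for (r in seq_len(k)) {
    reps <- matrix(0, nRepeats, k - 1L)
    for (rep_ in seq_len(nRepeats)) {
      sub <- forestSpec(spec@nTrees, seed = spec@seed + r * 1000L + rep_)
      reps[rep_, ] <- importanceValues(
        permutationImportance(d$x[, -r, drop = FALSE], d$y, sub,
                              nRepeats = impRepeats, seed = sub@seed))
    }
    effects[r, -r] <- colMeans(reps) - baseImp[-r]
    effectSD[r, -r] <- apply(reps, 2, sd)
  }
  new("InteractionMatrix", effects = effects, baseline = baseImp,
      permSD = setNames(base@importanceSD, nm), effectSD = effectSD)
}

#' Write an interaction matrix as CSV
#'
#' Square layout, header and first column carrying the feature names.
#'
#' @param im an [InteractionMatrix-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeInteractionMatrix <- function(im, path) {
  stopifnot(is(im, "InteractionMatrix"))
  df <- data.frame(feature = rownames(im@effects), im@effects,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
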