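#' @include mvar.R
NULL

#' Default region-of-interest set
#'
#' The 14 mesial temporal / cingulate regions used by the classification
#' pipeline: left and right hippocampus (Hipp), amygdala (Amyg),
#' parahippocampus (PHipp), anterior and posterior cingulate cortex
#' (ACC, PCC), olfactory cortex (Olf) and medial temporal pole (TPMid).
#'
#' @return character vector of 14 ROI labels, left/right pairs adjacent.
#' @export
defaultRoiNames <- function() {
  stems <- c("Hipp", "Amyg", "PHipp", "ACC", "PCC", "Olf", "TPMid")
  as.vector(t(outer(stems, c("L", "R"), paste, sep = "-")))
}

# left/right pairing of an even-length ROI list; pairs are adjacent entries
# unless all names carry -L/-R suffixes, in which case stems are matched.
.pairInfo <- function(roiNames) {
  R <- length(roiNames)
  if (R %% 2 != 0) stop("roiNames must have even length (left/right pairs)")
  suffixed <- all(grepl("-(L|R)$", roiNames))
  if (suffixed) {
    stems <- sub("-(L|R)$", "", roiNames)
    side <- sub("^.*-(L|R)$", "\\1", roiNames)
    uStems <- unique(stems)
    if (length(uStems) != R / 2 ||
        !all(vapply(uStems, function(s) setequal(side[stems == s], c("L", "R")),
                    logical(1))))
      stop("ROI names with -L/-R suffixes must form complete left/right pairs")
    pairs <- vapply(uStems, function(s)
      c(which(stems == s & side == "L"), which(stems == s & side == "R")),
      integer(2))
  } else {
    pairs <- matrix(seq_len(R), nrow = 2)
    side <- rep(c("L", "R"), R / 2)
  }
  # mirror[i] = index of i's contralateral homologue
  mirror <- integer(R)
  mirror[pairs[1, ]] <- pairs[2, ]
  mirror[pairs[2, ]] <- pairs[1, ]
  list(pairs = pairs, side = side, mirror = mirror)
}

# hub senders whose outflow carries the planted pathology
.hubIndices <- function(roiNames) {
  hubs <- grep("^(Hipp|ACC)", roiNames)
  if (length(hubs) == 0) hubs <- c(1L, 2L)
  hubs
}

# directed coupling edge list: every hub sends to its contralateral
# homologue and to the same-side members of the next three pairs, so every
# region receives inflow and participates in the network.
.couplingEdges <- function(roiNames) {
  info <- .pairInfo(roiNames)
  nPairs <- ncol(info$pairs)
  pairOf <- integer(length(roiNames))
  for (q in seq_len(nPairs)) pairOf[info$pairs[, q]] <- q
  hubs <- .hubIndices(roiNames)
  edges <- NULL
  for (s in hubs) {
    targets <- info$mirror[s]
    q <- pairOf[s]
    nextPairs <- (q + seq_len(min(3L, nPairs - 1L)) - 1L) %% nPairs + 1L
    for (nq in nextPairs) {
      members <- info$pairs[, nq]
      sameSide <- members[info$side[members] == info$side[s]]
      targets <- c(targets, sameSide)
    }
    targets <- setdiff(unique(targets), s)
    edges <- rbind(edges, cbind(sender = rep(s, length(targets)),
                                receiver = targets))
  }
  edges
}

#' Build a group network template
#'
#' Constructs a stable MVAR generator for one group. Every region carries a
#' damped AR(2) oscillator (pole radius `oscRho`, pair-specific centre
#' frequency between 6 and 11 Hz, jittered by `freqJitterSd`); directed
#' lag-1 couplings of strength `baseCoupling` run from hub regions (names
#' starting with Hipp or ACC) to their contralateral homologue and to the
#' same-side members of the three following region pairs, so every region
#' receives inflow. For the LTLE / RTLE groups the outflow
#' couplings from the ipsilateral hubs are reduced by the fraction
#' `effectSize`; the two patient groups are exact mirror images of one
#' another under the left/right ROI pairing. If the assembled coefficient
#' set is unstable it is rescaled by 0.95 up to `maxRescale` times before
#' failing.
#'
#' @param group one of "CONTROL", "LTLE", "RTLE".
#' @param roiNames even-length ROI list with left/right pairs (default
#'   [defaultRoiNames()]).
#' @param order MVAR order (>= 1; the oscillator needs >= 2).
#' @param baseCoupling coupling coefficient for planted edges.
#' @param effectSize fractional outflow reduction in \[0, 1\] for the
#'   patient groups (0 reproduces the control network exactly).
#' @param oscRho pole radius of the per-region oscillator (0 < oscRho < 1).
#' @param freqJitterSd SD in Hz of the seeded jitter on pair centre
#'   frequencies.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed for the frequency jitter.
#' @param maxRescale rescaling attempts before giving up on stability.
#' @return a [NetworkTemplate-class].
#' @examples
#' tpl <- makeTemplate("LTLE", effectSize = 0.5, seed = 1)
#' effectSpec(tpl)
#' @export
makeTemplate <- function(group = c("CONTROL", "LTLE", "RTLE"),
                         roiNames = defaultRoiNames(), order = 2L,
                         baseCoupling = 0.25, effectSize = 0,
                         oscRho = 0.75, freqJitterSd = 0.3, fs = 250,
                         seed = NULL, maxRescale = 50L) {
  group <- match.arg(group)
  order <- as.integer(order)
  if (order < 1) stop("order must be >= 1")
  if (effectSize < 0) stop("effectSize must be >= 0")
  R <- length(roiNames)
  info <- .pairInfo(roiNames)
  nPairs <- ncol(info$pairs)

  if (!is.null(seed)) set.seed(seed)
  f0 <- if (nPairs > 1) seq(6, 11, length.out = nPairs) else 8
  f0 <- pmax(4.5, f0 + rnorm(nPairs, sd = freqJitterSd))

  coeffs <- array(0, c(R, R, order))
  for (q in seq_len(nPairs)) {
    idx <- info$pairs[, q]
    if (order >= 2) {
      coeffs[cbind(idx, idx, 1L)] <- 2 * oscRho * cos(2 * pi * f0[q] / fs)
      coeffs[cbind(idx, idx, 2L)] <- -oscRho^2
    } else {
      coeffs[cbind(idx, idx, 1L)] <- 0.5
    }
  }
  edges <- .couplingEdges(roiNames)
  coeffs[cbind(edges[, "receiver"], edges[, "sender"], 1L)] <- baseCoupling

  # stabilize the control network first, so all three groups share one
  # global scale and differ only by their planted deltas
  attempts <- 0L
  while (.companionRadius(coeffs) >= 0.97 && attempts < maxRescale) {
    coeffs <- coeffs * 0.95
    attempts <- attempts + 1L
  }
  rho <- .companionRadius(coeffs)
  if (rho >= 1)
    stop(sprintf("unstable template after %d rescaling attempts (spectral radius %.3f)",
                 attempts, rho))

  # planted pathology: reduced outflow from the ipsilateral hubs, as a
  # fraction of the (stabilized) control coupling
  hubs <- .hubIndices(roiNames)
  ipsiSide <- switch(group, CONTROL = NA_character_, LTLE = "L", RTLE = "R")
  effectRows <- if (group == "CONTROL") integer(0) else
    which(edges[, "sender"] %in% hubs[info$side[hubs] == ipsiSide])
  si <- edges[effectRows, "sender"]; ri <- edges[effectRows, "receiver"]
  effectSpec <- data.frame(
    sender = roiNames[si], receiver = roiNames[ri],
    lag = rep(1L, length(effectRows)),
    delta = -effectSize * coeffs[cbind(ri, si, rep(1L, length(effectRows)))],
    stringsAsFactors = FALSE)
  if (nrow(effectSpec) > 0) {
    coeffs[cbind(ri, si, effectSpec$lag)] <-
      coeffs[cbind(ri, si, effectSpec$lag)] + effectSpec$delta
    rho <- .companionRadius(coeffs)
    if (rho >= 1)
      stop(sprintf("unstable template after planted effect (spectral radius %.3f)",
                   rho))
  }
  new("NetworkTemplate", coeffs = coeffs, noiseCov = diag(R), fs = fs,
      roiNames = roiNames, groupLabel = group, effectSpec = effectSpec,
      baseCoupling = baseCoupling)
}
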