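#' @include template.R
NULL

#' Simulate one subject's epoch-segmented recording
#'
#' Draws a subject-specific copy of the template by adding i.i.d. Gaussian
#' jitter (SD `subjectJitterSd`) to the nonzero MVAR coefficients, rejecting
#' unstable draws (up to `maxRetries`), then simulates `nEpochs` independent
#' epochs with a discarded burn-in of 10 x order samples each. Optional
#' white observation noise of SD `obsNoiseSd` is added on top of the MVAR
#' signal.
#'
#' @param template a [NetworkTemplate-class] (or any stable
#'   [MVARModel-class]).
#' @param nEpochs number of epochs (default 60).
#' @param epochSeconds epoch duration in seconds (default 1).
#' @param fs sampling rate in Hz (default: the template's).
#' @param subjectJitterSd SD of the coefficient jitter; default 10% of the
#'   template's base coupling (0.025 for plain MVAR models).
#' @param obsNoiseSd SD of additive white observation noise (default 0, so
#'   the recorded process is exactly MVAR).
#' @param subjectId subject identifier.
#' @param seed RNG seed.
#' @param maxRetries stability retries for the jittered model.
#' @return a [SubjectEpochs-class] of shape nEpochs x R x
#'   (epochSeconds * fs).
#' @examples
#' tpl <- makeTemplate("CONTROL", seed = 1)
#' s <- simulateSubject(tpl, nEpochs = 2, seed = 1)
#' dim(s@epochs)
#' @export
simulateSubject <- function(template, nEpochs = 60L, epochSeconds = 1,
                            fs = NULL, subjectJitterSd = NULL,
                            obsNoiseSd = 0, subjectId = "S001", seed = NULL,
                            maxRetries = 25L) {
  stopifnot(is(template, "MVARModel"))
  if (is.null(fs)) fs <- template@fs
  if (is.null(subjectJitterSd))
    subjectJitterSd <- if (is(template, "NetworkTemplate"))
      0.1 * template@baseCoupling else 0.025
  nEpochs <- as.integer(nEpochs)
  if (nEpochs < 1) stop("nEpochs must be >= 1")
  if (fs <= 0) stop("fs must be positive")
  if (.companionRadius(template@coeffs) >= 1) stop("template is not stable")
  if (!is.null(seed)) set.seed(seed)

  coeffs <- template@coeffs
  nz <- which(coeffs != 0)
  subjCoeffs <- NULL
  for (a in seq_len(maxRetries)) {
    cand <- coeffs
    if (subjectJitterSd > 0 && length(nz))
      cand[nz] <- cand[nz] + rnorm(length(nz), sd = subjectJitterSd)
    if (.companionRadius(cand) < 1) { subjCoeffs <- cand; break }
  }
  if (is.null(subjCoeffs))
    stop(sprintf("jittered model unstable after %d retries", maxRetries))
  model <- new("MVARModel", coeffs = subjCoeffs, noiseCov = template@noiseCov,
               fs = fs, roiNames = template@roiNames)

  R <- length(template@roiNames)
  nSamples <- as.integer(round(epochSeconds * fs))
  epochs <- array(0, c(nEpochs, R, nSamples))
  for (ep in seq_len(nEpochs)) {
    x <- .simulateMVAR(model, nSamples)
    if (obsNoiseSd > 0) x <- x + matrix(rnorm(R * nSamples, sd = obsNoiseSd),
                                        R, nSamples)
    epochs[ep, , ] <- x
  }
  grp <- if (is(template, "NetworkTemplate")) template@groupLabel else "CONTROL"
  new("SubjectEpochs", subjectId = subjectId, groupLabel = grp, fs = fs,
      roiNames = template@roiNames, epochs = epochs)
}

#' Simulate a three-group cohort
#'
#' Builds one template per group from shared `templateParams` (so the three
#' generators differ only by their planted effects) and simulates every
#' subject with its own derived seed. The returned manifest records all
#' generator parameters and seeds; passing it to [reproduceCohort()] yields
#' a bit-identical cohort.
#'
#' @param nControl,nLtle,nRtle group sizes (defaults 35 / 20 / 20).
#' @param templateParams named list of [makeTemplate()] arguments shared by
#'   the three groups (e.g. `effectSize`, `baseCoupling`, `roiNames`).
#' @param nEpochs,epochSeconds,fs epoch layout per subject.
#' @param subjectJitterSd coefficient jitter SD (see [simulateSubject()]).
#' @param obsNoiseSd additive observation noise SD.
#' @param seed master seed; all subject seeds derive from it.
#' @return an [EpochCohort-class].
#' @examples
#' coh <- simulateCohort(2, 2, 2, nEpochs = 2, seed = 7,
#'                       templateParams = list(effectSize = 0.6))
#' table(classLabels(coh))
#' @export
simulateCohort <- function(nControl = 35L, nLtle = 20L, nRtle = 20L,
                           templateParams = list(), nEpochs = 60L,
                           epochSeconds = 1, fs = 250,
                           subjectJitterSd = NULL, obsNoiseSd = 0,
                           seed = 1L) {
  counts <- c(CONTROL = as.integer(nControl), LTLE = as.integer(nLtle),
              RTLE = as.integer(nRtle))
  if (any(counts < 0)) stop("group sizes must be >= 0")
  set.seed(seed)
  templateSeed <- sample.int(.Machine$integer.max, 1L)
  nTotal <- sum(counts)
  subjectSeeds <- if (nTotal > 0) sample.int(.Machine$integer.max, nTotal)
                  else integer(0)

  groups <- rep(names(counts), counts)
  ids <- if (nTotal > 0)
    sprintf("%s_%02d", groups, unlist(lapply(counts, seq_len), use.names = FALSE))
    else character(0)

  templates <- lapply(names(counts), function(g)
    do.call(makeTemplate, modifyList(list(group = g, fs = fs,
                                          seed = templateSeed),
                                     templateParams)))
  names(templates) <- names(counts)

  subjects <- vector("list", nTotal)
  for (i in seq_len(nTotal)) {
    subjects[[i]] <- tryCatch(
      simulateSubject(templates[[groups[i]]], nEpochs = nEpochs,
                      epochSeconds = epochSeconds, fs = fs,
                      subjectJitterSd = subjectJitterSd,
                      obsNoiseSd = obsNoiseSd, subjectId = ids[i],
                      seed = subjectSeeds[i]),
      error = function(e)
        stop(sprintf("subject %s: %s", ids[i], conditionMessage(e))))
  }
  manifest <- list(
    seed = seed, templateSeed = templateSeed, subjectSeeds = subjectSeeds,
    subjectIds = ids, groups = groups,
    nControl = counts[["CONTROL"]], nLtle = counts[["LTLE"]],
    nRtle = counts[["RTLE"]],
    templateParams = templateParams, nEpochs = as.integer(nEpochs),
    epochSeconds = epochSeconds, fs = fs,
    subjectJitterSd = subjectJitterSd, obsNoiseSd = obsNoiseSd)
  new("EpochCohort", subjects = subjects, manifest = manifest)
}

#' Rebuild a cohort from its manifest
#'
#' @param manifest a manifest as stored in an [EpochCohort-class] (or read
#'   back from disk by [readCohort()]).
#' @return an [EpochCohort-class] bit-identical to the original.
#' @export
reproduceCohort <- function(manifest) {
  simulateCohort(nControl = manifest$nControl, nLtle = manifest$nLtle,
                 nRtle = manifest$nRtle,
                 templateParams = manifest$templateParams,
                 nEpochs = manifest$nEpochs,
                 epochSeconds = manifest$epochSeconds, fs = manifest$fs,
                 subjectJitterSd = manifest$subjectJitterSd,
                 obsNoiseSd = manifest$obsNoiseSd, seed = manifest$seed)
}
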