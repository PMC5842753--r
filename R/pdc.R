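#' @include mvar.R bands.R
NULL

#' Partial directed coherence spectrum of an MVAR model
#'
#' Computes the sender-normalized (column-wise) PDC of Baccala & Sameshima
#' on a frequency grid. With the spectral transfer
#' Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs), the PDC from sender j to
#' receiver i is |Abar(f)\[i, j\]| / sqrt(sum_k |Abar(f)\[k, j\]|^2), so for
#' every sender column the squared values sum to one at each frequency.
#' Diagonal (self) terms are retained.
#'
#' @param model an [MVARModel-class].
#' @param freqs frequencies in Hz, all in (0, fs/2).
#' @return a [ConnectivityTensor-class] on the frequency grid.
#' @examples
#' m <- mvarModel(matrix(c(0.5, 0.4, 0, 0.5), 2, 2))
#' pdc <- pdcSpectrum(m, freqs = 1:30)
#' colSums(connValues(pdc)[, , 10]^2)   # each sender column sums to 1
#' @export
pdcSpectrum <- function(model, freqs) {
  stopifnot(is(model, "MVARModel"))
  fs <- model@fs
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("all frequencies must lie in (0, fs/2)")
  coeffs <- model@coeffs
  R <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  vals <- array(0, c(R, R, length(freqs)))
  for (k in seq_along(freqs)) {
    Abar <- diag(R) + 0i
    for (r in seq_len(p))
      Abar <- Abar - coeffs[, , r] * exp(-2i * pi * freqs[k] * r / fs)
    mods <- Mod(Abar)
    colNorm <- sqrt(colSums(mods^2))
    if (any(colNorm == 0))
      stop("degenerate model: a sender column of Abar(f) has zero norm")
    vals[, , k] <- sweep(mods, 2L, colNorm, "/")
  }
  new("ConnectivityTensor", values = vals, axisKind = "frequency_grid",
      freqs = as.numeric(freqs), bands = NULL, roiNames = model@roiNames)
}

#' Weight a PDC tensor by sender signal power
#'
#' Multiplies each sender column of the PDC by the sender channel's mean
#' squared amplitude over the epoch, so outflow from weakly active regions
#' is downweighted. Weights are normalized within the epoch to keep values
#' scale-free across subjects: by the maximum channel power (default;
#' weights lie in (0, 1\] with at least one weight exactly 1) or by the
#' mean channel power (average weight 1). Note that either way the weights
#' couple the channels: the weighted values carry network-wide power
#' information on top of the per-edge coupling captured by the PDC factor.
#'
#' @param pdc a frequency-grid [ConnectivityTensor-class] from
#'   [pdcSpectrum()].
#' @param epoch the R x nSamples epoch the model was fitted on.
#' @param normalize weight normalization: "max" (default) or "mean".
#' @return a weighted [ConnectivityTensor-class] on the same grid.
#' @export
weightPDC <- function(pdc, epoch, normalize = c("max", "mean")) {
  stopifnot(is(pdc, "ConnectivityTensor"))
  normalize <- match.arg(normalize)
  if (pdc@axisKind != "frequency_grid")
    stop("weighting applies to frequency-grid PDC tensors")
  epoch <- as.matrix(epoch)
  if (nrow(epoch) != length(pdc@roiNames))
    stop("epoch channel count must match the tensor")
  w <- rowMeans(epoch^2)
  if (any(w == 0)) stop("a channel has zero power; cannot weight")
  w <- w / if (normalize == "max") max(w) else mean(w)
  vals <- pdc@values
  for (j in seq_along(w)) vals[, j, ] <- vals[, j, ] * w[j]
  new("ConnectivityTensor", values = vals, axisKind = "frequency_grid",
      freqs = pdc@freqs, bands = NULL, roiNames = pdc@roiNames)
}

# mean of grid values over each band's closed-open interval
.bandReduce <- function(vals, freqs, bands) {
  nb <- length(bands@labels)
  R <- dim(vals)[1]
  out <- array(0, c(R, R, nb))
  for (k in seq_len(nb)) {
    members <- .bandMembers(bands, freqs, k)
    if (length(members) == 0)
      stop(sprintf("band %s [%g, %g) captures no grid frequency",
                   bands@labels[k], bands@lower[k], bands@upper[k]))
    out[, , k] <- apply(vals[, , members, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Subject-level band-averaged wPDC connectivity
#'
#' For every epoch: fit an MVAR model, compute the PDC spectrum on `freqs`,
#' weight it by sender power ([weightPDC()]). The weighted spectra are then
#' averaged arithmetically across epochs on the frequency grid, and finally
#' reduced to band means over each closed-open band interval.
#'
#' @param subject a [SubjectEpochs-class].
#' @param bands a [BandSpec-class] (default theta/alpha/beta).
#' @param freqs frequency grid in Hz (default 1..30 at 1-Hz spacing).
#' @param order fixed MVAR order (default 5; ~20 ms of history at 250 Hz).
#' @param orderPolicy "fixed" uses `order` for every epoch;
#'   "ic" selects the order per subject on the first epoch by [selectOrder()].
#' @param maxOrder cap for information-criterion order selection.
#' @param criterion information criterion for `orderPolicy = "ic"`.
#' @param weighted set to FALSE for plain (unweighted) PDC band means.
#' @param normalize weight normalization passed to [weightPDC()].
#' @return a band-axis [ConnectivityTensor-class] (R x R x nBands).
#' @export
subjectConnectivity <- function(subject, bands = bandSpec(), freqs = 1:30,
                                order = 5L, orderPolicy = c("fixed", "ic"),
                                maxOrder = 12L, criterion = "bic",
                                weighted = TRUE,
                                normalize = c("max", "mean")) {
  stopifnot(is(subject, "SubjectEpochs"))
  orderPolicy <- match.arg(orderPolicy)
  nEp <- dim(subject@epochs)[1]
  if (nEp < 1) stop("subject has no epochs")
  R <- length(subject@roiNames)
  if (orderPolicy == "ic")
    order <- selectOrder(subject@epochs[1, , ], maxOrder = maxOrder,
                         criterion = criterion, fs = subject@fs)
  acc <- array(0, c(R, R, length(freqs)))
  for (ep in seq_len(nEp)) {
    epoch <- subject@epochs[ep, , , drop = TRUE]
    if (R == 1) epoch <- matrix(epoch, nrow = 1)
    model <- tryCatch(
      fitMVAR(epoch, order = order, fs = subject@fs,
              roiNames = subject@roiNames),
      error = function(e)
        stop(sprintf("epoch %d: %s", ep, conditionMessage(e))))
    tens <- pdcSpectrum(model, freqs)
    if (weighted) tens <- weightPDC(tens, epoch, normalize = normalize)
    acc <- acc + tens@values
  }
  acc <- acc / nEp
  bandVals <- .bandReduce(acc, freqs, bands)
  new("ConnectivityTensor", values = bandVals, axisKind = "bands",
      freqs = numeric(0), bands = bands, roiNames = subject@roiNames)
}
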