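#' @include AllClasses.R
NULL

# spectral radius of the companion matrix of an R x R x p coefficient array
.companionRadius <- function(coeffs) {
  R <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  comp <- matrix(0, R * p, R * p)
  for (r in seq_len(p))
    comp[seq_len(R), (r - 1L) * R + seq_len(R)] <- coeffs[, , r]
  if (p > 1)
    comp[R + seq_len(R * (p - 1L)), seq_len(R * (p - 1L))] <- diag(R * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Construct an MVAR model
#'
#' @param coeffs R x R x p array (or R x R matrix for order 1) of lag
#'   coefficients; `coeffs[i, j, r]` is the influence of channel j at lag r
#'   on channel i.
#' @param noiseCov innovation covariance (default identity).
#' @param fs sampling rate in Hz.
#' @param roiNames channel labels.
#' @return an [MVARModel-class].
#' @export
mvarModel <- function(coeffs, noiseCov = NULL, fs = 250,
                      roiNames = NULL) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(dim(coeffs), 1L))
  R <- dim(coeffs)[1]
  if (is.null(noiseCov)) noiseCov <- diag(R)
  if (is.null(roiNames)) roiNames <- paste0("roi", seq_len(R))
  new("MVARModel", coeffs = coeffs, noiseCov = noiseCov, fs = fs,
      roiNames = roiNames)
}

#' Spectral radius of an MVAR model's companion matrix
#'
#' The process is stationary/stable iff the radius is strictly below 1.
#'
#' @param model an [MVARModel-class] (or bare coefficient array).
#' @return the spectral radius (nonnegative scalar).
#' @export
companionRadius <- function(model) {
  coeffs <- if (is(model, "MVARModel")) model@coeffs else model
  if (is.matrix(coeffs)) coeffs <- array(coeffs, c(dim(coeffs), 1L))
  .companionRadius(coeffs)
}

#' Stationary covariance of a stable MVAR process
#'
#' Solves the discrete Lyapunov equation of the companion form by
#' vectorization; intended for small models (the linear system has (Rp)^2
#' unknowns).
#'
#' @param model a stable [MVARModel-class].
#' @return the R x R stationary covariance of the process.
#' @export
stationaryCovariance <- function(model) {
  stopifnot(is(model, "MVARModel"))
  coeffs <- model@coeffs
  R <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  if (.companionRadius(coeffs) >= 1) stop("process is not stable")
  comp <- matrix(0, R * p, R * p)
  for (r in seq_len(p))
    comp[seq_len(R), (r - 1L) * R + seq_len(R)] <- coeffs[, , r]
  if (p > 1)
    comp[R + seq_len(R * (p - 1L)), seq_len(R * (p - 1L))] <- diag(R * (p - 1L))
  Q <- matrix(0, R * p, R * p)
  Q[seq_len(R), seq_len(R)] <- model@noiseCov
  m <- R * p
  vecP <- solve(diag(m * m) - kronecker(comp, comp), as.vector(Q))
  P <- matrix(vecP, m, m)
  P[seq_len(R), seq_len(R), drop = FALSE]
}

#' Simulate a realization of an MVAR process
#'
#' Draws Gaussian innovations and iterates the model forward, discarding a
#' burn-in of `burnin` samples (default 10 x order).
#'
#' @param model a stable [MVARModel-class].
#' @param nSamples number of samples to return.
#' @param burnin burn-in samples to discard.
#' @param seed optional RNG seed.
#' @return R x nSamples matrix (channels in rows).
#' @export
simulateMVAR <- function(model, nSamples, burnin = NULL, seed = NULL) {
  stopifnot(is(model, "MVARModel"))
  if (.companionRadius(model@coeffs) >= 1) stop("model is not stable")
  if (!is.null(seed)) set.seed(seed)
  .simulateMVAR(model, nSamples, burnin)
}

# simulate n samples from an MVAR model (after burn-in), channels x samples
.simulateMVAR <- function(model, n, burnin = NULL) {
  coeffs <- model@coeffs
  R <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  if (is.null(burnin)) burnin <- 10L * p
  total <- n + burnin + p
  L <- t(chol(model@noiseCov))
  e <- L %*% matrix(rnorm(R * total), R, total)
  x <- matrix(0, R, total)
  x[, seq_len(p)] <- e[, seq_len(p)]
  A <- lapply(seq_len(p), function(r) coeffs[, , r])
  for (t in (p + 1L):total) {
    acc <- e[, t]
    for (r in seq_len(p)) acc <- acc + A[[r]] %*% x[, t - r]
    x[, t] <- acc
  }
  out <- x[, (total - n + 1L):total, drop = FALSE]
  if (!all(is.finite(out))) stop("MVAR simulation produced non-finite values")
  rownames(out) <- model@roiNames
  out
}

#' Fit an MVAR model to one epoch by ordinary least squares
#'
#' Each channel at time t is regressed on all channels' previous `order`
#' values; the innovation covariance is estimated from the residuals
#' (denominator T - R*order, T = number of usable time points).
#'
#' @param epoch R x nSamples numeric matrix (channels in rows).
#' @param order lag count p (>= 1).
#' @param fs sampling rate in Hz.
#' @param roiNames optional channel labels (default: rownames of `epoch`).
#' @return an [MVARModel-class].
#' @examples
#' x <- matrix(rnorm(500), 2, 250)
#' fitMVAR(x, order = 3)
#' @export
fitMVAR <- function(epoch, order, fs = 250, roiNames = NULL) {
  epoch <- as.matrix(epoch)
  R <- nrow(epoch); n <- ncol(epoch); p <- as.integer(order)
  if (p < 1) stop("order must be >= 1")
  if (p >= n) stop("order must be smaller than the number of samples")
  if (n <= R * p + p) stop("not enough samples for a least-squares MVAR fit")
  if (is.null(roiNames))
    roiNames <- if (!is.null(rownames(epoch))) rownames(epoch)
                else paste0("roi", seq_len(R))
  tIdx <- (p + 1L):n
  Y <- epoch[, tIdx, drop = FALSE]                       # R x T
  Z <- do.call(rbind, lapply(seq_len(p), function(r)
    epoch[, tIdx - r, drop = FALSE]))                    # Rp x T
  G <- tcrossprod(Z)                                     # Rp x Rp
  qrG <- qr(G)
  if (qrG$rank < nrow(G))
    stop("rank-deficient regressor matrix; cannot fit MVAR by least squares")
  B <- t(solve(qrG, tcrossprod(Z, Y)))                   # R x Rp
  resid <- Y - B %*% Z
  Tn <- length(tIdx)
  noiseCov <- tcrossprod(resid) / max(Tn - R * p, 1L)
  noiseCov <- (noiseCov + t(noiseCov)) / 2
  coeffs <- array(0, c(R, R, p))
  for (r in seq_len(p))
    coeffs[, , r] <- B[, (r - 1L) * R + seq_len(R), drop = FALSE]
  new("MVARModel", coeffs = coeffs, noiseCov = noiseCov, fs = fs,
      roiNames = roiNames)
}

#' Choose the MVAR order by an information criterion
#'
#' Fits orders 1..`maxOrder` on a common sample span (all fits condition on
#' the first `maxOrder` samples so criteria are comparable) and returns the
#' order minimizing AIC or BIC on the log determinant of the residual
#' covariance. Ties break toward the smaller order.
#'
#' @param epoch R x nSamples numeric matrix.
#' @param maxOrder largest candidate order.
#' @param criterion "bic" (default) or "aic".
#' @param fs sampling rate in Hz.
#' @return the selected order (integer).
#' @export
selectOrder <- function(epoch, maxOrder, criterion = c("bic", "aic"),
                        fs = 250) {
  criterion <- match.arg(criterion)
  epoch <- as.matrix(epoch)
  R <- nrow(epoch); n <- ncol(epoch)
  maxOrder <- as.integer(maxOrder)
  if (maxOrder < 1) stop("maxOrder must be >= 1")
  Tn <- n - maxOrder
  scores <- rep(NA_real_, maxOrder)
  for (p in seq_len(maxOrder)) {
    fit <- tryCatch({
      tIdx <- (maxOrder + 1L):n
      Y <- epoch[, tIdx, drop = FALSE]
      Z <- do.call(rbind, lapply(seq_len(p), function(r)
        epoch[, tIdx - r, drop = FALSE]))
      B <- t(solve(tcrossprod(Z), tcrossprod(Z, Y)))
      resid <- Y - B %*% Z
      tcrossprod(resid) / Tn
    }, error = function(e) NULL)
    if (is.null(fit)) next
    ld <- determinant(fit, logarithm = TRUE)
    if (ld$sign <= 0) next
    penalty <- if (criterion == "aic") 2 else log(Tn)
    scores[p] <- as.numeric(ld$modulus) + penalty * p * R^2 / Tn
  }
  if (all(is.na(scores))) stop("no candidate order could be fitted")
  which.min(scores)
}
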