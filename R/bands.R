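#' @include AllClasses.R
NULL

#' Construct a frequency band specification
#'
#' Bands are closed-open intervals \[lower, upper) in Hz, so a grid frequency
#' on a shared edge (e.g. 8 Hz) belongs to the upper band only. The defaults
#' are the conventional theta (4-8 Hz), alpha (8-12 Hz) and beta (12-30 Hz)
#' bands.
#'
#' @param ... named length-2 numeric vectors `c(lower, upper)`.
#' @return a [BandSpec-class].
#' @examples
#' bandSpec()                      # theta/alpha/beta defaults
#' bandSpec(slow = c(1, 4), fast = c(12, 45))
#' @export
bandSpec <- function(...) {
  defs <- list(...)
  if (length(defs) == 0)
    defs <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
  if (is.null(names(defs)) || any(names(defs) == ""))
    stop("all bands must be named")
  lower <- vapply(defs, `[`, numeric(1), 1L)
  upper <- vapply(defs, `[`, numeric(1), 2L)
  new("BandSpec", labels = names(defs), lower = unname(lower),
      upper = unname(upper))
}

# indices of grid frequencies falling in band k (closed-open interval)
.bandMembers <- function(bands, freqs, k) {
  which(freqs >= bands@lower[k] & freqs < bands@upper[k])
}
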