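#' FWHM scar quantification
#'
#' Full-width-at-half-maximum rule: the threshold is
#' \code{thresholdFraction} (default 0.5) of the maximal myocardial signal
#' intensity; every myocardial pixel at or above it is classified
#' hyperenhanced, and the result is reported as a percentage of myocardial
#' pixels.
#'
#' The bare rule labels essentially the whole myocardium when no scar is
#' present (in a homogeneous region every pixel sits near the maximum), so
#' a remote-reference gate is offered: with \code{gate = "remote_sd"} the
#' maximal intensity must exceed the mean of the remote myocardium (its
#' lowest-intensity tertile) by at least \code{gateK} standard deviations
#' of that remote region, otherwise the scan is called scar-free and
#' \code{lgePct} is 0. The gate defaults to off so that the bare
#' definition is what unit-level callers get; cohort pipelines enable it.
#'
#' @param image a [PhantomImage-class], numeric matrix/array, or bare
#'   numeric vector of myocardial intensities.
#' @param myocardiumMask logical mask; ignored for a bare vector, taken
#'   from the object for a [PhantomImage-class].
#' @param gate "none" or "remote_sd".
#' @param gateK SD multiplier of the remote gate (default 5).
#' @param thresholdFraction fraction of the maximum defining the
#'   threshold; 0.5 is the half-maximum of the method's name.
#' @return a [ScarResult-class].
#' @export
fwhmLge <- function(image, myocardiumMask = NULL,
                    gate = c("none", "remote_sd"), gateK = 5,
                    thresholdFraction = 0.5) {
  gate <- match.arg(gate)
  if (thresholdFraction <= 0 || thresholdFraction > 1)
    lgeError("thresholdFraction must lie in (0, 1]", "parameterError")
  v <- if (is(image, "PhantomImage") || !is.null(myocardiumMask) ||
           !is.null(dim(image))) {
    extractPixels(image, myocardiumMask)@intensities
  } else {
    as.numeric(image)
  }
  if (!length(v)) lgeError("myocardium is empty", "emptyRegionError")

  mx <- max(v)
  gated <- FALSE
  if (gate == "remote_sd") {
    gated <- TRUE
    remote <- sort(v)[seq_len(max(2L, floor(length(v) / 3)))]
    if (!(mx > mean(remote) + gateK * sd(remote))) {
      return(new("ScarResult", lgePct = 0,
                 thresholdUsed = thresholdFraction * mx,
                 gateApplied = TRUE))
    }
  }
  thr <- thresholdFraction * mx
  new("ScarResult", lgePct = 100 * mean(v >= thr), thresholdUsed = thr,
      gateApplied = gated)
}
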