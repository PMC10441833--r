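#' Extract the myocardial pixel sample
#'
#' Pools the intensities at pixels inside the myocardium mask, minus any
#' overlap with the blood-pool mask, over all slices. Blood-pool signal is
#' always excluded from the entropy calculation: its uniformly bright
#' pixels would otherwise dominate the intensity histogram.
#'
#' @param image a [PhantomImage-class], or a numeric matrix/array of
#'   intensities.
#' @param myocardiumMask,bloodpoolMask logical arrays aligned with the
#'   image; taken from the [PhantomImage-class] slots when omitted.
#' @param sourceId identifier carried into the sample.
#' @return a [PixelSample-class].
#' @export
extractPixels <- function(image, myocardiumMask = NULL,
                          bloodpoolMask = NULL, sourceId = "") {
  if (is(image, "PhantomImage")) {
    pix <- image@pixels
    if (is.null(myocardiumMask)) myocardiumMask <- image@myocardiumMask
    if (is.null(bloodpoolMask)) bloodpoolMask <- image@bloodpoolMask
  } else {
    pix <- image
  }
  if (is.null(myocardiumMask))
    lgeError("a myocardium mask is required", "inputError")
  if (!identical(dim(pix), dim(myocardiumMask)))
    lgeError("myocardium mask is not aligned with the image",
             "alignmentError")
  eff <- myocardiumMask
  if (!is.null(bloodpoolMask)) {
    if (!identical(dim(pix), dim(bloodpoolMask)))
      lgeError("blood-pool mask is not aligned with the image",
               "alignmentError")
    eff <- eff & !bloodpoolMask
  }
  if (!any(eff))
    lgeError("myocardium mask is empty after blood-pool exclusion",
             "emptyRegionError")
  v <- as.numeric(pix[eff])
  new("PixelSample", intensities = v, nPixels = length(v),
      sourceId = as.character(sourceId))
}

#' Bin a pixel sample into an intensity histogram
#'
#' Equal-width bins spanning the sample's [min, max] (\code{min_max} mode)
#' or a caller-given range (\code{fixed} mode); the right-most bin is
#' closed. A constant sample has no range to divide, so all mass is placed
#' in the first bin over a unit-width surrogate range rather than failing;
#' entropy of such a histogram is 0, which is the intended degenerate
#' behaviour for a perfectly homogeneous myocardium.
#'
#' @param sample a [PixelSample-class] or a numeric vector.
#' @param nBins number of bins (>= 2); 128 by default, which puts the
#'   entropy of a heterogeneous myocardium on a 0-7 bit scale.
#' @param rangeMode "min_max" or "fixed".
#' @param range length-2 numeric, required for \code{fixed} mode; values
#'   outside it are clamped into the end bins.
#' @return an [IntensityHistogram-class].
#' @export
buildHistogram <- function(sample, nBins = 128L,
                           rangeMode = c("min_max", "fixed"),
                           range = NULL) {
  rangeMode <- match.arg(rangeMode)
  x <- if (is(sample, "PixelSample")) sample@intensities else
    as.numeric(sample)
  if (length(x) < 1L) lgeError("sample is empty", "emptyRegionError")
  if (nBins < 2L) lgeError("nBins must be >= 2", "parameterError")
  nBins <- as.integer(nBins)
  if (rangeMode == "fixed") {
    if (is.null(range) || length(range) != 2L || diff(range) <= 0)
      lgeError("fixed mode needs an increasing length-2 range",
               "parameterError")
    lo <- range[1]; hi <- range[2]
  } else {
    lo <- min(x); hi <- max(x)
  }
  if (hi <= lo) {                       # constant sample: designated bin
    edges <- seq(lo, lo + 1, length.out = nBins + 1L)
    counts <- integer(nBins)
    counts[1L] <- length(x)
  } else {
    edges <- seq(lo, hi, length.out = nBins + 1L)
    idx <- findInterval(x, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(idx, nbins = nBins)
  }
  new("IntensityHistogram", binEdges = edges, counts = as.integer(counts),
      p = counts / sum(counts))
}

#' Compute the entropy of an intensity histogram
#'
#' The default is the Shannon entropy of the binned intensity distribution,
#' \deqn{H = -\sum_i p_i \log p_i,} with the convention
#' \eqn{0 \log 0 := 0}, reported in the chosen log base (bits for base 2).
#' A perfectly homogeneous region -- all mass in one bin -- has entropy
#' exactly 0, and H is bounded above by log(nBins), attained when all bins
#' are equally occupied.
#'
#' \code{formula = "printed"} instead evaluates
#' \eqn{-\sum_i p_i \log(1 - p_i)}, a variant that appears in some reports
#' of this statistic. It is not a Shannon entropy: it diverges as any
#' \eqn{p_i \to 1}, so a homogeneous region maps to \code{Inf} rather than
#' 0, and it is provided for comparison only.
#'
#' @param hist an [IntensityHistogram-class].
#' @param logBase 2 (bits, default) or exp(1) (nats).
#' @param formula "shannon" (default) or "printed".
#' @return an [EntropyResult-class].
#' @export
computeEntropy <- function(hist, logBase = 2,
                           formula = c("shannon", "printed")) {
  formula <- match.arg(formula)
  stopifnot(is(hist, "IntensityHistogram"))
  validObject(hist)
  p <- hist@p
  if (formula == "shannon") {
    pp <- p[p > 0]
    h <- -sum(pp * log(pp)) / log(logBase)
    h <- max(h, 0) + 0                  # clip rounding; drop IEEE -0
  } else {
    if (any(p >= 1)) {
      warning("printed-formula entropy diverges when a bin holds all mass")
      h <- Inf
    } else {
      pp <- p[p > 0]
      h <- -sum(pp * log(1 - pp)) / log(logBase)
    }
  }
  new("EntropyResult", entropy = h, nPixels = sum(hist@counts),
      nBins = length(hist@p), logBase = as.numeric(logBase),
      formula = formula)
}

#' Entropy of a masked image in one call
#'
#' Composition of [extractPixels()], [buildHistogram()] and
#' [computeEntropy()]: the per-image entry point used by the pipeline and
#' the command-line wrapper.
#'
#' @inheritParams extractPixels
#' @inheritParams buildHistogram
#' @inheritParams computeEntropy
#' @return an [EntropyResult-class].
#' @export
entropyFromImage <- function(image, myocardiumMask = NULL,
                             bloodpoolMask = NULL, nBins = 128L,
                             logBase = 2,
                             formula = c("shannon", "printed")) {
  sample <- extractPixels(image, myocardiumMask, bloodpoolMask)
  computeEntropy(buildHistogram(sample, nBins = nBins),
                 logBase = logBase, formula = match.arg(formula))
}
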