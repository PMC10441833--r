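#' @import methods
#' @importFrom stats median rnorm rexp runif sd var lm pchisq pt qnorm
#'   t.test chisq.test cor complete.cases quantile setNames predict
NULL

#' Phantom specification
#'
#' Parameters of a synthetic short-axis LGE-style phantom: a myocardial ring
#' (annulus) surrounding a blood pool, with Gaussian tissue heterogeneity, an
#' optional focal hyperenhanced scar, and an optional noise model.
#'
#' @slot gridSize pixels per side of the square grid.
#' @slot innerRadius,outerRadius ring bounds in pixels;
#'   \code{0 < innerRadius < outerRadius < gridSize/2}.
#' @slot nSlices number of short-axis slices.
#' @slot spacing mm per pixel (isotropic in-plane).
#' @slot baseIntensity mean myocardial signal, arbitrary units.
#' @slot heterogeneitySigma SD of myocardial intensity variation (>= 0).
#' @slot scarFraction target fraction of myocardial pixels hyperenhanced,
#'   in [0, 1].
#' @slot scarIntensityMultiplier scar intensity as a multiple of
#'   \code{baseIntensity} (> 1).
#' @slot scarMode \code{"sector"} (contiguous angular sector, the focal
#'   morphology FWHM assumes) or \code{"scattered"}.
#' @slot noiseModel \code{"none"}, \code{"gaussian"} or \code{"rician"}.
#' @slot noiseSd SD of the noise model, arbitrary units.
#' @slot seed integer seed; identical specs reproduce bit-identical phantoms.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    gridSize = "integer", innerRadius = "numeric", outerRadius = "numeric",
    nSlices = "integer", spacing = "numeric", baseIntensity = "numeric",
    heterogeneitySigma = "numeric", scarFraction = "numeric",
    scarIntensityMultiplier = "numeric", scarMode = "character",
    noiseModel = "character", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@gridSize < 8) msg <- c(msg, "gridSize must be >= 8")
  if (!(object@innerRadius > 0 &&
        object@innerRadius < object@outerRadius &&
        object@outerRadius < object@gridSize / 2))
    msg <- c(msg, "need 0 < innerRadius < outerRadius < gridSize/2")
  if (object@scarFraction < 0 || object@scarFraction > 1)
    msg <- c(msg, "scarFraction must lie in [0, 1]")
  if (object@heterogeneitySigma < 0)
    msg <- c(msg, "heterogeneitySigma must be >= 0")
  if (object@scarIntensityMultiplier <= 1)
    msg <- c(msg, "scarIntensityMultiplier must be > 1")
  if (!object@scarMode %in% c("sector", "scattered"))
    msg <- c(msg, "scarMode must be 'sector' or 'scattered'")
  if (!object@noiseModel %in% c("none", "gaussian", "rician"))
    msg <- c(msg, "noiseModel must be 'none', 'gaussian' or 'rician'")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nSlices < 1) msg <- c(msg, "nSlices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Phantom image with aligned label masks
#'
#' A grayscale pixel grid (2D matrix or 3D array) with pairwise-disjoint
#' boolean masks for myocardium and blood pool, and a scar truth mask that is
#' a subset of the myocardium.
#'
#' @slot pixels nonnegative intensity array.
#' @slot spacing mm per pixel.
#' @slot myocardiumMask,bloodpoolMask,scarTruthMask logical arrays with the
#'   shape of \code{pixels}.
#' @export
setClass("PhantomImage",
  representation(
    pixels = "array", spacing = "numeric",
    myocardiumMask = "array", bloodpoolMask = "array",
    scarTruthMask = "array"
  )
)

setValidity("PhantomImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  for (nm in c("myocardiumMask", "bloodpoolMask", "scarTruthMask")) {
    m <- slot(object, nm)
    if (!identical(dim(m), d))
      msg <- c(msg, sprintf("%s shape differs from pixels", nm))
    if (!is.logical(m)) msg <- c(msg, sprintf("%s must be logical", nm))
  }
  if (!length(msg)) {
    if (any(object@myocardiumMask & object@bloodpoolMask))
      msg <- c(msg, "myocardium and blood-pool masks overlap")
    if (any(object@scarTruthMask & !object@myocardiumMask))
      msg <- c(msg, "scar truth mask extends outside the myocardium")
  }
  if (any(object@pixels < 0)) msg <- c(msg, "pixel intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Cohort simulation specification
#'
#' Defines a simulated patient cohort: per-subject entropy drawn from a
#' normal distribution, an exponential proportional-hazards event process
#' whose log hazard is linear in entropy, independent exponential censoring
#' truncated at the end of follow-up, and correlated auxiliary covariates.
#'
#' @slot nSubjects number of subjects (>= 2).
#' @slot entropyMean,entropySd distribution of simulated entropy (bits).
#' @slot logHrPerUnitEntropy true Cox coefficient per 1.0 entropy unit.
#' @slot baselineHazard events per month at \code{entropy == entropyMean}.
#' @slot censoringRate censoring events per month (>= 0).
#' @slot maxFollowup administrative censoring time, months.
#' @slot primaryEventFraction fraction of composite (secondary) events that
#'   are also primary-endpoint events.
#' @slot covariateSpec list with \code{means}, \code{sds} and
#'   \code{corEntropy} (correlation of each auxiliary covariate with
#'   entropy); auxiliaries are conditionally independent given entropy.
#' @slot seed integer seed.
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer", entropyMean = "numeric", entropySd = "numeric",
    logHrPerUnitEntropy = "numeric", baselineHazard = "numeric",
    censoringRate = "numeric", maxFollowup = "numeric",
    primaryEventFraction = "numeric", covariateSpec = "list",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 2) msg <- c(msg, "nSubjects must be >= 2")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (object@censoringRate < 0) msg <- c(msg, "censoringRate must be >= 0")
  if (object@maxFollowup <= 0) msg <- c(msg, "maxFollowup must be > 0")
  if (object@entropySd < 0) msg <- c(msg, "entropySd must be >= 0")
  if (object@primaryEventFraction < 0 || object@primaryEventFraction > 1)
    msg <- c(msg, "primaryEventFraction must lie in [0, 1]")
  cs <- object@covariateSpec
  if (!all(c("means", "sds", "corEntropy") %in% names(cs)))
    msg <- c(msg, "covariateSpec needs 'means', 'sds', 'corEntropy'")
  if (length(msg)) msg else TRUE
})

#' Pixel sample pooled from a masked myocardium
#'
#' 1D nonnegative intensities at myocardial pixels (blood pool excluded),
#' pooled over all included slices.
#'
#' @slot intensities numeric vector of pixel values.
#' @slot nPixels its length.
#' @slot sourceId subject or image identifier.
#' @export
setClass("PixelSample",
  representation(intensities = "numeric", nPixels = "integer",
                 sourceId = "character")
)

setValidity("PixelSample", function(object) {
  msg <- character()
  if (object@nPixels != length(object@intensities))
    msg <- c(msg, "nPixels must equal length(intensities)")
  if (object@nPixels < 1) msg <- c(msg, "sample must contain >= 1 pixel")
  if (any(object@intensities < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Binned intensity probability distribution
#'
#' Holds the probability vector p_i that the entropy statistic consumes.
#'
#' @slot binEdges B+1 strictly increasing edges; right-most bin closed.
#' @slot counts B nonnegative integer counts.
#' @slot p B probabilities, counts / total, summing to 1.
#' @export
setClass("IntensityHistogram",
  representation(binEdges = "numeric", counts = "integer", p = "numeric")
)

setValidity("IntensityHistogram", function(object) {
  msg <- character()
  b <- length(object@counts)
  if (length(object@binEdges) != b + 1)
    msg <- c(msg, "need length(binEdges) == length(counts) + 1")
  if (length(object@p) != b) msg <- c(msg, "p and counts lengths differ")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (abs(sum(object@p) - 1) > 1e-12) msg <- c(msg, "p must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Entropy result
#'
#' @slot entropy entropy of the intensity histogram, in the chosen log base
#'   (bits for base 2).
#' @slot nPixels,nBins sample size and histogram resolution.
#' @slot logBase 2 or exp(1).
#' @slot formula "shannon" (default) or "printed" (see [computeEntropy()]).
#' @export
setClass("EntropyResult",
  representation(entropy = "numeric", nPixels = "integer", nBins = "integer",
                 logBase = "numeric", formula = "character")
)

setValidity("EntropyResult", function(object) {
  if (object@formula == "shannon" &&
      is.finite(object@entropy) &&
      (object@entropy < -1e-9 ||
       object@entropy > log(object@nBins) / log(object@logBase) + 1e-9))
    "entropy must lie in [0, log(nBins)] in the chosen base" else TRUE
})

#' FWHM scar quantification result
#'
#' @slot lgePct percent of myocardial pixels classified hyperenhanced,
#'   in [0, 100].
#' @slot thresholdUsed intensity threshold applied (half the maximal
#'   myocardial signal by default).
#' @slot gateApplied whether the remote-reference gate was in effect.
#' @export
setClass("ScarResult",
  representation(lgePct = "numeric", thresholdUsed = "numeric",
                 gateApplied = "logical")
)

setValidity("ScarResult", function(object) {
  if (object@lgePct < 0 || object@lgePct > 100)
    "lgePct must lie in [0, 100]" else TRUE
})

#' Kaplan-Meier curve
#'
#' Product-limit estimates at event times, plus the full step function
#' (including censoring times) for rendering.
#'
#' @slot eventTimes ascending times at which events occurred.
#' @slot survival product-limit survival just after each event time.
#' @slot atRisk number at risk at each event time.
#' @slot steps data.frame with \code{time}, \code{nRisk}, \code{nEvent},
#'   \code{survival} at every distinct observed time.
#' @export
setClass("KMCurve",
  representation(eventTimes = "numeric", survival = "numeric",
                 atRisk = "numeric", steps = "data.frame")
)

setValidity("KMCurve", function(object) {
  s <- object@survival
  msg <- character()
  if (length(s) && (any(s < -1e-12) || any(s > 1 + 1e-12)))
    msg <- c(msg, "survival must lie in [0, 1]")
  if (length(s) > 1 && any(diff(s) > 1e-12))
    msg <- c(msg, "survival must be nonincreasing")
  if (is.unsorted(object@eventTimes))
    msg <- c(msg, "eventTimes must be ascending")
  if (length(msg)) msg else TRUE
})

#' Cox proportional-hazards fit
#'
#' @slot coefficients log-hazard ratios per covariate unit.
#' @slot se standard errors from the observed information.
#' @slot hazardRatios matrix with columns \code{hr}, \code{lower},
#'   \code{upper} (Wald 95\% CI, exp(beta +/- 1.96 se)).
#' @slot pValues two-sided Wald p-values.
#' @slot converged whether the partial-likelihood maximization converged
#'   without a monotone-likelihood warning.
#' @slot nEvents,n events and subjects used.
#' @slot endpoint which endpoint was modelled.
#' @slot model underlying fit object (used for linear predictors and the
#'   baseline cumulative hazard).
#' @export
setClass("CoxFitResult",
  representation(
    coefficients = "numeric", se = "numeric", hazardRatios = "matrix",
    pValues = "numeric", converged = "logical", nEvents = "integer",
    n = "integer", endpoint = "character", model = "ANY"
  )
)

setValidity("CoxFitResult", function(object) {
  hr <- object@hazardRatios
  ok <- is.finite(hr[, "hr"])
  if (any(hr[ok, "lower"] > hr[ok, "hr"] + 1e-12) ||
      any(hr[ok, "upper"] < hr[ok, "hr"] - 1e-12))
    "CI bounds must bracket the hazard ratio" else TRUE
})

#' Discrimination and reclassification statistics
#'
#' Harrell C-indices of a base and an extended risk model, with continuous
#' (category-free) NRI and IDI comparing predicted event probabilities at a
#' fixed horizon, each with percentile bootstrap 95\% CIs.
#'
#' @slot cIndexBase,cIndexExt concordance of each model's linear predictor.
#' @slot nri,nriCI,idi,idiCI point estimates and CIs.
#' @slot horizonMonths risk-prediction horizon.
#' @slot bootReps bootstrap replicates used for the CIs.
#' @export
setClass("ReclassStats",
  representation(
    cIndexBase = "numeric", cIndexExt = "numeric",
    nri = "numeric", nriCI = "numeric", idi = "numeric", idiCI = "numeric",
    horizonMonths = "numeric", bootReps = "integer"
  )
)

setValidity("ReclassStats", function(object) {
  msg <- character()
  if (object@cIndexBase < 0 || object@cIndexBase > 1 ||
      object@cIndexExt < 0 || object@cIndexExt > 1)
    msg <- c(msg, "C-indices must lie in [0, 1]")
  if (abs(object@nri) > 2 + 1e-12) msg <- c(msg, "NRI must lie in [-2, 2]")
  if (abs(object@idi) > 1 + 1e-12) msg <- c(msg, "IDI must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' End-to-end study report
#'
#' Per-stage result tables of the synthetic study replica, plus a
#' provenance block (seed, canonical config JSON and its fingerprint).
#'
#' @slot groups group-comparison table by event status.
#' @slot correlations Pearson correlations of entropy with LV parameters.
#' @slot km long-format KM step functions per endpoint and entropy group.
#' @slot logrank log-rank statistics per endpoint.
#' @slot unicox,multicox univariate and multivariable Cox tables.
#' @slot selection univariate p < 0.1 selection trace with collinearity
#'   screen results.
#' @slot reclass model-improvement table (C-index, NRI, IDI).
#' @slot cohort the simulated cohort analysed.
#' @slot provenance list: seed, configJSON, configHash, packageVersion.
#' @export
setClass("StudyReport",
  representation(
    groups = "data.frame", correlations = "data.frame", km = "data.frame",
    logrank = "data.frame", unicox = "data.frame", multicox = "data.frame",
    selection = "data.frame", reclass = "data.frame", cohort = "data.frame",
    provenance = "list"
  )
)
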