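#' @describeIn EntropyResult-class the entropy value.
#' @param object an object of the documented class.
#' @export
setGeneric("entropyValue", function(object) standardGeneric("entropyValue"))

#' @rdname EntropyResult-class
#' @export
setMethod("entropyValue", "EntropyResult", function(object) object@entropy)

#' @describeIn ScarResult-class hyperenhanced percentage of the myocardium.
#' @export
setGeneric("lgePercent", function(object) standardGeneric("lgePercent"))

#' @rdname ScarResult-class
#' @export
setMethod("lgePercent", "ScarResult", function(object) object@lgePct)

#' @describeIn IntensityHistogram-class probability vector p_i.
#' @export
setGeneric("probabilities", function(object)
  standardGeneric("probabilities"))

#' @rdname IntensityHistogram-class
#' @export
setMethod("probabilities", "IntensityHistogram", function(object) object@p)

#' Build an intensity histogram directly from probabilities
#'
#' Convenience constructor for closed-form checks: fabricates unit-width
#' bin edges and integer counts proportional to \code{p}.
#'
#' @param p probability vector (nonnegative, summing to 1).
#' @param scale count scale factor (counts = round(p * scale)).
#' @return an [IntensityHistogram-class].
#' @export
histogramFromProbs <- function(p, scale = 1e6) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    lgeError("p must be nonnegative and sum to 1", "parameterError")
  counts <- as.integer(round(p * scale))
  new("IntensityHistogram", binEdges = seq(0, length(p)),
      counts = counts, p = counts / sum(counts))
}

#' @describeIn PhantomImage-class the pixel intensity array.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname PhantomImage-class
#' @export
setMethod("pixels", "PhantomImage", function(object) object@pixels)

#' @describeIn PhantomImage-class the myocardium mask.
#' @export
setGeneric("myocardiumMask", function(object)
  standardGeneric("myocardiumMask"))

#' @rdname PhantomImage-class
#' @export
setMethod("myocardiumMask", "PhantomImage",
          function(object) object@myocardiumMask)

#' @describeIn PhantomImage-class the blood-pool mask.
#' @export
setGeneric("bloodpoolMask", function(object)
  standardGeneric("bloodpoolMask"))

#' @rdname PhantomImage-class
#' @export
setMethod("bloodpoolMask", "PhantomImage",
          function(object) object@bloodpoolMask)

#' @describeIn PhantomImage-class the scar truth mask.
#' @export
setGeneric("scarTruthMask", function(object)
  standardGeneric("scarTruthMask"))

#' @rdname PhantomImage-class
#' @export
setMethod("scarTruthMask", "PhantomImage",
          function(object) object@scarTruthMask)

#' @describeIn CoxFitResult-class hazard-ratio matrix (hr, lower, upper).
#' @export
setGeneric("hazardRatios", function(object) standardGeneric("hazardRatios"))

#' @rdname CoxFitResult-class
#' @export
setMethod("hazardRatios", "CoxFitResult",
          function(object) object@hazardRatios)

#' @rdname CoxFitResult-class
#' @param ... unused.
#' @export
setMethod("coef", "CoxFitResult", function(object, ...)
  object@coefficients)

setMethod("show", "PhantomImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PhantomImage %s, spacing %.2f mm/px\n",
              paste(d, collapse = " x "), object@spacing))
  cat(sprintf("  myocardium %d px | blood pool %d px | scar %d px\n",
              sum(object@myocardiumMask), sum(object@bloodpoolMask),
              sum(object@scarTruthMask)))
})

setMethod("show", "EntropyResult", function(object) {
  unit <- if (object@logBase == 2) "bits" else "nats"
  cat(sprintf("LV entropy: %.4f %s (%d pixels, %d bins, %s formula)\n",
              object@entropy, unit, object@nPixels, object@nBins,
              object@formula))
})

setMethod("show", "ScarResult", function(object) {
  cat(sprintf("FWHM LGE extent: %.2f%% (threshold %.2f%s)\n",
              object@lgePct, object@thresholdUsed,
              if (object@gateApplied) ", remote gate applied" else ""))
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("Kaplan-Meier curve: %d event times, final survival %.3f\n",
              length(object@eventTimes),
              if (length(object@survival)) min(object@survival) else 1))
})

setMethod("show", "CoxFitResult", function(object) {
  cat(sprintf("Cox model (%s endpoint): %d subjects, %d events%s\n",
              object@endpoint, object@n, object@nEvents,
              if (object@converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(
    coef = round(object@coefficients, 4), se = round(object@se, 4),
    HR = round(object@hazardRatios[, "hr"], 3),
    CI = sprintf("(%.3f, %.3f)", object@hazardRatios[, "lower"],
                 object@hazardRatios[, "upper"]),
    p = signif(object@pValues, 3))
  print(tab)
})

setMethod("show", "ReclassStats", function(object) {
  cat(sprintf("C-index: base %.3f -> extended %.3f\n",
              object@cIndexBase, object@cIndexExt))
  cat(sprintf("NRI %.3f (%.3f, %.3f); IDI %.3f (%.3f, %.3f); %d-month horizon\n",
              object@nri, object@nriCI[1], object@nriCI[2],
              object@idi, object@idiCI[1], object@idiCI[2],
              as.integer(object@horizonMonths)))
})

setMethod("show", "StudyReport", function(object) {
  ran <- vapply(c("groups", "correlations", "km", "logrank", "unicox",
                  "multicox", "reclass"),
                function(nm) nrow(slot(object, nm)) > 0, logical(1))
  cat("StudyReport; stages with results:",
      paste(names(ran)[ran], collapse = ", "), "\n")
  cat(sprintf("  cohort n = %d, seed = %s\n", nrow(object@cohort),
              object@provenance$seed))
})
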