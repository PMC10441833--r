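#' Harrell concordance index
#'
#' Fraction of usable subject pairs in which the subject with the higher
#' risk score fails first. A pair is usable when its ordering is
#' determinable under right censoring: the two observed times differ and
#' the shorter time ended in an event. Ties in risk score count 0.5.
#'
#' @param times observed follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param riskScores higher = predicted to fail earlier.
#' @return the C-index in [0, 1].
#' @export
harrellCindex <- function(times, events, riskScores) {
  n <- length(times)
  stopifnot(length(events) == n, length(riskScores) == n)
  events <- as.integer(events)
  # usable pair (i, j): times[i] < times[j] and subject i had the event
  earlier <- outer(times, times, "<")
  usable <- earlier & (events == 1L)
  nUsable <- sum(usable)
  if (nUsable == 0)
    lgeError("no usable pairs under censoring", "undefinedValueError")
  riskDiff <- outer(riskScores, riskScores, "-")
  concordant <- sum(usable & riskDiff > 0) + 0.5 * sum(usable & riskDiff == 0)
  concordant / nUsable
}

bootCI <- function(stat, n, bootReps, seed, conf = 0.95) {
  # percentile bootstrap over subject indices; stat(idx) may return NA for
  # degenerate resamples (e.g. no events), which are dropped
  reps <- withSeed(if (is.null(seed)) sample.int(2^31 - 1, 1) else seed, {
    vapply(seq_len(bootReps),
           function(i) stat(sample.int(n, n, replace = TRUE)), numeric(1))
  })
  a <- (1 - conf) / 2
  unname(quantile(reps, c(a, 1 - a), na.rm = TRUE, type = 7))
}

#' Continuous (category-free) net reclassification improvement
#'
#' \deqn{NRI = [P(up|event) - P(down|event)] +
#'            [P(down|nonevent) - P(up|nonevent)]}
#' where "up"/"down" mean the extended model moved a subject's predicted
#' risk strictly up/down relative to the base model. Bounded in [-2, 2];
#' 2 when the extended model raises every event's risk and lowers every
#' non-event's. The CI is a seeded percentile bootstrap over subjects.
#'
#' @param riskBase,riskExt predicted risks under the base and extended
#'   models.
#' @param events event indicators.
#' @param bootReps bootstrap replicates (default 1000); 0 skips the CI.
#' @param seed bootstrap seed.
#' @return list with \code{nri}, \code{ci}, and the four movement
#'   probabilities.
#' @export
nriContinuous <- function(riskBase, riskExt, events, bootReps = 1000L,
                          seed = NULL) {
  events <- as.logical(events)
  n <- length(events)
  stopifnot(length(riskBase) == n, length(riskExt) == n)
  if (!any(events) || all(events))
    lgeError("need at least one event and one non-event", "inputError")
  pointNri <- function(idx) {
    e <- events[idx]
    up <- riskExt[idx] > riskBase[idx]
    down <- riskExt[idx] < riskBase[idx]
    if (!any(e) || all(e)) return(NA_real_)
    (mean(up[e]) - mean(down[e])) + (mean(down[!e]) - mean(up[!e]))
  }
  all_idx <- seq_len(n)
  est <- pointNri(all_idx)
  if (all(riskExt == riskBase))
    message("no risk movement between models; NRI is 0")
  ci <- if (bootReps > 0) bootCI(pointNri, n, bootReps, seed) else
    c(NA_real_, NA_real_)
  up <- riskExt > riskBase; down <- riskExt < riskBase
  list(nri = est, ci = ci,
       pUpEvent = mean(up[events]), pDownEvent = mean(down[events]),
       pUpNonevent = mean(up[!events]), pDownNonevent = mean(down[!events]))
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slope between models:
#' \deqn{IDI = [\bar r_{ext}^{event} - \bar r_{base}^{event}] -
#'             [\bar r_{ext}^{nonevent} - \bar r_{base}^{nonevent}]}
#' i.e. how much further apart the extended model pushes the mean
#' predicted risks of events and non-events. Bootstrap CI as in
#' [nriContinuous()].
#'
#' @inheritParams nriContinuous
#' @return list with \code{idi} and \code{ci}.
#' @export
idiContinuous <- function(riskBase, riskExt, events, bootReps = 1000L,
                          seed = NULL) {
  events <- as.logical(events)
  n <- length(events)
  stopifnot(length(riskBase) == n, length(riskExt) == n)
  if (!any(events) || all(events))
    lgeError("need at least one event and one non-event", "inputError")
  pointIdi <- function(idx) {
    e <- events[idx]
    if (!any(e) || all(e)) return(NA_real_)
    (mean(riskExt[idx][e]) - mean(riskBase[idx][e])) -
      (mean(riskExt[idx][!e]) - mean(riskBase[idx][!e]))
  }
  est <- pointIdi(seq_len(n))
  ci <- if (bootReps > 0) bootCI(pointIdi, n, bootReps, seed) else
    c(NA_real_, NA_real_)
  list(idi = est, ci = ci)
}

# Breslow cumulative baseline hazard of a CoxFitResult at a horizon,
# matched to centred linear predictors (predict(type = "lp")).
baselineCumHaz <- function(coxFit, horizonMonths) {
  bh <- basehaz(coxFit@model, centered = TRUE)
  idx <- which(bh$time <= horizonMonths)
  if (!length(idx)) 0 else bh$hazard[max(idx)]
}

#' Predicted event probability at a horizon
#'
#' \code{1 - exp(-H0(t) * exp(lp))} with H0 the Breslow baseline
#' cumulative hazard and lp the model's (centred) linear predictor.
#'
#' @param coxFit a [CoxFitResult-class].
#' @param cohort cohort to predict for.
#' @param horizonMonths prediction horizon in months.
#' @return vector of event probabilities.
#' @export
predictedRisk <- function(coxFit, cohort, horizonMonths = 24) {
  lp <- unname(predict(coxFit@model, newdata = cohort, type = "lp"))
  1 - exp(-baselineCumHaz(coxFit, horizonMonths) * exp(lp))
}

#' Incremental value of one covariate over a base risk model
#'
#' Fits a base Cox model and an extended model (base + one added
#' covariate) on the same cohort and endpoint, then quantifies the
#' improvement three ways: Harrell C-index of each model's linear
#' predictor, and continuous NRI and IDI on predicted event probabilities
#' at a fixed horizon (default 24 months) from the Breslow baseline-hazard
#' estimator, with seeded percentile-bootstrap CIs.
#'
#' @inheritParams fitCox
#' @param baseCovariates covariates of the base model.
#' @param addedCovariate covariate whose incremental value is assessed.
#' @param horizonMonths risk horizon for NRI/IDI.
#' @param bootReps bootstrap replicates for the CIs.
#' @param seed bootstrap seed.
#' @return a [ReclassStats-class].
#' @export
modelImprovement <- function(cohort, baseCovariates, addedCovariate,
                             endpoint = c("secondary", "primary"),
                             horizonMonths = 24, bootReps = 1000L,
                             seed = NULL) {
  endpoint <- match.arg(endpoint)
  evCol <- endpointColumn(endpoint)
  fitBase <- fitCox(cohort, baseCovariates, endpoint = endpoint)
  fitExt <- fitCox(cohort, unique(c(baseCovariates, addedCovariate)),
                   endpoint = endpoint)
  lpBase <- unname(predict(fitBase@model, type = "lp"))
  lpExt <- unname(predict(fitExt@model, type = "lp"))
  times <- cohort$time_months
  events <- cohort[[evCol]]
  cBase <- harrellCindex(times, events, lpBase)
  cExt <- harrellCindex(times, events, lpExt)
  rBase <- predictedRisk(fitBase, cohort, horizonMonths)
  rExt <- predictedRisk(fitExt, cohort, horizonMonths)
  nri <- nriContinuous(rBase, rExt, events, bootReps = bootReps,
                       seed = seed)
  idi <- idiContinuous(rBase, rExt, events, bootReps = bootReps,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  new("ReclassStats", cIndexBase = cBase, cIndexExt = cExt,
      nri = nri$nri, nriCI = nri$ci, idi = idi$idi, idiCI = idi$ci,
      horizonMonths = horizonMonths, bootReps = as.integer(bootReps))
}
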