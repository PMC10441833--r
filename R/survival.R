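#' @importFrom survival Surv survfit survdiff coxph coxph.control basehaz
NULL

endpointColumn <- function(endpoint) {
  switch(match.arg(endpoint, c("secondary", "primary")),
         primary = "event_primary", secondary = "event_secondary")
}

#' Compare covariates between two groups
#'
#' Welch (unequal-variance) two-sample t-test for continuous covariates
#' and a chi-square test for categorical ones, one row per covariate --
#' the standard baseline-characteristics table comparing, e.g., subjects
#' with and without events.
#'
#' @param cohort a cohort data.frame.
#' @param groupFlag logical or 0/1 vector, one per subject.
#' @param covariates covariate columns to test; defaults to every numeric
#'   column except identifiers, times and event flags.
#' @return a data.frame with covariate, test type, group means (or
#'   proportions), statistic and p-value.
#' @export
compareGroups <- function(cohort, groupFlag, covariates = NULL) {
  g <- as.logical(groupFlag)
  if (length(g) != nrow(cohort))
    lgeError("groupFlag length must match the cohort", "inputError")
  if (sum(g) < 2 || sum(!g) < 2)
    lgeError("each group needs at least 2 subjects",
             "insufficientDataError")
  if (is.null(covariates)) {
    skip <- c("subject_id", "time_months", "event_primary",
              "event_secondary")
    covariates <- setdiff(names(cohort), skip)
  }
  rows <- lapply(covariates, function(nm) {
    x <- cohort[[nm]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      if (stats::var(x[g]) + stats::var(x[!g]) == 0) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- t.test(x[g], x[!g])
      }
      data.frame(covariate = nm, type = "t",
                 mean_group1 = mean(x[g]), mean_group0 = mean(x[!g]),
                 statistic = unname(tt$statistic),
                 p = unname(tt$p.value))
    } else {
      tab <- table(factor(g, c(FALSE, TRUE)), x)
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      data.frame(covariate = nm, type = "chisq",
                 mean_group1 = if (is.numeric(x)) mean(x[g]) else NA_real_,
                 mean_group0 = if (is.numeric(x)) mean(x[!g]) else NA_real_,
                 statistic = unname(ct$statistic),
                 p = unname(ct$p.value))
    }
  })
  do.call(rbind, rows)
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return a list with \code{r}, \code{p} (two-sided, from the t
#'   transform) and \code{n}.
#' @export
pearsonCorr <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) lgeError("need n >= 3", "insufficientDataError")
  if (sd(x) == 0 || sd(y) == 0)
    lgeError("correlation undefined for a constant vector",
             "undefinedValueError")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator. With no events (all censored)
#' the curve is flat at 1 and \code{eventTimes} is empty.
#'
#' @param times follow-up times (> 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return a [KMCurve-class].
#' @export
kmEstimate <- function(times, events) {
  if (any(times <= 0) || anyNA(times))
    lgeError("times must be positive and non-missing", "inputError")
  fit <- survfit(Surv(times, as.integer(events)) ~ 1)
  ev <- fit$n.event > 0
  new("KMCurve",
      eventTimes = fit$time[ev], survival = fit$surv[ev],
      atRisk = fit$n.risk[ev],
      steps = data.frame(time = fit$time, nRisk = fit$n.risk,
                         nEvent = fit$n.event, survival = fit$surv))
}

#' Two-sample log-rank test
#'
#' Observed-vs-expected chi-square on the pooled event times, 1 df.
#'
#' @param timesA,eventsA,timesB,eventsB follow-up times and event flags of
#'   the two arms.
#' @return list with \code{statistic} (chi-square), \code{p}, and the
#'   per-arm observed and expected event counts.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (sum(eventsA) + sum(eventsB) == 0)
    lgeError("log-rank test undefined with no events",
             "undefinedValueError")
  time <- c(timesA, timesB)
  event <- as.integer(c(eventsA, eventsB))
  arm <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd_ <- survdiff(Surv(time, event) ~ arm)
  stat <- unname(sd_$chisq)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Median dichotomization
#'
#' Splits the cohort at the median of a covariate; ties go to the high
#' group (high = value >= median). With an all-equal covariate every
#' subject lands in the high group and a degenerate-split warning is
#' raised.
#'
#' @param cohort a cohort data.frame.
#' @param covariateName column to split on.
#' @return logical vector, TRUE for the high group.
#' @export
medianSplit <- function(cohort, covariateName) {
  if (!covariateName %in% names(cohort))
    lgeError(sprintf("covariate '%s' not present", covariateName),
             "inputError")
  x <- cohort[[covariateName]]
  med <- median(x)
  high <- x >= med
  if (all(high) || !any(high))
    warning("degenerate split: all subjects fall in one group")
  high
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Efron tie handling (Breslow
#' behind the \code{ties} flag), reporting coefficients, standard errors
#' from the observed information, two-sided Wald p-values, and hazard
#' ratios with Wald 95\% CIs exp(beta +/- 1.96 se). Non-convergence and
#' monotone-likelihood (complete-separation) conditions are flagged in
#' \code{converged}, never silent.
#'
#' @param cohort a cohort data.frame.
#' @param covariateNames covariates to include.
#' @param endpoint "secondary" (composite, default) or "primary".
#' @param ties "efron" (default) or "breslow".
#' @return a [CoxFitResult-class].
#' @export
fitCox <- function(cohort, covariateNames,
                   endpoint = c("secondary", "primary"),
                   ties = c("efron", "breslow")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  evCol <- endpointColumn(endpoint)
  if (sum(cohort[[evCol]]) < 1)
    lgeError("Cox model needs at least one event",
             "insufficientDataError")
  for (nm in covariateNames) {
    if (!nm %in% names(cohort))
      lgeError(sprintf("covariate '%s' not present", nm), "inputError")
    if (length(unique(cohort[[nm]])) < 2L)
      lgeError(sprintf("covariate '%s' is constant", nm), "inputError")
  }
  fml <- stats::as.formula(paste(
    sprintf("Surv(time_months, %s) ~", evCol),
    paste(covariateNames, collapse = " + ")))
  monotone <- FALSE
  fit <- withCallingHandlers(
    coxph(fml, data = cohort, ties = ties,
          control = coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converged", conditionMessage(w))) {
        monotone <<- TRUE
        if (grepl("infinite", conditionMessage(w)))
          warning(warningCondition(
            paste("monotone likelihood:", conditionMessage(w)),
            class = "monotoneLikelihoodWarning"))
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  names(se) <- names(beta)
  z <- beta / se
  hr <- cbind(hr = exp(beta), lower = exp(beta - 1.96 * se),
              upper = exp(beta + 1.96 * se))
  rownames(hr) <- names(beta)
  new("CoxFitResult",
      coefficients = beta, se = se, hazardRatios = hr,
      pValues = setNames(2 * stats::pnorm(-abs(z)), names(beta)),
      converged = !monotone && fit$iter < 100,
      nEvents = as.integer(sum(cohort[[evCol]])),
      n = as.integer(nrow(cohort)), endpoint = endpoint, model = fit)
}

#' Collinearity screen: tolerance and VIF
#'
#' For each covariate j, regresses it on the remaining covariates;
#' \code{VIF_j = 1 / (1 - R^2_j)} and \code{Tol_j = 1 / VIF_j}. A
#' covariate passes when Tol > 0.1 and VIF < 10. Perfect collinearity
#' yields an infinite VIF and a failed screen, not an error.
#'
#' @param cohort a cohort data.frame.
#' @param covariateNames at least two covariates; n must exceed their
#'   count + 1.
#' @return data.frame with covariate, r2, tolerance, vif, pass.
#' @export
collinearityScreen <- function(cohort, covariateNames) {
  if (length(covariateNames) < 2L)
    lgeError("screen needs >= 2 covariates", "inputError")
  if (nrow(cohort) <= length(covariateNames) + 1L)
    lgeError("too few subjects for the screen", "insufficientDataError")
  X <- as.matrix(cohort[covariateNames])
  rows <- lapply(seq_along(covariateNames), function(j) {
    r2 <- suppressWarnings(          # summary.lm warns on a perfect fit
      summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    tol <- 1 - r2
    vif <- if (tol < 1e-12) Inf else 1 / tol
    data.frame(covariate = covariateNames[j], r2 = r2, tolerance = tol,
               vif = vif, pass = tol > 0.1 & vif < 10)
  })
  do.call(rbind, rows)
}

#' Univariate screening then multivariable Cox fit
#'
#' The variable-selection rule of the study workflow: a univariate Cox
#' model per candidate, retention of candidates with p < \code{alpha}
#' (default 0.1), a tolerance/VIF collinearity screen on the retained set,
#' then one multivariable model. When the screen fails, the covariate with
#' the largest VIF is dropped (with a warning) and the screen repeated
#' until it passes. The selection trace records every candidate's
#' univariate result and fate.
#'
#' @inheritParams fitCox
#' @param candidateNames candidate covariates.
#' @param alpha univariate retention threshold (default 0.1).
#' @return a list with \code{trace} (per-candidate univariate table with
#'   \code{retained}), \code{screen} (collinearity table or NULL),
#'   \code{droppedCollinear}, \code{retained}, and \code{fit} (a
#'   [CoxFitResult-class], or NULL when nothing passed the rule).
#' @export
selectMultivariable <- function(cohort, candidateNames,
                                endpoint = c("secondary", "primary"),
                                alpha = 0.1, ties = c("efron", "breslow")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  if (!length(candidateNames))
    lgeError("no candidates supplied", "inputError")
  uni <- lapply(candidateNames, function(nm) {
    f <- fitCox(cohort, nm, endpoint = endpoint, ties = ties)
    data.frame(candidate = nm, coef = unname(f@coefficients),
               hr = unname(f@hazardRatios[1, "hr"]),
               hr_lower = unname(f@hazardRatios[1, "lower"]),
               hr_upper = unname(f@hazardRatios[1, "upper"]),
               p = unname(f@pValues))
  })
  trace <- do.call(rbind, uni)
  trace$retained <- trace$p < alpha
  retained <- trace$candidate[trace$retained]
  dropped <- character()
  screen <- NULL
  if (length(retained) >= 2L) {
    repeat {
      screen <- collinearityScreen(cohort, retained)
      if (all(screen$pass)) break
      worst <- screen$covariate[which.max(screen$vif)]
      warning(sprintf(
        "dropping '%s' from the multivariable model (VIF = %.3g)",
        worst, screen$vif[screen$covariate == worst]))
      dropped <- c(dropped, worst)
      retained <- setdiff(retained, worst)
      if (length(retained) < 2L) break
    }
  }
  fit <- if (length(retained) >= 1L)
    fitCox(cohort, retained, endpoint = endpoint, ties = ties)
  else NULL
  list(trace = trace, screen = screen, droppedCollinear = dropped,
       retained = retained, fit = fit)
}
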