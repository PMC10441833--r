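test_that("C-index hits its closed-form extremes", {
  t <- c(1, 2, 3, 4, 5)
  e <- rep(1, 5)
  expect_equal(harrellCindex(t, e, 5:1), 1)      # perfect ranking
  expect_equal(harrellCindex(t, e, 1:5), 0)      # perfectly wrong
  expect_equal(harrellCindex(t, e, rep(2, 5)), 0.5)  # all ties
})

test_that("C-index equals exhaustive pair enumeration under censoring", {
  set.seed(17)
  for (i in 1:100) {
    n <- 10
    t <- round(rexp(n, 0.1), 1)
    e <- rbinom(n, 1, 0.7)
    r <- sample(5, n, replace = TRUE)          # deliberate risk ties
    if (sum(e) == 0) next
    ok <- tryCatch(harrellCindex(t, e, r), error = function(err) NULL)
    if (is.null(ok)) next
    expect_identical(ok, bruteCindex(t, e, r))
  }
  expect_error(harrellCindex(c(1, 2), c(0, 1), c(1, 2)),
               class = "undefinedValueError")
})

test_that("C-index agrees with the survival package on tie-free data", {
  set.seed(23)
  t <- rexp(80); e <- rbinom(80, 1, 0.6); r <- rnorm(80)
  ours <- harrellCindex(t, e, r)
  ref <- survival::concordance(survival::Surv(t, e) ~ r,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("C-index is invariant under strictly monotone transforms", {
  set.seed(5)
  t <- rexp(50); e <- rbinom(50, 1, 0.5); r <- rnorm(50)
  c0 <- harrellCindex(t, e, r)
  expect_identical(harrellCindex(t, e, exp(r)), c0)
  expect_identical(harrellCindex(t, e, 3 * r - 7), c0)
})

test_that("NRI and IDI are zero for identical models and maximal for
           perfect reclassification", {
  set.seed(8)
  e <- rbinom(40, 1, 0.4)
  r <- runif(40)
  expect_equal(nriContinuous(r, r, e, bootReps = 0)$nri, 0)
  expect_equal(idiContinuous(r, r, e, bootReps = 0)$idi, 0)

  rExt <- ifelse(e == 1, r + 0.1, r - 0.1)
  expect_equal(nriContinuous(r, rExt, e, bootReps = 0)$nri, 2)

  # IDI worked example: constant base 0.5, extended 0.9/0.1
  base <- rep(0.5, 40)
  ext <- ifelse(e == 1, 0.9, 0.1)
  expect_equal(idiContinuous(base, ext, e, bootReps = 0)$idi, 0.8)
})

test_that("NRI matches a hand count of up/down movements", {
  e <-  c(1,   1,   1,   0,   0,   0,   0,   1,   0,   0)
  rb <- c(0.5, 0.3, 0.6, 0.2, 0.4, 0.1, 0.3, 0.2, 0.5, 0.6)
  re <- c(0.7, 0.2, 0.6, 0.1, 0.5, 0.1, 0.2, 0.4, 0.4, 0.5)
  # events: up {1,8}, down {2}, same {3} -> (2-1)/4 = 0.25
  # non-events: down {4,7,9,10}, up {5}, same {6} -> (4-1)/6 = 0.5
  got <- nriContinuous(rb, re, e, bootReps = 0)
  expect_equal(got$nri, 0.25 + 0.5)
  idiHand <- (mean(re[e == 1]) - mean(rb[e == 1])) -
    (mean(re[e == 0]) - mean(rb[e == 0]))
  expect_equal(idiContinuous(rb, re, e, bootReps = 0)$idi, idiHand)
})

test_that("NRI and IDI flip sign when the models are swapped", {
  set.seed(9)
  e <- rbinom(60, 1, 0.3)
  rb <- runif(60); re <- pmin(1, rb + rnorm(60, 0, 0.2))
  expect_equal(nriContinuous(re, rb, e, bootReps = 0)$nri,
               -nriContinuous(rb, re, e, bootReps = 0)$nri)
  expect_equal(idiContinuous(re, rb, e, bootReps = 0)$idi,
               -idiContinuous(rb, re, e, bootReps = 0)$idi)
})

test_that("bootstrap CIs are seeded and bracket the estimate", {
  set.seed(11)
  e <- rbinom(120, 1, 0.3)
  rb <- runif(120); re <- pmin(1, pmax(0, rb + ifelse(e, 0.15, -0.1)))
  a <- nriContinuous(rb, re, e, bootReps = 200, seed = 4)
  b <- nriContinuous(rb, re, e, bootReps = 200, seed = 4)
  expect_identical(a$ci, b$ci)
  expect_lte(a$ci[1], a$nri); expect_gte(a$ci[2], a$nri)
})

test_that("adding the true hazard driver improves every metric", {
  co <- generateCohort(cohortSpec(nSubjects = 400,
                                  logHrPerUnitEntropy = 1.2, seed = 41))
  rs <- modelImprovement(co, baseCovariates = c("age", "la_diam"),
                         addedCovariate = "entropy",
                         endpoint = "secondary", bootReps = 200,
                         seed = 42)
  expect_gt(rs@cIndexExt, rs@cIndexBase)
  expect_gt(rs@nri, 0)
  expect_gt(rs@idi, 0)
})

test_that("re-adding a base covariate leaves the model unchanged", {
  co <- generateCohort(cohortSpec(nSubjects = 300, seed = 43))
  rs <- modelImprovement(co, baseCovariates = c("age", "la_diam"),
                         addedCovariate = "age", endpoint = "secondary",
                         bootReps = 0)
  expect_equal(rs@cIndexBase, rs@cIndexExt)
  expect_equal(rs@nri, 0)
  expect_equal(rs@idi, 0)
})

test_that("a pure-noise addition yields CIs covering no improvement", {
  co <- nullCohortWithNoise(400, seed = 45)
  rs <- modelImprovement(co, baseCovariates = c("age", "la_diam"),
                         addedCovariate = "noise",
                         endpoint = "secondary", bootReps = 300,
                         seed = 46)
  expect_lt(abs(rs@cIndexExt - rs@cIndexBase), 0.1)
  expect_lte(rs@nriCI[1], 0 + 1e-9)
  expect_gte(rs@nriCI[2], 0 - 1e-9)
  expect_lte(rs@idiCI[1], rs@idi)
})
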