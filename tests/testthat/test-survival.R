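test_that("group comparison handles identical and separated groups", {
  x <- rep(c(1, 2, 3, 4, 6), 2)
  co <- data.frame(v = x)
  g <- rep(c(TRUE, FALSE), each = 5)
  out <- compareGroups(co, g, covariates = "v")
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)

  set.seed(1)
  co2 <- data.frame(v = c(rnorm(200, 0), rnorm(200, 2)))
  out2 <- compareGroups(co2, rep(c(TRUE, FALSE), each = 200),
                        covariates = "v")
  expect_lt(out2$p, 1e-3)

  # balanced 2x2 table has zero chi-square
  co3 <- data.frame(v = rep(c("a", "b"), 100))
  out3 <- compareGroups(co3, rep(c(TRUE, FALSE), each = 100),
                        covariates = "v")
  expect_equal(unname(out3$statistic), 0)
  expect_error(compareGroups(co, c(TRUE, rep(FALSE, 9)), "v"),
               class = "insufficientDataError")
})

test_that("Pearson correlation matches the sum-product formula", {
  x <- c(1, 2, 4, 5, 9)
  y <- c(2, 4, 5, 9, 14)
  # oracle: explicit Sigma-product computation + t transform
  n <- 5
  rOracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  tt <- rOracle * sqrt((n - 2) / (1 - rOracle^2))
  pOracle <- 2 * stats::pt(-abs(tt), n - 2)
  got <- pearsonCorr(x, y)
  expect_equal(got$r, rOracle, tolerance = 1e-12)
  expect_equal(got$p, pOracle, tolerance = 1e-12)

  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorr(x, -x)$r, -1)
  expect_error(pearsonCorr(x, rep(3, 5)), class = "undefinedValueError")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km@survival, c(2 / 3, 1 / 3, 0))

  # {(1,E),(2,C),(3,E),(4,E)}: 3/4; 3/4 * 1/2; 0
  km2 <- kmEstimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km2@eventTimes, c(1, 3, 4))
  expect_equal(km2@survival, c(3 / 4, 3 / 8, 0))
  expect_equal(km2@atRisk, c(4, 2, 1))

  allCens <- kmEstimate(c(2, 5, 7), c(0, 0, 0))
  expect_length(allCens@eventTimes, 0)
  expect_true(all(allCens@steps$survival == 1))
  expect_error(kmEstimate(c(0, 1), c(1, 1)), class = "inputError")
})

test_that("with no censoring KM equals the empirical survival function", {
  set.seed(4)
  t <- rexp(60)
  km <- kmEstimate(t, rep(1, 60))
  emp <- vapply(km@eventTimes, function(u) mean(t > u), numeric(1))
  expect_equal(km@survival, emp, tolerance = 1e-12)
})

test_that("log-rank matches the hand-tabulated O-E statistic", {
  tA <- c(2, 4, 6); eA <- c(1, 0, 1)
  tB <- c(1, 3, 5); eB <- c(1, 1, 0)
  got <- logrankTest(tA, eA, tB, eB)
  expect_equal(got$statistic, bruteLogrank(tA, eA, tB, eB),
               tolerance = 1e-9)

  # an arm compared with its exact copy
  same <- logrankTest(tA, eA, tA, eA)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrankTest(tA, c(0, 0, 0), tB, c(0, 0, 0)),
               class = "undefinedValueError")
})

test_that("median split sends ties to the high group", {
  co <- data.frame(v = c(1, 2, 3, 4))
  expect_equal(medianSplit(co, "v"), c(FALSE, FALSE, TRUE, TRUE))
  co2 <- data.frame(v = c(1, 2, 2, 4))
  expect_equal(medianSplit(co2, "v"), c(FALSE, TRUE, TRUE, TRUE))
  expect_warning(s <- medianSplit(data.frame(v = rep(5, 3)), "v"),
                 "degenerate")
  expect_true(all(s))
  co3 <- generateCohort(cohortSpec(nSubjects = 101, seed = 13))
  hi <- medianSplit(co3, "entropy")
  expect_lte(abs(sum(hi) - sum(!hi)), 1)
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  co <- data.frame(
    subject_id = letters[1:8], entropy = 0, lge_pct = 0, age = 0,
    la_diam = 0,
    time_months = c(1.5, 2.1, 3.3, 4.0, 5.2, 6.8, 7.5, 9.1),
    event_primary = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L),
    event_secondary = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L))
  co$x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  fit <- fitCox(co, "x")
  beta <- unname(coef(fit)[1])

  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, brutePartialLoglik, numeric(1),
               times = co$time_months, events = co$event_secondary,
               x = co$x)
  betaOracle <- grid[which.max(ll)]
  expect_lt(abs(beta - betaOracle), 1e-4 + 5e-5)
  # returned maximizer beats every grid point
  expect_gte(brutePartialLoglik(beta, co$time_months,
                                co$event_secondary, co$x),
             max(ll) - 1e-9)
  expect_true(fit@converged)
  expect_equal(unname(hazardRatios(fit)[1, "hr"]), exp(beta))
  expect_error(fitCox(co, "entropy"), "constant")
})

test_that("null covariates produce small coefficients and honest p-values", {
  co <- nullCohortWithNoise(1000, seed = 21)
  fit <- fitCox(co, "noise")
  expect_lt(abs(coef(fit)[1]), 3 * fit@se[1])
})

test_that("collinearity screen matches a hand R-squared and flags copies", {
  set.seed(6)
  co <- data.frame(a = rnorm(100), b = rnorm(100))
  co$c <- 0.8 * co$a + 0.3 * co$b + rnorm(100, 0, 0.5)
  scr <- collinearityScreen(co, c("a", "b", "c"))
  # oracle: normal-equations R^2 of a ~ b + c
  X <- cbind(1, co$b, co$c)
  bhat <- solve(t(X) %*% X, t(X) %*% co$a)
  r2 <- 1 - sum((co$a - X %*% bhat)^2) / sum((co$a - mean(co$a))^2)
  expect_equal(scr$r2[1], r2, tolerance = 1e-10)
  expect_equal(scr$vif[1], 1 / (1 - r2), tolerance = 1e-10)

  ind <- data.frame(x = rnorm(500), y = rnorm(500))
  scrInd <- collinearityScreen(ind, c("x", "y"))
  expect_true(all(abs(scrInd$vif - 1) < 0.1))
  expect_true(all(scrInd$pass))

  dup <- data.frame(x = rnorm(50)); dup$y <- dup$x
  scrDup <- collinearityScreen(dup, c("x", "y"))
  expect_true(all(is.infinite(scrDup$vif)))
  expect_false(any(scrDup$pass))
})

test_that("the p<0.1 rule keeps strong predictors and screens collinearity", {
  co <- generateCohort(cohortSpec(nSubjects = 600,
                                  logHrPerUnitEntropy = 1.2, seed = 31))
  set.seed(32)
  co$noise1 <- rnorm(600); co$noise2 <- rnorm(600)
  sel <- selectMultivariable(co, c("entropy", "noise1", "noise2"))
  expect_true("entropy" %in% sel$retained)
  expect_equal(sel$trace$retained, sel$trace$p < 0.1)
  expect_setequal(sel$trace$candidate, c("entropy", "noise1", "noise2"))

  co$entropy_copy <- co$entropy
  expect_warning(
    sel2 <- selectMultivariable(co, c("entropy", "entropy_copy")),
    "VIF")
  expect_length(sel2$retained, 1)
  expect_false(is.null(sel2$fit))

  # all-noise candidate set may legitimately select nothing
  selNull <- selectMultivariable(co, c("noise1", "noise2"))
  expect_true(is.null(selNull$fit) || length(selNull$retained) >= 1)
  expect_equal(selNull$trace$retained, selNull$trace$p < 0.1)
})
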