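test_that("pixel extraction pools masked values and excludes blood pool", {
  img <- matrix(c(2, 2, 3, 5, 9, 9, 9, 9, 9), 3, 3)
  myo <- matrix(FALSE, 3, 3); myo[1:4] <- TRUE
  s <- extractPixels(img, myo)
  expect_equal(s@nPixels, 4L)
  expect_setequal(s@intensities, c(2, 2, 3, 5))

  blood <- myo                              # fully swallowed by blood pool
  expect_error(extractPixels(img, myo, blood), class = "emptyRegionError")
  expect_error(extractPixels(img, matrix(TRUE, 2, 2)),
               class = "alignmentError")
})

test_that("scar pixels appear in the extracted sample at the set rate", {
  img <- generatePhantom(phantomSpec(scarFraction = 0.25, noiseSd = 2,
                                     heterogeneitySigma = 10, seed = 8))
  s <- extractPixels(img)
  cut <- 100 * (3 + 1) / 2                  # between tissue and scar
  fracHigh <- mean(s@intensities > cut)
  trueFrac <- sum(scarTruthMask(img)) / sum(myocardiumMask(img))
  expect_lt(abs(fracHigh - trueFrac), 0.02)
  expect_lt(abs(trueFrac - 0.25), 0.01)
})

test_that("histogram binning covers the range and normalizes", {
  h <- buildHistogram(c(0, 0, 1, 1), nBins = 2)
  expect_equal(probabilities(h), c(0.5, 0.5))

  hc <- buildHistogram(c(7, 7, 7), nBins = 8)
  expect_equal(sum(probabilities(hc)), 1)
  expect_equal(max(probabilities(hc)), 1)    # one designated bin

  expect_error(buildHistogram(c(1, 2), nBins = 1), class = "parameterError")
  expect_error(buildHistogram(numeric(0)), class = "emptyRegionError")
})

test_that("uniform draws fill bins evenly within the binomial bound", {
  set.seed(1)
  x <- runif(10000)
  h <- buildHistogram(x, nBins = 16)
  p <- probabilities(h)
  sdBin <- sqrt((1 / 16) * (15 / 16) / 10000)
  expect_true(all(abs(p - 1 / 16) < 3.5 * sdBin))
})

test_that("entropy matches closed forms", {
  expect_equal(entropyValue(computeEntropy(histogramFromProbs(1))), 0)
  expect_identical(entropyValue(computeEntropy(histogramFromProbs(1))), 0)
  expect_equal(entropyValue(computeEntropy(
    histogramFromProbs(rep(0.25, 4)))), 2)
  expect_equal(entropyValue(computeEntropy(
    histogramFromProbs(c(0.5, 0.25, 0.25)))), 1.5)
  # natural-log base
  expect_equal(entropyValue(computeEntropy(
    histogramFromProbs(rep(0.25, 4)), logBase = exp(1))), log(4))
})

test_that("the non-default printed formula behaves as documented", {
  # -sum p log(1-p): diverges when one bin holds all mass
  expect_warning(
    r <- computeEntropy(histogramFromProbs(1), formula = "printed"),
    "diverges")
  expect_identical(entropyValue(r), Inf)
  h <- histogramFromProbs(c(0.75, 0.25))
  expect_equal(entropyValue(computeEntropy(h, formula = "printed")),
               -(0.75 * log2(0.25) + 0.25 * log2(0.75)))
  # shannon default differs from the printed variant
  expect_equal(entropyValue(computeEntropy(h)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("entropy is bounded by log2(nBins) with equality conditions", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(2:32, 1)
    p <- rexp(k); p <- p / sum(p)
    h <- entropyValue(computeEntropy(histogramFromProbs(p)))
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-9)
  }
})

test_that("image entropy is a composition of the three stages", {
  img <- generatePhantom(phantomSpec(seed = 12))
  direct <- entropyFromImage(img, nBins = 64)
  manual <- computeEntropy(buildHistogram(extractPixels(img), nBins = 64))
  expect_identical(entropyValue(direct), entropyValue(manual))
})

test_that("a homogeneous phantom has exactly zero entropy", {
  img <- generatePhantom(phantomSpec(heterogeneitySigma = 0,
                                     scarFraction = 0,
                                     noiseModel = "none", seed = 2))
  expect_identical(entropyValue(entropyFromImage(img)), 0)
})

test_that("a two-intensity half/half myocardium has 1 bit of entropy", {
  img <- matrix(c(rep(10, 8), rep(20, 8)), 4, 4)
  myo <- matrix(TRUE, 4, 4)
  expect_equal(entropyValue(entropyFromImage(img, myo, nBins = 2)), 1)
})

test_that("entropy is scale- and permutation-invariant under min-max bins", {
  set.seed(7)
  x <- rexp(500, 0.01)
  h0 <- entropyValue(computeEntropy(buildHistogram(x, 32)))
  hScaled <- entropyValue(computeEntropy(buildHistogram(x * 3.7, 32)))
  hPerm <- entropyValue(computeEntropy(buildHistogram(sample(x), 32)))
  expect_equal(hScaled, h0, tolerance = 1e-12)
  expect_identical(hPerm, h0)
})

test_that("entropy matches brute-force per-pixel bin assignment", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    k <- sample(2:4, 1)
    v <- round(runif(n, 0, 50), 2)
    got <- entropyValue(computeEntropy(buildHistogram(v, k)))
    expect_equal(got, bruteEntropyBits(v, k), tolerance = 1e-12)
  }
})
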