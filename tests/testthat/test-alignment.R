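mkHist <- function(values, provenance = "fourier") {
  bins <- length(values)
  OrientationHistogram(centers = (seq_len(bins) - 0.5) * 180 / bins,
                       values = values, provenance = provenance)
}

test_that("background subtraction removes the minimum bin and flags flat input", {
  h <- mkHist(c(1, 3, 1, 1, 1, 1, 1, 1))
  out <- subtractBackground(h)
  expect_equal(binValues(out), c(0, 2, 0, 0, 0, 0, 0, 0))
  expect_false(isDegenerate(out))

  flat <- subtractBackground(mkHist(rep(5, 90)))
  expect_equal(binValues(flat), rep(0, 90))
  expect_true(isDegenerate(flat))

  perc <- subtractBackground(mkHist(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9)),
                             method = "percentile", prob = 0.5)
  expect_equal(min(binValues(perc)), 0)
  expect_equal(sum(binValues(perc) > 0), 5)
})

test_that("removing a pedestal never lowers the range AI", {
  set.seed(4)
  for (i in 1:50) {
    peak <- numeric(90)
    ctr <- sample(10:35, 1)
    peak[ctr + (-2:2)] <- stats::dnorm(-2:2) * stats::runif(1, 5, 50)
    pedestal <- stats::runif(1, 0.5, 5)
    h <- mkHist(peak + pedestal)
    hb <- subtractBackground(h)
    lowBefore <- splitRanges(h)$low
    lowAfter <- splitRanges(hb)$low
    expect_gte(alignmentIndex(lowAfter) + 1e-12, alignmentIndex(lowBefore))
  }
})

test_that("the range split partitions mass exactly", {
  h <- mkHist(replace(numeric(90), 23, 7))  # peak at bin centre 45
  sr <- splitRanges(h)
  expect_equal(sum(binValues(sr$low)), 7)
  expect_equal(sum(binValues(sr$high)), 0)
  expect_true(isDegenerate(sr$high))

  two <- mkHist(replace(numeric(90), c(23, 68), c(4, 4)))  # 45 and 135
  sr2 <- splitRanges(two)
  expect_equal(sum(binValues(sr2$low)), sum(binValues(sr2$high)))

  set.seed(2)
  for (i in 1:200) {
    v <- stats::rexp(90)
    sr <- splitRanges(mkHist(v))
    expect_lt(abs(sum(binValues(sr$low)) + sum(binValues(sr$high)) - sum(v)),
              1e-12)
  }
  # 9 bins of 20 degrees: a bin straddles 90
  expect_error(splitRanges(mkHist(rep(1, 9))), "straddles")
})

test_that("the doubled-angle mean orientation matches hand-computed cases", {
  expect_equal(circularMeanOrientation(c(10, 30)), 20)
  expect_lt(axialDiff(circularMeanOrientation(c(170, 10)), 0), 1e-9)
  expect_equal(circularMeanOrientation(37), 37)
  expect_equal(circularMeanOrientation(c(10, 30), weights = c(1, 0)), 10)

  degenerate <- circularMeanOrientation(c(10, 30), weights = c(0, 0))
  expect_true(is.na(degenerate))
  expect_true(attr(degenerate, "degenerate"))

  balanced <- circularMeanOrientation(c(40, 130))  # exactly perpendicular
  expect_true(isTRUE(attr(balanced, "ambiguous")))
  expect_lt(balanced, 90)
})

test_that("the Alignment Index reproduces its defining cases", {
  expect_identical(alignmentIndex(rep(37, 100), theta = 37), 1)
  expect_identical(alignmentIndex(rep(122.5, 100)), 1)
  expect_lt(alignmentIndex(0:179), 1e-12)
  expect_lt(alignmentIndex(0:179, theta = 61.3), 1e-12)
  expect_equal(alignmentIndex(c(10, 30), theta = 20), cos(20 * pi / 180))
  # histogram path agrees with the sample path at bin centres
  h <- histogramFromAngles(c(rep(45, 8), rep(51, 4)), bins = 90)
  expect_equal(alignmentIndex(h), alignmentIndex(c(rep(45, 8), rep(51, 4))))
})

test_that("AI lies in [0, 1] for arbitrary non-negative histograms", {
  set.seed(6)
  for (i in 1:200) {
    v <- stats::rexp(90) * stats::rbinom(90, 1, 0.6)
    if (sum(v) == 0) v[1] <- 1
    ai <- alignmentIndex(mkHist(v))
    expect_gte(ai, 0)
    expect_lte(ai, 1)
  }
})

test_that("AI is exactly invariant under rotation of a sample", {
  set.seed(9)
  th <- stats::runif(40, 0, 180)
  base <- alignmentIndex(th)
  for (delta in c(7.3, 45, 90, 133.1)) {
    expect_equal(alignmentIndex((th + delta) %% 180), base,
                 tolerance = 1e-12)
  }
})

test_that("zero-weight input never divides by zero", {
  empty <- mkHist(numeric(90))
  ai <- alignmentIndex(empty)
  expect_identical(as.numeric(ai), 0)
  expect_true(attr(ai, "degenerate"))
  expect_true(is.na(circularMeanOrientation(empty)))
})

test_that("analyzeImage recovers a tight single family in the low range", {
  sim <- simulateFibrilScene(OrientationMixture(mu = 45, kappa = 1e6), 150,
                             size = 256, noiseSigma = 0.005, seed = 4)
  res <- analyzeImage(renderScene(sim$scene))
  expect_gt(aiLow(res), 0.9)
  m <- rangeMasses(res)
  expect_lt(m["high"] / sum(m), 0.1)
  expect_lt(axialDiff(thetaLow(res), 45), 3)
})

test_that("an orthogonal 45/135 lattice scores high in both ranges", {
  sim <- simulateFibrilScene(OrientationMixture(mu = c(45, 135), kappa = 50),
                             150, size = 256, seed = 3)
  res <- analyzeImage(renderScene(sim$scene))
  expect_gt(aiLow(res), 0.5)
  expect_gt(aiHigh(res), 0.5)
  expect_gt(min(rangeMasses(res)) / sum(rangeMasses(res)), 0.25)
})

test_that("a structureless image gives a degenerate zero result, not an error", {
  res <- analyzeImage(matrix(3.7, 96, 96))
  expect_equal(aiCombined(res), 0)
  expect_true(res@degenerateLow && res@degenerateHigh)
  df <- as.data.frame(res)
  expect_true(is.na(df$theta_th_low))
})
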