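test_that("the developmental presets produce an increasingly aligned series", {
  dev <- makeDevelopmentalSeries(developmentalStages(size = 256), size = 256,
                                 seed = 1)
  expect_length(dev, 3)
  expect_equal(vapply(dev, `[[`, "", "label"), c("2dpf", "3dpf", "4dpf"))
  expect_true(all(vapply(dev, function(s) is.matrix(s$image), TRUE)))
  # ground-truth AI of the dominant fibril family increases strictly
  gt <- vapply(dev, function(s) aiOracleDominant(angles(s$truth)), 1)
  expect_true(all(diff(gt) > 0))
  # and the same series is reproducible bit for bit
  dev2 <- makeDevelopmentalSeries(developmentalStages(size = 256),
                                  size = 256, seed = 1)
  expect_identical(dev[[2]]$image, dev2[[2]]$image)
})

test_that("uniform ground truth has a near-zero full-range AI at n = 500", {
  s <- sampleOrientations(OrientationMixture(mu = 0, kappa = 0), 500,
                          seed = 12)
  expect_lt(alignmentIndex(s), 0.1)
})

test_that("a fully concentrated family has AI above 0.99", {
  s <- sampleOrientations(OrientationMixture(mu = 77, kappa = 1e6), 500,
                          seed = 13)
  expect_gt(alignmentIndex(s), 0.99)
})

test_that("an empty wound contains no fibrils and only background", {
  sc <- WoundScenario(size = 192, nFibrils = 85, noiseSigma = 0)
  series <- makeWoundSeries(sc, list(list(label = "1dpi",
                                          densityFraction = 0,
                                          insideMixture = OrientationMixture(0, 0))),
                            seed = 3)
  tp <- series[[1]]
  expect_length(tp$insideTruth, 0)
  expect_lt(abs(mean(tp$image[tp$masks$inside]) - sc@background), 0.005)
})

test_that("the wound ground-truth AI follows the none / low / high sequence", {
  sc <- WoundScenario(size = 192, nFibrils = 85)
  tps <- list(
    list(label = "a", densityFraction = 0,
         insideMixture = OrientationMixture(0, 0)),
    list(label = "b", densityFraction = 0.5,
         insideMixture = OrientationMixture(0, 0)),
    list(label = "c", densityFraction = 1,
         insideMixture = OrientationMixture(c(45, 135), 20)))
  series <- makeWoundSeries(sc, tps, seed = 7)
  expect_length(series[[1]]$insideTruth, 0)
  aiLowTp <- aiOracleDominant(angles(series[[2]]$insideTruth))
  aiHighTp <- aiOracleDominant(angles(series[[3]]$insideTruth))
  expect_lt(aiLowTp, 0.85)
  expect_gt(aiHighTp, 0.9)
  expect_lt(aiLowTp, aiHighTp)
})

test_that("pixels beyond the wound's reach are identical across timepoints", {
  # (at 256 px the conservative reach estimate leaves a nonempty outside)
  sc <- WoundScenario(size = 256, nFibrils = 150)
  series <- makeWoundSeries(sc, woundTimepoints(), seed = 2)
  outside <- series[[1]]$masks$outside
  expect_gt(sum(outside), 0)
  for (i in 2:length(series))
    expect_identical(series[[1]]$image[outside], series[[i]]$image[outside])
  # and the outside ground truth is shared
  expect_identical(angles(series[[1]]$outsideTruth),
                   angles(series[[4]]$outsideTruth))
})

test_that("wound geometry is validated", {
  expect_error(WoundScenario(size = 128, woundRadius = -3), "radius")
  expect_error(WoundScenario(size = 128, woundRadius = 100), "bounds")
  expect_error(WoundScenario(size = 128, densityFraction = 1.5), "0, 1")
  expect_error(makeWoundSeries(WoundScenario(size = 128), list(), seed = 1),
               "timepoint")
})

test_that("cropWound extracts the inscribed analysis window", {
  img <- matrix(seq_len(100 * 100), 100, 100)
  crop <- cropWound(img, center = c(50, 50), radius = 30)
  h <- floor(30 / sqrt(2))
  expect_equal(dim(crop), c(2 * h, 2 * h))
  expect_equal(crop[1, 1], img[50 - h + 1, 50 - h + 1])
  expect_error(cropWound(img, c(5, 5), 30), "bounds")
})

test_that("ground truth export round-trips through CSV and JSON", {
  sim <- simulateFibrilScene(OrientationMixture(10, 5), 20, size = 64,
                             seed = 6)
  csv <- tempfile(fileext = ".csv")
  writeGroundTruth(sim$scene, csv)
  seg <- utils::read.csv(csv)
  expect_equal(nrow(seg), 20)
  expect_equal(seg$angle_deg, sim$scene@segments$angle)
  pars <- jsonlite::read_json(sub("\\.csv$", ".json", csv))
  expect_equal(pars$size, 64)
  expect_equal(pars$n_segments, 20)
})
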