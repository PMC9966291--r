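test_that("percent of field of view is a guarded ratio", {
  expect_identical(percentFov(8, 200), 4)
  expect_identical(percentFov(12, 200), 6)
  expect_identical(percentFov(200, 200), 100)
  expect_error(percentFov(0, 200), class = "fidreg_invalid_input")
  expect_error(percentFov(8, -1), class = "fidreg_invalid_input")
})

test_that("grid summary arithmetic matches hand computation", {
  g <- matrix(c(2, 4, 10, 20), 2, 2, byrow = TRUE)
  s <- summarizeErrorGrid(g)
  expect_equal(unname(s$rowAverages), c(3, 15))
  expect_equal(unname(s$colAverages), c(6, 12))
  expect_equal(s$grandAverage, 9)
  expect_equal(unname(s$sizeRatios), c(1, 5))
  expect_equal(unname(s$onePlaneExcessPct), 100)
})

test_that("the factorial table summarizes into the size x planes grid", {
  tab <- expand.grid(csaCm2 = c(4, 0.25), nPlanes = 1:2,
                     replicate = 1:3)
  tab$roiMeanUm <- with(tab, 10 * (csaCm2 == 0.25) + nPlanes + replicate)
  s <- summarizeFactorial(tab)
  expect_equal(dim(s$grid), c(2L, 2L))
  expect_equal(rownames(s$grid), c("4", "0.25"))
  expect_equal(colnames(s$grid), c("2", "1"))
  expect_equal(s$grid["4", "2"], mean(2 + 1:3))
  expect_equal(s$grid["0.25", "1"], mean(11 + 1:3))
  expect_equal(unname(s$sdGrid["4", "1"]), sd(1 + 1:3))
})

test_that("a small factorial run is reproducible and complete", {
  scn <- testScan(spacing = 0.7)
  run <- function() runFactorial(csaCm2 = c(4, 0.25), planeCounts = c(2, 4),
                                 nReplicates = 2L, masterSeed = 5L,
                                 scan = scn)
  t1 <- run()
  expect_equal(nrow(t1), 8L)
  expect_true(all(is.na(t1$error)))
  expect_true(all(t1$roiMeanUm >= 0))
  expect_identical(run(), t1)
})

test_that("the zero-baseline design yields zero error end to end", {
  tab <- runFactorial(csaCm2 = c(4, 0.25), planeCounts = c(2, 4),
                      nReplicates = 2L, masterSeed = 5L,
                      scan = testScan(spacing = 0.7, noise = 0,
                                      maxRotationDeg = 0,
                                      maxTranslationMm = 0),
                      identicalSampling = TRUE)
  expect_true(all(tab$roiMeanUm < 1e-6))
  expect_true(all(tab$markerMeanUm < 1e-6))
  expect_true(all(tab$treMeanUm < 1e-6))
})

test_that("failed cells are recorded, not dropped", {
  tab <- runFactorial(csaCm2 = 4, planeCounts = 2, nReplicates = 1L,
                      masterSeed = 5L, scan = testScan(spacing = 0.7),
                      roi = roiSpec(minPoints = 10000000L))
  expect_equal(nrow(tab), 1L)
  expect_true(is.na(tab$roiMeanUm))
  expect_match(tab$error, "ROI selects")
})

test_that("permutation tests behave at the null and under clear effects", {
  expect_lt(pairedPermutationTest(1:10 + 10, 1:10, seed = 8L), 0.01)
  balanced <- rep(c(-1, 1), 5)
  expect_equal(pairedPermutationTest(balanced + 1:10, 1:10, seed = 8L), 1,
               tolerance = 0.01)
  m0 <- matrix(rep(1:6, 3), 6, 3) + 0       # identical conditions
  expect_gt(equalityPermutationTest(m0 + matrix(rnorm(18, 0, 0.1), 6, 3),
                                    nPerm = 500, seed = 9L), 0.05)
  mEff <- cbind(rnorm(6, 0, 0.1), rnorm(6, 5, 0.1), rnorm(6, 0, 0.1))
  expect_lt(equalityPermutationTest(mEff, nPerm = 500, seed = 9L), 0.01)
})

test_that("every two-face configuration recovers identical models exactly", {
  pair <- makePair(phantomSpec(), testScan(seed = 81L, noise = 0),
                   identicalSampling = TRUE)
  for (cf in utils::combn(4, 2, simplify = FALSE)) {
    res <- registerViaFeatures(pair$reference, pair$target,
                               planeSelection(cf))
    resid <- composeTransforms(res@transform, pair$truth)
    tre <- targetRegistrationError(res@transform, pair$truth,
                                   extractRoi(pair$reference))
    expect_lt(tre@maxUm, 1e-3)   # 1e-6 mm
  }
})

test_that("the configuration sweep reports per-config summaries and a test", {
  sw <- planarConfigurationSweep(csaCm2 = 4,
                                 configurations = list(1L, c(1L, 2L),
                                                       c(3L, 4L)),
                                 nReplicates = 2L, masterSeed = 6L,
                                 scan = testScan(spacing = 0.7),
                                 nPerm = 200L)
  expect_equal(nrow(sw$table), 6L)
  expect_equal(nrow(sw$summary), 3L)
  expect_true(sw$equalityTwoPlane > 0 && sw$equalityTwoPlane <= 1)
  expect_true(all(c("meanUm", "sdUm", "medianUm") %in% colnames(sw$summary)))
})

test_that("whole-model registration is exact for identical models and seeded", {
  pair <- makePair(phantomSpec(), testScan(seed = 82L, spacing = 0.7,
                                           noise = 0),
                   identicalSampling = TRUE)
  w <- wholeModelCondition(pair)
  expect_lt(w$stats@meanUm, 1e-6)
  pair2 <- makePair(phantomSpec(), testScan(seed = 83L, spacing = 0.7))
  w1 <- wholeModelCondition(pair2)
  w2 <- wholeModelCondition(pair2)
  expect_identical(w1$stats@meanUm, w2$stats@meanUm)
})

test_that("the benchmark grid carries its dispersion attribute", {
  g <- referenceErrorGrid()
  expect_equal(dim(g), c(3L, 4L))
  expect_equal(dim(attr(g, "sd")), c(3L, 4L))
  expect_true(all(g > 0))
})
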