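test_that("surface variation reproduces analytic offsets", {
  grid <- as.matrix(expand.grid(x = seq(0, 10, 0.5), y = seq(0, 10, 0.5)))
  plane <- cbind(grid, 0)
  expect_equal(surfaceVariation(plane, plane)@meanUm, 0)
  shifted <- cbind(grid, 0.005)
  sv <- surfaceVariation(shifted, plane)
  expect_equal(sv@meanUm, 5)          # 0.005 mm = 5 um, exactly
  expect_equal(sv@sdUm, 0)
  expect_equal(sv@maxUm, 5)
  # mesh path: points at height h above a square
  mesh <- unitSquareMesh()
  pts <- cbind(runif(20, -8, 8), runif(20, -8, 8), 0.42)
  expect_equal(surfaceVariation(pts, mesh)@meanUm, 420)
  expect_error(surfaceVariation(matrix(numeric(), 0, 3), plane),
               class = "fidreg_invalid_input")
})

test_that("surface variation equals the brute-force minimum distances", {
  A <- randomCloud(150, seed = 71)
  B <- randomCloud(180, seed = 72)
  sv <- surfaceVariation(A, B)
  want <- bruteNearest(A, B)$distance * 1000
  expect_equal(sv@meanUm, mean(want))
  expect_equal(sv@maxUm, max(want))
  expect_equal(sv@medianUm, median(want))
  expect_equal(surfaceVariationField(A, B), want)
  expect_true(all(want >= 0))
})

test_that("target registration error follows rigid-body kinematics", {
  pts <- randomCloud(100, seed = 73)
  set.seed(74)
  truth <- randomRigidTransform(10, 10)
  expect_equal(targetRegistrationError(invertTransform(truth), truth,
                                       pts)@maxUm, 0)
  # an extra pure translation of 10 um is reported exactly
  off <- composeTransforms(rigidTransform(translation = c(0.01, 0, 0)),
                           invertTransform(truth))
  tre <- targetRegistrationError(off, truth, pts)
  expect_equal(tre@meanUm, 10, tolerance = 1e-9)
  expect_equal(tre@sdUm, 0, tolerance = 1e-9)
  # a pure rotation about the centroid scales linearly with radius
  ring <- function(r) cbind(r * cos(seq(0, 2 * pi, length.out = 37))[-37],
                            r * sin(seq(0, 2 * pi, length.out = 37))[-37], 0)
  rot <- rigidTransform(fidreg:::.axisAngleToMatrix(c(0, 0, 0.001)))
  e1 <- targetRegistrationError(rot, identityTransform(), ring(5))@meanUm
  e2 <- targetRegistrationError(rot, identityTransform(), ring(10))@meanUm
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
})

test_that("TRE and surface variation agree for sub-spacing residuals", {
  pair <- makePair(phantomSpec(), testScan(seed = 75L, noise = 0),
                   identicalSampling = TRUE)
  roiRef <- extractRoi(pair$reference)
  delta <- rigidTransform(fidreg:::.axisAngleToMatrix(c(2e-5, 0, 1e-5)),
                          c(0.008, -0.005, 0.006))
  tEst <- composeTransforms(delta, invertTransform(pair$truth))
  reg <- applyToModel(pair$target, tEst)
  sv <- surfaceVariation(extractRoi(reg), roiRef)
  tre <- targetRegistrationError(tEst, pair$truth, roiRef)
  expect_gt(sv@meanUm, tre@meanUm / 2)
  expect_lt(sv@meanUm, tre@meanUm * 2)
})

test_that("a fixed angular error hurts more at larger block standoff", {
  errAt <- function(standoff) {
    ph <- phantomSpec(standoffMm = standoff)
    mesh <- makePhantom(ph)
    ctr <- translation(blockPlacement(ph))
    # 0.5 degree rotation about an axis through the block center
    ang <- 0.5 * pi / 180
    rot <- rigidTransform(fidreg:::.axisAngleToMatrix(c(ang, 0, 0)))
    tEst <- composeTransforms(
      rigidTransform(translation = ctr),
      composeTransforms(rot, rigidTransform(translation = -ctr)))
    roi <- extractRoi(simulateScan(mesh, testScan(seed = 76L, spacing = 1)))
    targetRegistrationError(tEst, identityTransform(), roi)@meanUm
  }
  e <- vapply(c(5, 15, 30), errAt, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("deviation maps are zero for perfect registration and exportable", {
  mesh <- unitSquareMesh()
  cl <- simulateScan(mesh, testScan(seed = 77L, spacing = 1, noise = 0))
  map <- deviationMap(cl, mesh)
  expect_lt(max(map$fieldUm), 1e-6)
  expect_length(map$colors, nPoints(cl))
  expect_true(all(map$fieldUm >= 0))
})
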