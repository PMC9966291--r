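# shared noisy pair at desk-scale settings (built once)
pairFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makePair(phantomSpec(), testScan(seed = 61L))
    cache
  }
})

test_that("rough alignment recovers constructed transforms", {
  cl <- asymmetricCloud()
  same <- roughAlign(cl, cl)
  expect_lt(rotationAngleDeg(same), 1e-8)
  expect_lt(max(abs(translation(same))), 1e-8)
  set.seed(62)
  tr <- randomRigidTransform(40, 20)
  est <- roughAlign(cl, applyTransform(cl, tr))
  expect_lt(max(abs(rotation(est) - rotation(tr))), 1e-6)
  expect_lt(max(abs(translation(est) - translation(tr))), 1e-6)
})

test_that("isotropic clouds fall back to centroid-only translation", {
  octa <- rbind(diag(3), -diag(3))
  iso <- pointCloud(octa[rep(1:6, 3), ] * 5 +
                    matrix(3, 18, 3))  # exactly isotropic, shifted
  est <- roughAlign(iso, applyTransform(iso,
                                        rigidTransform(translation = c(1, 2, 3))))
  expect_true(isTRUE(est@metadata$degenerate))
  expect_equal(rotation(est), diag(3))
  expect_equal(translation(est), c(1, 2, 3), tolerance = 1e-9)
})

test_that("ICP on identical clouds converges immediately to the identity", {
  cl <- asymmetricCloud(n = 200)
  res <- icp(cl, cl)
  expect_true(res@converged)
  expect_equal(res@nIterations, 1L)
  expect_lt(max(res@rmsTrace), 1e-12)
  expect_lt(max(abs(rotation(res@transform) - diag(3))), 1e-10)
  expect_lt(max(abs(translation(res@transform))), 1e-10)
})

test_that("ICP recovers a small perturbation of two orthogonal planes", {
  mesh <- makePhantom(phantomSpec())
  cloud <- extractBlock(simulateScan(mesh, testScan(seed = 63L, noise = 0)),
                        planeSelection(1:2))
  pert <- composeTransforms(
    rigidTransform(fidreg:::.axisAngleToMatrix(c(0.02, 0.025, 0.01))),
    rigidTransform(translation = c(0.6, -0.5, 0.6)))  # ~2 deg / ~1 mm
  res <- icp(applyTransform(cloud, pert), cloud)
  expect_true(res@converged)
  resid <- composeTransforms(res@transform, pert)
  tre <- sqrt(rowSums((applyTransform(coords(cloud), resid) -
                       coords(cloud))^2))
  expect_lt(max(tre), 1e-6)
})

test_that("the RMS trace of untrimmed point-to-point ICP is monotone", {
  pair <- pairFixture()
  ref <- extractBlock(pair$reference, planeSelection(1:2))
  tgt <- extractBlock(pair$target, planeSelection(1:2))
  res <- icp(tgt, ref, init = roughAlign(tgt, ref))
  expect_true(all(diff(res@rmsTrace) <= 1e-12))
  expect_true(res@converged)
  # convergence flag is honest about the last RMS change
  n <- length(res@rmsTrace)
  expect_lt(abs(res@rmsTrace[n] - res@rmsTrace[n - 1]), 1e-7)
})

test_that("forward and reverse registrations are mutually inverse", {
  pair <- pairFixture()
  ref <- extractBlock(pair$reference, planeSelection(1:4))
  tgt <- extractBlock(pair$target, planeSelection(1:4))
  fwd <- icp(tgt, ref, init = roughAlign(tgt, ref))
  rev <- icp(ref, tgt, init = roughAlign(ref, tgt))
  both <- composeTransforms(fwd@transform, rev@transform)
  expect_lt(rotationAngleDeg(both), 0.5)
  expect_lt(sqrt(sum(translation(both)^2)), 0.5)
})

test_that("degenerate geometry inside ICP reports the iteration", {
  line <- pointCloud(cbind(1:20, 0, 0) + 0)
  err <- tryCatch(icp(line, line, init = rigidTransform(translation = c(0.1, 0, 0))),
                  condition = identity)
  expect_s3_class(err, "fidreg_degenerate_geometry")
  expect_equal(err$iteration, 1L)
})

test_that("point-to-plane ICP refines a two-plane alignment", {
  mesh <- makePhantom(phantomSpec())
  cloud <- extractBlock(simulateScan(mesh, testScan(seed = 64L)),
                        planeSelection(1:2))
  pert <- rigidTransform(fidreg:::.axisAngleToMatrix(c(0.01, 0, 0.015)),
                         c(0.3, 0.2, -0.4))
  res <- icp(applyTransform(cloud, pert), cloud,
             params = icpParams(pointToPlane = TRUE))
  # point-to-plane with re-matching has no monotone-convergence guarantee;
  # the residual trace must still stabilize at the noise level
  expect_lt(diff(range(tail(res@rmsTrace, 5))), 1e-3)
  expect_lt(tail(res@rmsTrace, 1), 3 * 0.02)
  resid <- composeTransforms(res@transform, pert)
  # the constrained (out-of-plane) error is at the noise scale
  expect_lt(rotationAngleDeg(resid), 0.5)
  bare <- pointCloud(coords(cloud))
  expect_error(icp(bare, bare, params = icpParams(pointToPlane = TRUE)),
               class = "fidreg_invalid_input")
})

test_that("trimming rejects injected outliers", {
  set.seed(65)
  cl <- asymmetricCloud(n = 300)
  tr <- randomRigidTransform(5, 2)
  moved <- applyTransform(cl, tr)
  outliers <- pointCloud(matrix(runif(45, 50, 60), 15, 3))
  contaminated <- pointCloud(rbind(coords(moved), coords(outliers)))
  res <- icp(contaminated, cl, params = icpParams(trimFraction = 0.1))
  resid <- composeTransforms(res@transform, tr)
  expect_lt(rotationAngleDeg(resid), 0.5)
})

test_that("feature registration of identical noise-free models is exact", {
  pair <- makePair(phantomSpec(), testScan(seed = 66L, noise = 0),
                   identicalSampling = TRUE)
  res <- registerViaFeatures(pair$reference, pair$target, planeSelection(1:2))
  resid <- composeTransforms(res@transform, pair$truth)
  expect_lt(rotationAngleDeg(resid), 1e-8)
  expect_lt(max(abs(translation(resid))), 1e-8)
})

test_that("icp parameter validation enforces the documented ranges", {
  expect_error(icpParams(trimFraction = 0.7), "trimFraction")
  expect_error(icpParams(convergenceTolMm = 0), "convergenceTolMm")
  expect_error(icp(pointCloud(matrix(0, 2, 3) + rnorm(6)),
                   pointCloud(matrix(rnorm(9), 3, 3))),
               class = "fidreg_invalid_input")
})
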