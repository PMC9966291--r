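scanFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- phantomSpec()
      cache <<- list(phantom = ph, mesh = makePhantom(ph),
                     cloud = simulateScan(makePhantom(ph),
                                          testScan(seed = 51L)))
    }
    cache
  }
})

test_that("block extraction by label filters exactly the selected faces", {
  cl <- scanFixture()$cloud
  all4 <- extractBlock(cl, planeSelection(1:4))
  expect_true(all(pointLabels(all4) %in% paste0("block_face_", 1:4)))
  expect_gt(nPoints(all4), 0)
  # four single-face selections partition the full selection
  singles <- lapply(1:4, function(f) extractBlock(cl, planeSelection(f)))
  expect_equal(sum(vapply(singles, nPoints, numeric(1))), nPoints(all4))
  keyAll <- sort(apply(coords(all4), 1, paste, collapse = ","))
  keySingles <- sort(unlist(lapply(singles, function(s)
    apply(coords(s), 1, paste, collapse = ","))))
  expect_identical(keySingles, keyAll)
  # union property
  u12 <- extractBlock(cl, planeSelection(1:2))
  expect_equal(nPoints(u12), nPoints(singles[[1]]) + nPoints(singles[[2]]))
  expect_error(extractBlock(subsetCloud(cl, pointLabels(cl) == "object"),
                            planeSelection(1)),
               class = "fidreg_empty_selection")
})

test_that("a single-face extract is coplanar up to noise and spacing", {
  cl <- scanFixture()$cloud
  one <- extractBlock(cl, planeSelection(1))
  expect_lte(planeFitRms(coords(one)), 0.02 + 0.35 / 2)
})

test_that("label-free extraction recovers the labeled faces", {
  fx <- scanFixture()
  unlabeled <- pointCloud(coords(fx$cloud))
  tol <- 3 * 0.02 + 0.35
  got <- extractBlock(unlabeled, planeSelection(1:2),
                      block = fx$phantom@block,
                      blockPose = blockPlacement(fx$phantom),
                      toleranceMm = tol)
  want <- extractBlock(fx$cloud, planeSelection(1:2))
  # captures nearly all labeled face points and nothing from the object
  keyG <- apply(coords(got), 1, paste, collapse = ",")
  keyW <- apply(coords(want), 1, paste, collapse = ",")
  expect_gt(mean(keyW %in% keyG), 0.95)
  objKeys <- apply(coords(fx$cloud)[pointLabels(fx$cloud) %in%
                                    c("object", "roi"), ], 1,
                   paste, collapse = ",")
  expect_equal(sum(keyG %in% objKeys), 0)
  expect_error(extractBlock(unlabeled, planeSelection(1)),
               class = "fidreg_invalid_input")
})

test_that("selected area is |faces| x csa and additive", {
  expect_equal(selectedAreaCm2(planeSelection(1:2), blockSpec(4)), 8)
  expect_equal(selectedAreaCm2(planeSelection(1), blockSpec(0.25)), 0.25)
  expect_equal(selectedAreaCm2(planeSelection(1:4), blockSpec(1)), 4)
  a <- selectedAreaCm2(planeSelection(c(1, 3)), blockSpec(4)) +
       selectedAreaCm2(planeSelection(c(2, 4)), blockSpec(4))
  expect_equal(a, selectedAreaCm2(planeSelection(1:4), blockSpec(4)))
  expect_error(planeSelection(c(1, 1)), "duplicate")
  expect_error(planeSelection(integer(0)), "nonempty")
  expect_error(planeSelection(5), "1:4")
})

test_that("ROI extraction is consistent and disjoint from the block", {
  fx <- scanFixture()
  roi <- extractRoi(fx$cloud)
  expect_true(all(pointLabels(roi) == "roi"))
  expect_gte(nPoints(roi), 100)
  blockPts <- extractBlock(fx$cloud, planeSelection(1:4))
  keyR <- apply(coords(roi), 1, paste, collapse = ",")
  keyB <- apply(coords(blockPts), 1, paste, collapse = ",")
  expect_length(intersect(keyR, keyB), 0)
  # same spec on a same-seed scan selects the identical point set
  again <- extractRoi(simulateScan(fx$mesh, testScan(seed = 51L)))
  expect_identical(coords(again), coords(roi))
  # snipping-polygon path: a square around the plateau center
  poly <- rbind(c(-10, -10), c(10, -10), c(10, 10), c(-10, 10))
  snip <- extractRoi(fx$cloud, roiSpec(polygon = poly))
  expect_true(all(abs(coords(snip)[, 1]) <= 10))
  expect_true(all(abs(coords(snip)[, 2]) <= 10))
  expect_error(extractRoi(fx$cloud, roiSpec(label = "missing")),
               class = "fidreg_invalid_roi")
  tiny <- roiSpec(polygon = rbind(c(0, 0), c(0.1, 0), c(0.1, 0.1)))
  expect_error(extractRoi(fx$cloud, tiny), class = "fidreg_invalid_roi")
})
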