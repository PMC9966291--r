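test_that("phantom block faces have the specified area and orthogonality", {
  for (csa in c(4, 1, 0.25)) {
    mesh <- makePhantom(phantomSpec(block = blockSpec(csa)))
    areas <- surfaceArea(mesh, byLabel = TRUE)
    for (f in paste0("block_face_", 1:4))
      expect_lt(abs(areas[[f]] - csa * 100) / (csa * 100), 1e-3)
    # face normals are mutually orthogonal (or antiparallel laterals)
    nrm <- fidreg:::.triNormals(vertices(mesh), faces(mesh))
    labs <- faceLabels(mesh)
    n1 <- nrm[match("block_face_1", labs), ]
    n2 <- nrm[match("block_face_2", labs), ]
    angle <- acos(abs(sum(n1 * n2))) * 180 / pi
    expect_lt(abs(angle - 90), 1e-6)
  }
  expect_equal(blockSideMm(blockSpec(0.25)), 5)
  expect_equal(blockSideMm(blockSpec(4)), 20)
})

test_that("phantom area grows with block size and oversized blocks fail", {
  a <- vapply(c(0.25, 1, 4),
              function(csa) surfaceArea(makePhantom(
                phantomSpec(block = blockSpec(csa)))), numeric(1))
  expect_true(all(diff(a) > 0))
  expect_error(makePhantom(phantomSpec(block = blockSpec(26))),
               class = "fidreg_invalid_input")
})

test_that("scan simulation is seeded, dense and surface-faithful", {
  mesh <- makePhantom(phantomSpec())
  s1 <- simulateScan(mesh, testScan(seed = 41L))
  s2 <- simulateScan(mesh, testScan(seed = 41L))
  expect_identical(coords(s1), coords(s2))   # bitwise reproducibility
  expect_identical(pointLabels(s1), pointLabels(s2))
  s3 <- simulateScan(mesh, testScan(seed = 42L))
  expect_false(identical(coords(s1), coords(s3)))

  # expected point count ~ scanned area / spacing^2, within 5% over seeds
  areas <- surfaceArea(mesh, byLabel = TRUE)
  scanned <- sum(areas) - areas[["block_attached"]]
  spacing <- 0.7
  counts <- vapply(1:10, function(s)
    nPoints(simulateScan(mesh, testScan(seed = s, spacing = spacing))),
    numeric(1))
  expect_lt(max(abs(counts - scanned / spacing^2)) / (scanned / spacing^2),
            0.05)

  # the attached face is not scannable
  expect_false("block_attached" %in% pointLabels(s1))

  # noise-free samples lie on the mesh
  s0 <- simulateScan(mesh, testScan(seed = 5L, spacing = 1, noise = 0))
  idx <- seq(1, nPoints(s0), by = 17)
  expect_lt(max(pointMeshDistance(coords(s0)[idx, ], mesh)), 1e-9)

  # a phantom wider than the field of view is rejected
  expect_error(simulateScan(mesh, scanSpec(fovAreaCm2 = 0.5)),
               class = "fidreg_invalid_input")
})

test_that("makePair returns bounded ground-truth perturbations", {
  ph <- phantomSpec()
  for (s in 1:10) {
    pair <- makePair(ph, testScan(seed = s, spacing = 1.2))
    expect_lte(rotationAngleDeg(pair$truth), 10)
    expect_lte(sqrt(sum(translation(pair$truth)^2)), 10)
  }
  # zero perturbation, zero noise: truth is the identity
  p0 <- makePair(ph, testScan(seed = 1, spacing = 1.2, noise = 0,
                              maxRotationDeg = 0, maxTranslationMm = 0))
  expect_equal(rotation(p0$truth), diag(3))
  expect_equal(translation(p0$truth), c(0, 0, 0))
  expect_false(identical(coords(p0$reference), coords(p0$target)))

  # registering with truth^-1 puts noise-free target points on the surface
  pair <- makePair(ph, testScan(seed = 7, spacing = 1.2, noise = 0))
  undone <- applyToModel(pair$target, invertTransform(pair$truth))
  d <- pointMeshDistance(coords(extractRoi(undone)), pair$mesh)
  expect_lt(max(d), 1e-9)

  # identical-sampling pairs share the reference sampling
  pid <- makePair(ph, testScan(seed = 9, spacing = 1.2, noise = 0),
                  identicalSampling = TRUE)
  back <- applyTransform(pid$target, invertTransform(pid$truth))
  expect_equal(coords(back), coords(pid$reference), tolerance = 1e-12)
})
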