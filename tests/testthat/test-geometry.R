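test_that("nearest neighbors match exhaustive search with lowest-index ties", {
  # query == reference
  P <- randomCloud(50, seed = 21)
  nn <- nearestNeighbors(P, P)
  expect_equal(nn$index, 1:50)
  expect_equal(nn$distance, rep(0, 50))
  # analytically forced case
  ref <- rbind(c(0, 0, 0), c(10, 0, 0))
  nn2 <- nearestNeighbors(matrix(c(4, 0, 0), 1, 3), ref)
  expect_equal(nn2$index, 1L)
  expect_equal(nn2$distance, 4)
  # oracle comparison on random clouds, several sizes
  for (n in c(20, 200, 1000)) {
    Q <- randomCloud(100, seed = n + 1)
    R <- randomCloud(n, seed = n + 2)
    got <- nearestNeighbors(Q, R)
    want <- bruteNearest(Q, R)
    expect_identical(got$index, want$index)
    expect_equal(got$distance, want$distance)
  }
  # exact ties broken by the lowest reference index
  refDup <- rbind(c(1, 1, 1), c(5, 5, 5), c(1, 1, 1), c(5, 5, 5))
  nn3 <- nearestNeighbors(rbind(c(1, 1, 1), c(5, 5, 5), c(3, 3, 3)), refDup)
  expect_equal(nn3$index, c(1L, 2L, 1L))
  expect_error(nearestNeighbors(P, matrix(numeric(), 0, 3)),
               class = "fidreg_invalid_input")
})

test_that("point-to-mesh distance handles face, edge and vertex regions", {
  tri <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(c(1, 2, 3), 1))
  onFace <- matrix(c(0.2, 0.2, 0), 1, 3)
  expect_equal(pointMeshDistance(onFace, tri), 0)
  above <- matrix(c(0.2, 0.2, 0.7), 1, 3)
  expect_equal(pointMeshDistance(above, tri), 0.7)
  # beyond an edge and beyond a vertex
  expect_equal(pointMeshDistance(matrix(c(0.5, -2, 0), 1, 3), tri), 2)
  expect_equal(pointMeshDistance(matrix(c(-3, -4, 0), 1, 3), tri), 5)
  expect_error(pointMeshDistance(above, "not a mesh"),
               class = "fidreg_invalid_input")
})

test_that("mesh distance agrees with a dense vertex-sampling oracle", {
  mesh <- makePhantom(phantomSpec(meshResolutionMm = 1.0))
  set.seed(23)
  Q <- coords(simulateScan(mesh, testScan(seed = 23, noise = 0)))
  Q <- Q[sample(nrow(Q), 200), ] + matrix(rnorm(600, 0, 0.5), 200, 3)
  d <- pointMeshDistance(Q, mesh)
  dv <- nearestNeighbors(Q, vertices(mesh))$distance
  V <- vertices(mesh)
  F <- faces(mesh)
  edgeLen <- function(i, j) sqrt(rowSums((V[F[, i], ] - V[F[, j], ])^2))
  maxEdge <- max(edgeLen(1, 2), edgeLen(2, 3), edgeLen(1, 3))
  expect_true(all(d <= dv + 1e-12))
  expect_true(all(dv - d <= maxEdge))
})

test_that("mesh distance is invariant under a common rigid transform", {
  mesh <- unitSquareMesh()
  Q <- randomCloud(40, seed = 24, scale = 15)
  d0 <- pointMeshDistance(Q, mesh)
  set.seed(25)
  g <- randomRigidTransform(80, 30)
  d1 <- pointMeshDistance(applyTransform(Q, g), applyTransform(mesh, g))
  expect_lt(max(abs(d0 - d1)), 1e-8)
})

test_that("mesh and cloud containers validate their invariants", {
  expect_error(triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0)),
                            matrix(c(1, 2, 3), 1)), "out of range")
  expect_error(pointCloud(matrix(c(1, NA, 3), 1, 3)), "finite")
  expect_error(pointCloud(matrix(rnorm(9), 3, 3),
                          normals = matrix(2, 3, 3) * 0.5), "unit norm")
  m <- unitSquareMesh()
  expect_equal(surfaceArea(m), 400)
  expect_equal(unname(surfaceArea(m, byLabel = TRUE)["face"]), 400)
  sub <- meshSubset(makePhantom(phantomSpec()), "roi")
  expect_true(all(faceLabels(sub) == "roi"))
  expect_error(meshSubset(sub, "nope"), class = "fidreg_empty_selection")
})
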