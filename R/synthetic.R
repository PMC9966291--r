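#' @include AllClasses.R AllGenerics.R
NULL

#' Specification constructors for the synthetic study
#'
#' `blockSpec()` describes the cubic registration block (face cross-sectional
#' area in cm2, so the study sizes 4 / 1 / 0.25 cm2 give sides 2 / 1 /
#' 0.5 cm). `scanSpec()` describes the simulated structured-light
#' acquisition. `phantomSpec()` describes the scanned object: an undulating
#' elliptical plateau (the analyzed surface) on a tapered shaft, with the
#' block held anterior of the plateau.
#'
#' @param csaCm2 block face cross-sectional area (cm2).
#' @param pose extra [RigidTransform-class] applied to the block on top of
#'   its default placement.
#' @param attachedFace label of the face glued toward the object; it is not
#'   scannable and never selectable.
#' @return the corresponding S4 specification object.
#' @export
blockSpec <- function(csaCm2 = 4, pose = identityTransform(),
                      attachedFace = "block_attached") {
  new("BlockSpec", csaCm2 = csaCm2, pose = pose, attachedFace = attachedFace)
}

#' @rdname blockSpec
#' @param fovAreaCm2 scanner field of view (cm2).
#' @param pointSpacingMm sampling resolution (mm): the simulated scan has
#'   area density `1 / pointSpacingMm^2`.
#' @param noiseSdMm Gaussian measurement-noise sd along the local surface
#'   normal (mm).
#' @param seed integer master seed (identical seeds give bitwise-identical
#'   clouds).
#' @param maxRotationDeg,maxTranslationMm bounds of the random rigid
#'   perturbation applied to the target scan.
#' @export
scanSpec <- function(fovAreaCm2 = 200, pointSpacingMm = 0.12,
                     noiseSdMm = 0.02, seed = 1L,
                     maxRotationDeg = 10, maxTranslationMm = 10) {
  new("ScanSpec", fovAreaCm2 = fovAreaCm2, pointSpacingMm = pointSpacingMm,
      noiseSdMm = noiseSdMm, seed = as.integer(seed),
      maxRotationDeg = maxRotationDeg, maxTranslationMm = maxTranslationMm)
}

#' @rdname blockSpec
#' @param plateauSemiAxesMm semi-axes of the elliptical plateau patch (mm).
#' @param roughnessAmplitudeMm amplitude of the plateau undulation (mm).
#' @param roughnessWavelengthMm wavelengths of its three sinusoidal
#'   components (mm).
#' @param shaftDepthMm,shaftTaper depth and taper of the shaft below the
#'   plateau.
#' @param block a [BlockSpec-class].
#' @param standoffMm gap between the block's attached face and the plateau
#'   boundary (mm).
#' @param meshResolutionMm target edge length of the triangulation (mm).
#' @export
phantomSpec <- function(plateauSemiAxesMm = c(30, 20),
                        roughnessAmplitudeMm = 2,
                        roughnessWavelengthMm = c(23, 31, 17),
                        shaftDepthMm = 30, shaftTaper = 0.65,
                        block = blockSpec(), standoffMm = 10,
                        meshResolutionMm = 1.5) {
  new("PhantomSpec", plateauSemiAxesMm = plateauSemiAxesMm,
      roughnessAmplitudeMm = roughnessAmplitudeMm,
      roughnessWavelengthMm = roughnessWavelengthMm,
      shaftDepthMm = shaftDepthMm, shaftTaper = shaftTaper, block = block,
      standoffMm = standoffMm, meshResolutionMm = meshResolutionMm)
}

#' Side length of the block in mm
#'
#' @param block a [BlockSpec-class].
#' @return cube side length in mm (`sqrt(csaCm2) * 10`).
#' @export
blockSideMm <- function(block) sqrt(block@csaCm2) * 10

# plateau height field: sum of three low-frequency sinusoids; weights sum to
# 1 so the peak undulation is ~ the stated amplitude
.plateauHeight <- function(x, y, amplitude, wavelengths) {
  amplitude * (0.5  * sin(2 * pi * x / wavelengths[1] + 0.7) +
               0.35 * sin(2 * pi * y / wavelengths[2] + 1.9) +
               0.15 * sin(2 * pi * (x + y) / wavelengths[3] + 3.1))
}

#' Pose of the registration block on the phantom
#'
#' The rigid transform placing the cube (modeled centered at the origin)
#' onto the phantom: anterior of the plateau at the configured standoff,
#' with the top face flush with the plateau mid-level, composed with any
#' extra pose in the block spec.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [RigidTransform-class].
#' @export
blockPlacement <- function(spec) {
  side <- blockSideMm(spec@block)
  composeTransforms(
    rigidTransform(translation = c(0, -(spec@plateauSemiAxesMm[2] +
                                        spec@standoffMm + side / 2),
                                   -side / 2)),
    spec@block@pose)
}

#' Generate the labeled phantom mesh
#'
#' Builds the plateau analog (labeled `"roi"`), the tapered shaft and bottom
#' cap (labeled `"object"`), and the cubic block with faces labeled
#' `"block_face_1"` (top) through `"block_face_4"`, `"block_attached"`
#' (toward the object, not scannable) and `"block_other"` (bottom). Block
#' faces are planar and mutually orthogonal by construction; each selectable
#' face has area `csaCm2 * 100` mm2.
#'
#' @param spec a [PhantomSpec-class].
#' @return a labeled [TriangleMesh-class].
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  ab <- spec@plateauSemiAxesMm
  a <- ab[1]; b <- ab[2]
  h <- spec@meshResolutionMm
  side <- blockSideMm(spec@block)
  if (side > 2 * min(a, b))
    .stopInvalid(sprintf(
      "block side %.1f mm exceeds the plateau minor diameter %.1f mm",
      side, 2 * min(a, b)))

  # ---- plateau: polar grid over the ellipse, undulating height field
  perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  nAng <- max(24L, as.integer(round(perim / h)))
  nRing <- max(4L, as.integer(ceiling(max(a, b) / h)))
  theta <- seq(0, 2 * pi, length.out = nAng + 1L)[-(nAng + 1L)]
  zf <- function(x, y) .plateauHeight(x, y, spec@roughnessAmplitudeMm,
                                      spec@roughnessWavelengthMm)
  V <- matrix(c(0, 0, zf(0, 0)), 1, 3)
  ringStart <- integer(nRing)       # index of first vertex of each ring
  for (j in seq_len(nRing)) {
    r <- j / nRing
    x <- a * r * cos(theta); y <- b * r * sin(theta)
    ringStart[j] <- nrow(V) + 1L
    V <- rbind(V, cbind(x, y, zf(x, y)))
  }
  nxt <- function(i) i %% nAng + 1L
  F <- matrix(integer(), 0, 3)
  # central fan (wound so normals point +z)
  r1 <- ringStart[1]
  F <- rbind(F, cbind(1L, r1 + seq_len(nAng) - 1L,
                      r1 + nxt(seq_len(nAng)) - 1L))
  # quad strips between rings
  for (j in seq_len(nRing - 1L)) {
    i0 <- ringStart[j] + seq_len(nAng) - 1L
    i1 <- ringStart[j] + nxt(seq_len(nAng)) - 1L
    o0 <- ringStart[j + 1L] + seq_len(nAng) - 1L
    o1 <- ringStart[j + 1L] + nxt(seq_len(nAng)) - 1L
    F <- rbind(F, cbind(i0, o0, o1), cbind(i0, o1, i1))
  }
  lab <- rep("roi", nrow(F))

  # ---- shaft skirt: extrude the boundary ring downward with taper
  nSeg <- max(3L, as.integer(ceiling(spec@shaftDepthMm / (2 * h))))
  prevStart <- ringStart[nRing]
  for (k in seq_len(nSeg)) {
    f <- k / nSeg
    s <- 1 - (1 - spec@shaftTaper) * f
    x <- s * a * cos(theta); y <- s * b * sin(theta)
    newStart <- nrow(V) + 1L
    V <- rbind(V, cbind(x, y, -f * spec@shaftDepthMm))
    u0 <- prevStart + seq_len(nAng) - 1L
    u1 <- prevStart + nxt(seq_len(nAng)) - 1L
    d0 <- newStart + seq_len(nAng) - 1L
    d1 <- newStart + nxt(seq_len(nAng)) - 1L
    F <- rbind(F, cbind(u0, d1, d0), cbind(u0, u1, d1))
    lab <- c(lab, rep("object", 2L * nAng))
    prevStart <- newStart
  }
  # bottom cap
  cIdx <- nrow(V) + 1L
  V <- rbind(V, c(0, 0, -spec@shaftDepthMm))
  u0 <- prevStart + seq_len(nAng) - 1L
  u1 <- prevStart + nxt(seq_len(nAng)) - 1L
  F <- rbind(F, cbind(cIdx, u1, u0))
  lab <- c(lab, rep("object", nAng))

  # ---- cubic registration block
  cube <- .makeCube(side)
  placement <- blockPlacement(spec)
  cubeV <- applyTransform(cube$vertices, placement)
  F <- rbind(F, cube$faces + nrow(V))
  V <- rbind(V, cubeV)
  lab <- c(lab, cube$labels)

  triangleMesh(V, F, lab)
}

# unit-placement cube centered at the origin; labels follow the selection
# convention: 1 = top (+z), 2 = outward front (-y), 3 = +x lateral,
# 4 = -x lateral, attached = +y (toward the object), other = bottom (-z)
.makeCube <- function(side) {
  s <- side / 2
  V <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  dimnames(V) <- NULL
  # vertex order: (-,-,-)(+,-,-)(-,+,-)(+,+,-)(-,-,+)(+,-,+)(-,+,+)(+,+,+)
  quad <- function(i1, i2, i3, i4) rbind(c(i1, i2, i3), c(i1, i3, i4))
  F <- rbind(
    quad(5L, 6L, 8L, 7L),  # +z top
    quad(1L, 2L, 6L, 5L),  # -y front
    quad(2L, 4L, 8L, 6L),  # +x lateral
    quad(3L, 1L, 5L, 7L),  # -x lateral
    quad(4L, 3L, 7L, 8L),  # +y attached
    quad(3L, 4L, 2L, 1L))  # -z bottom
  labels <- rep(c("block_face_1", "block_face_2", "block_face_3",
                  "block_face_4", "block_attached", "block_other"),
                each = 2L)
  list(vertices = V, faces = F, labels = labels)
}

#' Simulate a structured-light surface scan
#'
#' Samples the mesh surface quasi-uniformly at area density
#' `1 / pointSpacingMm^2` (area-weighted triangle sampling with uniform
#' barycentric coordinates), adds isotropic Gaussian measurement noise of sd
#' `noiseSdMm` along the local facet normal, then moves the whole cloud by
#' `pose`. Triangles labeled as the block's attached face are not scannable
#' and are excluded. Per-point labels and facet normals are carried along.
#' Output is bitwise-reproducible for a given `scan@seed`.
#'
#' @param mesh a labeled [TriangleMesh-class].
#' @param scan a [ScanSpec-class].
#' @param pose rigid pose applied to the sampled cloud (default identity).
#' @param attachedFace label of the unscannable face.
#' @return a [PointCloud-class] with normals and labels.
#' @export
simulateScan <- function(mesh, scan = scanSpec(), pose = identityTransform(),
                         attachedFace = "block_attached") {
  validObject(scan)
  V <- mesh@vertices
  bbox <- apply(V[, 1:2, drop = FALSE], 2, range)
  fovSide <- sqrt(scan@fovAreaCm2 * 100)
  if (any(bbox[2, ] - bbox[1, ] > fovSide))
    .stopInvalid(sprintf(
      "phantom footprint %.0f x %.0f mm exceeds the %.0f mm field-of-view side",
      bbox[2, 1] - bbox[1, 1], bbox[2, 2] - bbox[1, 2], fovSide))
  F <- mesh@faces
  labs <- mesh@faceLabels
  keep <- if (length(labs)) labs != attachedFace else rep(TRUE, nrow(F))
  F <- F[keep, , drop = FALSE]
  labs <- if (length(labs)) labs[keep] else character()
  areas <- .triAreas(V, F)
  nrm <- .triNormals(V, F)
  nTotal <- max(1L, as.integer(round(sum(areas) / scan@pointSpacingMm^2)))
  .withSeed(scan@seed, {
    counts <- as.vector(stats::rmultinom(1, nTotal, areas / sum(areas)))
    fi <- rep.int(seq_len(nrow(F)), counts)
    A <- V[F[fi, 1], , drop = FALSE]
    B <- V[F[fi, 2], , drop = FALSE]
    C <- V[F[fi, 3], , drop = FALSE]
    r1 <- stats::runif(nTotal); r2 <- stats::runif(nTotal)
    flip <- r1 + r2 > 1
    r1[flip] <- 1 - r1[flip]; r2[flip] <- 1 - r2[flip]
    P <- A + r1 * (B - A) + r2 * (C - A)
    N <- nrm[fi, , drop = FALSE]
    if (scan@noiseSdMm > 0)
      P <- P + N * stats::rnorm(nTotal, 0, scan@noiseSdMm)
    cl <- pointCloud(P, normals = N,
                     labels = if (length(labs)) labs[fi] else NULL)
    applyTransform(cl, pose)
  })
}

#' Generate a reference/target scan pair with known ground truth
#'
#' Simulates two scans of the same phantom: a reference, and a target that
#' additionally carries a random rigid perturbation `truth` drawn within the
#' scan spec's perturbation bounds (emulating repositioning between time
#' points). Reference and target sampling noise are independent unless
#' `identicalSampling = TRUE`, which reuses the reference sampling for the
#' target (two copies of the *identical* model, the zero-baseline
#' condition).
#'
#' @param phantom a [PhantomSpec-class].
#' @param scan a [ScanSpec-class]; its `seed` drives all randomness.
#' @param identicalSampling reuse the reference sampling for the target.
#' @return a list with elements `reference` and `target`
#'   ([PointCloud-class]s), `truth` (the [RigidTransform-class] moving the
#'   unperturbed target into its observed pose), and `mesh` (the phantom
#'   [TriangleMesh-class]).
#' @export
makePair <- function(phantom, scan = scanSpec(), identicalSampling = FALSE) {
  mesh <- makePhantom(phantom)
  refSeed <- .subSeed(scan@seed, 0L, 1L)
  tgtSeed <- if (identicalSampling) refSeed else .subSeed(scan@seed, 0L, 2L)
  truth <- .withSeed(.subSeed(scan@seed, 0L, 3L),
                     randomRigidTransform(scan@maxRotationDeg,
                                          scan@maxTranslationMm))
  reference <- simulateScan(mesh, .reseed(scan, refSeed))
  target <- applyTransform(simulateScan(mesh, .reseed(scan, tgtSeed)), truth)
  list(reference = reference, target = target, truth = truth, mesh = mesh)
}

.reseed <- function(scan, seed) {
  scan@seed <- as.integer(seed)
  scan
}
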