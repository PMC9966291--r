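#' @include AllClasses.R AllGenerics.R
NULL

.deviationStats <- function(distMm) {
  um <- distMm * 1000
  new("DeviationStats", meanUm = mean(um), sdUm = stats::sd(um),
      maxUm = max(um), medianUm = stats::median(um),
      p95Um = as.numeric(stats::quantile(um, 0.95, names = FALSE)),
      nPoints = length(um))
}

#' Mean surface variation between registered surfaces
#'
#' Registration error metric: the unsigned distance from each point of the
#' registered target ROI to the reference ROI, summarized in micrometres.
#' With a reference [PointCloud-class] the distance is to the nearest
#' reference point; with a reference [TriangleMesh-class] it is the
#' point-to-mesh distance. Registering two identical models perfectly
#' yields a surface variation of zero, so any deviation from zero measures
#' registration error.
#'
#' @param registeredTarget the target ROI [PointCloud-class], already moved
#'   by the block-derived transform.
#' @param reference the reference ROI as [PointCloud-class] or
#'   [TriangleMesh-class].
#' @return a [DeviationStats-class] (um).
#' @export
surfaceVariation <- function(registeredTarget, reference) {
  P <- .asPointMatrix(registeredTarget, "registeredTarget")
  if (nrow(P) < 1) .stopInvalid("registered target ROI is empty")
  d <- if (is(reference, "TriangleMesh")) {
    pointMeshDistance(P, reference)
  } else {
    R <- .asPointMatrix(reference, "reference")
    if (nrow(R) < 1) .stopInvalid("reference ROI is empty")
    nearestNeighbors(P, R)$distance
  }
  .deviationStats(d)
}

#' Per-point surface variation
#'
#' The per-point unsigned distances underlying [surfaceVariation()], in um.
#'
#' @inheritParams surfaceVariation
#' @return numeric vector of distances (um).
#' @export
surfaceVariationField <- function(registeredTarget, reference) {
  P <- .asPointMatrix(registeredTarget, "registeredTarget")
  d <- if (is(reference, "TriangleMesh")) {
    pointMeshDistance(P, reference)
  } else {
    nearestNeighbors(P, .asPointMatrix(reference, "reference"))$distance
  }
  d * 1000
}

#' Ground-truth target registration error
#'
#' Available only in simulation, where the true perturbation is known:
#' summarizes `|(tEst o truth) x - x|` over evaluation points, i.e. the
#' residual displacement the estimated transform leaves after undoing the
#' known perturbation. Zero everywhere iff `tEst` is exactly the inverse of
#' `truth`.
#'
#' @param tEst estimated [RigidTransform-class] (target to reference).
#' @param truth the true perturbation applied to the target.
#' @param evalPoints a [PointCloud-class] or matrix of evaluation points in
#'   the unperturbed frame (typically the ROI).
#' @return a [DeviationStats-class] (um).
#' @export
targetRegistrationError <- function(tEst, truth, evalPoints) {
  P <- .asPointMatrix(evalPoints, "evalPoints")
  if (nrow(P) < 1) .stopInvalid("evalPoints is empty")
  resid <- composeTransforms(tEst, truth)
  d <- sqrt(rowSums((applyTransform(P, resid) - P)^2))
  .deviationStats(d)
}

#' Per-point deviation map
#'
#' Computes the per-point surface-variation scalar field of a registered
#' target against the reference surface, with a color palette for export
#' (the colorimetric deviation-map analog). The default palette bounds are
#' 0 to 3x the median deviation.
#'
#' @param registeredTarget registered target [PointCloud-class].
#' @param reference reference [PointCloud-class] or [TriangleMesh-class].
#' @param paletteRangeUm length-2 palette bounds in um, or `NULL` for the
#'   default.
#' @param nColors number of palette colors.
#' @return a list with `cloud` (the target cloud), `fieldUm` (per-point
#'   deviation, um), `colors` (per-point hex colors) and `paletteRangeUm`.
#' @export
deviationMap <- function(registeredTarget, reference,
                         paletteRangeUm = NULL, nColors = 64L) {
  fieldUm <- surfaceVariationField(registeredTarget, reference)
  if (is.null(paletteRangeUm))
    paletteRangeUm <- c(0, max(3 * stats::median(fieldUm),
                               .Machine$double.eps))
  pal <- grDevices::hcl.colors(nColors, "Blue-Red 3")
  idx <- pmin(nColors, pmax(1L, 1L + as.integer(floor(
    (fieldUm - paletteRangeUm[1]) / diff(paletteRangeUm) * (nColors - 1L)))))
  list(cloud = if (is(registeredTarget, "PointCloud")) registeredTarget
               else pointCloud(registeredTarget),
       fieldUm = fieldUm, colors = pal[idx],
       paletteRangeUm = paletteRangeUm)
}

#' Export a deviation map as a colored PLY
#'
#' Writes the cloud with per-vertex colors and the deviation scalar stored
#' in a `quality` property; the scalar field round-trips losslessly through
#' [readPly()].
#'
#' @param map result of [deviationMap()].
#' @param path output PLY path.
#' @param binary write binary little-endian PLY (default ASCII).
#' @return `path`, invisibly.
#' @export
writeDeviationPly <- function(map, path, binary = FALSE) {
  writePly(map$cloud, path, binary = binary, scalars = map$fieldUm,
           colors = map$colors)
}

#' Spatial trend of registration error with distance from the fiducial
#'
#' Tests whether per-point ROI error grows with distance from the
#' registration block (error propagating away from a too-small fiducial):
#' Spearman rank correlation between point-to-block distance and per-point
#' deviation, with a permutation p-value.
#'
#' @param roiRegistered registered target ROI [PointCloud-class].
#' @param roiReference reference ROI cloud or mesh.
#' @param blockCloud reference block-face [PointCloud-class] (distance
#'   origin).
#' @param nSample number of ROI points subsampled for the test.
#' @param nPerm number of permutations.
#' @param seed RNG seed for subsampling/permutation.
#' @return list with `rho`, `pValue`, `n`.
#' @export
spatialErrorTrend <- function(roiRegistered, roiReference, blockCloud,
                              nSample = 2000L, nPerm = 999L, seed = 1L) {
  fieldUm <- surfaceVariationField(roiRegistered, roiReference)
  dBlock <- nearestNeighbors(roiRegistered, blockCloud)$distance
  .withSeed(seed, {
    n <- length(fieldUm)
    if (n > nSample) {
      i <- sample.int(n, nSample)
      fieldUm <- fieldUm[i]
      dBlock <- dBlock[i]
    }
    rx <- rank(dBlock)
    ry <- rank(fieldUm)
    rho <- stats::cor(rx, ry)
    # permutation null: shuffle the error ranks
    rx0 <- rx - mean(rx)
    denom <- sum(rx0^2)  # equals sum((ry - mean)^2) for untied ranks
    ry0 <- ry - mean(ry)
    perm <- replicate(nPerm, sum(rx0 * sample(ry0)) /
                              sqrt(denom * sum(ry0^2)))
    p <- (1 + sum(perm >= rho)) / (nPerm + 1)
    list(rho = rho, pValue = p, n = length(fieldUm))
  })
}
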