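#' @import methods
NULL

# ---------------------------------------------------------------- transforms

#' Rigid transform in 3-d
#'
#' A proper rigid transform `x -> R x + t` with a 3x3 rotation matrix `R`
#' (orthonormal, determinant +1) and a translation vector `t` in mm. Rigid
#' transforms carry the registration result from the fiducial block to the
#' whole scanned model, so the class enforces orthonormality at construction.
#'
#' @slot rotation 3x3 rotation matrix (dimensionless).
#' @slot translation length-3 translation vector (mm).
#' @slot metadata free-form list (e.g. provenance of a rough alignment).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 metadata = "list"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), metadata = list()))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  t <- object@translation
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)) || any(!is.finite(R)))
    return("rotation must be a finite 3x3 numeric matrix")
  if (length(t) != 3L || any(!is.finite(t)))
    return("translation must be a finite length-3 numeric vector")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthonormal (|R'R - I| > 1e-8)")
  if (det(R) < 0)
    return("rotation is a reflection (determinant -1)")
  TRUE
})

# ------------------------------------------------------------------ geometry

#' Triangle mesh surface
#'
#' A triangulated surface with vertices in mm, 1-based face indices and
#' optional per-face region labels (e.g. `"roi"`, `"object"`,
#' `"block_face_1"`). Labels drive feature extraction downstream.
#'
#' @slot vertices n x 3 numeric matrix of coordinates (mm).
#' @slot faces m x 3 integer matrix of vertex indices (1-based).
#' @slot faceLabels character vector of length m, or length 0 when unlabeled.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 faceLabels = "character"))

setValidity("TriangleMesh", function(object) {
  V <- object@vertices
  F <- object@faces
  if (ncol(V) != 3L || any(!is.finite(V)))
    return("vertices must be a finite n x 3 matrix")
  if (ncol(F) != 3L || nrow(F) < 1L)
    return("faces must be an m x 3 index matrix with m >= 1")
  if (any(F < 1L) || any(F > nrow(V)))
    return("face indices out of range")
  if (length(object@faceLabels) != 0L &&
      length(object@faceLabels) != nrow(F))
    return("faceLabels must be empty or one label per face")
  if (.meshArea(V, F) <= 0)
    return("surface area must be strictly positive")
  TRUE
})

#' Point cloud
#'
#' A set of 3-d points in mm with optional unit normals and per-point region
#' labels. Simulated scans carry labels inherited from the phantom mesh,
#' which stand in for the manual segmentation a scanner operator performs.
#'
#' @slot points n x 3 numeric matrix (mm).
#' @slot normals n x 3 matrix of unit normals, or 0 x 3 when absent.
#' @slot labels character vector of length n, or length 0 when unlabeled.
#' @export
setClass("PointCloud",
  representation(points = "matrix", normals = "matrix", labels = "character"),
  prototype(normals = matrix(numeric(), 0, 3), labels = character()))

setValidity("PointCloud", function(object) {
  P <- object@points
  N <- object@normals
  if (ncol(P) != 3L || any(!is.finite(P)))
    return("points must be a finite n x 3 matrix")
  if (nrow(N) != 0L) {
    if (!identical(dim(N), dim(P)) || any(!is.finite(N)))
      return("normals must be absent or a finite n x 3 matrix")
    nrm <- sqrt(rowSums(N^2))
    if (any(abs(nrm - 1) > 1e-6))
      return("normals must have unit norm within 1e-6")
  }
  if (length(object@labels) != 0L && length(object@labels) != nrow(P))
    return("labels must be empty or one label per point")
  TRUE
})

# ---------------------------------------------------------------- statistics

#' Deviation statistics
#'
#' Summary of unsigned per-point distances (surface variation or target
#' registration error), reported in micrometres.
#'
#' @slot meanUm,sdUm,maxUm,medianUm,p95Um summary statistics (um).
#' @slot nPoints number of points summarized.
#' @export
setClass("DeviationStats",
  representation(meanUm = "numeric", sdUm = "numeric", maxUm = "numeric",
                 medianUm = "numeric", p95Um = "numeric",
                 nPoints = "integer"))

setValidity("DeviationStats", function(object) {
  if (object@nPoints < 1L) return("nPoints must be >= 1")
  v <- c(object@meanUm, object@maxUm, object@medianUm, object@p95Um)
  if (any(!is.finite(v)) || any(v < 0))
    return("distance statistics must be finite and non-negative")
  if (object@meanUm > object@maxUm + 1e-9)
    return("mean exceeds max")
  TRUE
})

# -------------------------------------------------------------- registration

#' ICP parameters
#'
#' @slot maxIterations iteration cap (default 100).
#' @slot convergenceTolMm absolute change in RMS correspondence distance (mm)
#'   below which the iteration is declared converged (default 1e-7).
#' @slot trimFraction fraction of worst correspondences rejected each
#'   iteration, in `[0, 0.5]` (default 0: the reference and target are scans
#'   of identical morphology, so there are no outliers by construction).
#' @slot pointToPlane use the point-to-plane error metric (requires
#'   reference normals); point-to-point is the default variant.
#' @export
setClass("IcpParams",
  representation(maxIterations = "integer", convergenceTolMm = "numeric",
                 trimFraction = "numeric", pointToPlane = "logical"),
  prototype(maxIterations = 100L, convergenceTolMm = 1e-7,
            trimFraction = 0, pointToPlane = FALSE))

setValidity("IcpParams", function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!(object@convergenceTolMm > 0)) return("convergenceTolMm must be > 0")
  if (object@trimFraction < 0 || object@trimFraction > 0.5)
    return("trimFraction must be in [0, 0.5]")
  TRUE
})

#' ICP registration result
#'
#' @slot transform estimated [RigidTransform-class] mapping the source
#'   (target scan) into the reference frame.
#' @slot rmsTrace RMS correspondence distance (mm) recorded at each
#'   correspondence step.
#' @slot converged whether the RMS change fell below the tolerance.
#' @slot nIterations number of transform updates performed.
#' @slot metadata free-form list (e.g. degenerate rough-alignment flag).
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", rmsTrace = "numeric",
                 converged = "logical", nIterations = "integer",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("RegistrationResult", function(object) {
  if (any(object@rmsTrace < 0)) return("rmsTrace must be non-negative")
  if (object@nIterations < 0L) return("nIterations must be >= 0")
  TRUE
})

# ---------------------------------------------------------------- spec types

#' Cubic registration block specification
#'
#' The fiducial is a cube characterized by the cross-sectional area of one
#' face. The study sizes are 4, 1 and 0.25 cm2 (sides 2, 1 and 0.5 cm). The
#' face glued to the object is not scannable and can never be selected.
#'
#' @slot csaCm2 face cross-sectional area (cm2).
#' @slot pose [RigidTransform-class] placing the cube on the phantom.
#' @slot attachedFace label of the glued face.
#' @export
setClass("BlockSpec",
  representation(csaCm2 = "numeric", pose = "RigidTransform",
                 attachedFace = "character"),
  prototype(csaCm2 = 4, attachedFace = "block_attached"))

setValidity("BlockSpec", function(object) {
  if (!(object@csaCm2 > 0)) return("csaCm2 must be > 0")
  TRUE
})

#' Scan simulation specification
#'
#' Parameters of the simulated structured-light acquisition: field of view,
#' sampling resolution, measurement noise, the master seed, and the magnitude
#' of the random rigid perturbation applied to the target before
#' registration (standing in for repositioning between time points).
#'
#' @slot fovAreaCm2 scanner field of view (cm2, default 200).
#' @slot pointSpacingMm sampling resolution (mm, default 0.12).
#' @slot noiseSdMm Gaussian measurement noise sd along the surface normal
#'   (mm, default 0.02).
#' @slot seed integer master seed; identical seeds give bitwise-identical
#'   clouds.
#' @slot maxRotationDeg,maxTranslationMm perturbation magnitude bounds.
#' @export
setClass("ScanSpec",
  representation(fovAreaCm2 = "numeric", pointSpacingMm = "numeric",
                 noiseSdMm = "numeric", seed = "integer",
                 maxRotationDeg = "numeric", maxTranslationMm = "numeric"),
  prototype(fovAreaCm2 = 200, pointSpacingMm = 0.12, noiseSdMm = 0.02,
            seed = 1L, maxRotationDeg = 10, maxTranslationMm = 10))

setValidity("ScanSpec", function(object) {
  if (!(object@pointSpacingMm > 0)) return("pointSpacingMm must be > 0")
  if (object@noiseSdMm < 0) return("noiseSdMm must be >= 0")
  if (!(object@fovAreaCm2 > 0)) return("fovAreaCm2 must be > 0")
  if (object@maxRotationDeg < 0 || object@maxTranslationMm < 0)
    return("perturbation magnitudes must be >= 0")
  TRUE
})

#' Phantom specification
#'
#' A parametric analog of a tibial plateau: a smoothly undulating elliptical
#' plateau patch (the analyzed region of interest) atop a tapered shaft,
#' with a cubic registration block held anterior of the plateau at a
#' configurable standoff.
#'
#' @slot plateauSemiAxesMm semi-axes of the elliptical plateau (mm).
#' @slot roughnessAmplitudeMm amplitude of the low-frequency plateau
#'   undulation (mm).
#' @slot roughnessWavelengthMm wavelengths of the 3 sinusoidal components
#'   (mm).
#' @slot shaftDepthMm depth of the tapered shaft below the plateau (mm).
#' @slot shaftTaper ratio of bottom to top shaft cross-section.
#' @slot block [BlockSpec-class] of the attached fiducial.
#' @slot standoffMm gap between the block and the plateau boundary (mm).
#' @slot meshResolutionMm target edge length of the generated triangulation
#'   (mm).
#' @export
setClass("PhantomSpec",
  representation(plateauSemiAxesMm = "numeric",
                 roughnessAmplitudeMm = "numeric",
                 roughnessWavelengthMm = "numeric",
                 shaftDepthMm = "numeric", shaftTaper = "numeric",
                 block = "BlockSpec", standoffMm = "numeric",
                 meshResolutionMm = "numeric"),
  prototype(plateauSemiAxesMm = c(30, 20), roughnessAmplitudeMm = 2,
            roughnessWavelengthMm = c(23, 31, 17), shaftDepthMm = 30,
            shaftTaper = 0.65, standoffMm = 10, meshResolutionMm = 1.5))

setValidity("PhantomSpec", function(object) {
  if (length(object@plateauSemiAxesMm) != 2L ||
      any(object@plateauSemiAxesMm <= 0))
    return("plateauSemiAxesMm must be two positive semi-axes")
  if (object@roughnessAmplitudeMm < 0)
    return("roughnessAmplitudeMm must be >= 0")
  if (object@shaftDepthMm <= 0) return("shaftDepthMm must be > 0")
  if (object@shaftTaper <= 0 || object@shaftTaper > 1)
    return("shaftTaper must be in (0, 1]")
  if (object@standoffMm < 0) return("standoffMm must be >= 0")
  if (!(object@meshResolutionMm > 0)) return("meshResolutionMm must be > 0")
  TRUE
})

#' Planar feature selection
#'
#' The subset of the cube's four selectable faces used to compute the
#' registration transform. Faces are numbered 1 (top, most parallel to the
#' analyzed surface), 2 (outward front), 3 and 4 (laterals); the attached
#' face and the bottom face are never selectable.
#'
#' @slot faces ordered unique integer subset of `1:4`.
#' @export
setClass("PlaneSelection", representation(faces = "integer"))

setValidity("PlaneSelection", function(object) {
  f <- object@faces
  if (length(f) < 1L) return("selection must be nonempty")
  if (anyDuplicated(f)) return("selection contains duplicate faces")
  if (any(f < 1L | f > 4L))
    return("faces must be drawn from 1:4 (attached and bottom faces are not selectable)")
  TRUE
})

#' Region-of-interest specification
#'
#' The analysis region (plateau analog) is selected either by its region
#' label or by a planar snipping polygon applied in the xy plane; the same
#' RoiSpec applied to reference and target guarantees a consistent region.
#'
#' @slot label region label (default `"roi"`); ignored when a polygon is
#'   given.
#' @slot polygon k x 2 matrix of polygon vertices (mm) in the xy plane, or
#'   0 x 2 when selection is by label.
#' @slot minPoints minimum admissible number of selected points.
#' @export
setClass("RoiSpec",
  representation(label = "character", polygon = "matrix",
                 minPoints = "integer"),
  prototype(label = "roi", polygon = matrix(numeric(), 0, 2),
            minPoints = 100L))

setValidity("RoiSpec", function(object) {
  if (nrow(object@polygon) != 0L &&
      (ncol(object@polygon) != 2L || nrow(object@polygon) < 3L))
    return("polygon must be a k x 2 matrix with k >= 3")
  if (object@minPoints < 1L) return("minPoints must be >= 1")
  TRUE
})
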