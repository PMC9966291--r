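#' @include AllClasses.R
NULL

#' Accessors for geometric objects
#'
#' `vertices()`, `faces()` and `faceLabels()` access [TriangleMesh-class]
#' slots; `coords()`, `normals()`, `pointLabels()` and `nPoints()` access
#' [PointCloud-class] slots; `rotation()` and `translation()` access
#' [RigidTransform-class] slots.
#'
#' @param x the object.
#' @return the slot contents (a matrix, character vector or count).
#' @name accessors
#' @aliases vertices faces faceLabels coords normals pointLabels nPoints
#'   rotation translation
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("faceLabels", function(x) standardGeneric("faceLabels"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("normals", function(x) standardGeneric("normals"))
#' @rdname accessors
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' Surface area of a mesh
#'
#' @param x a [TriangleMesh-class].
#' @param byLabel if `TRUE`, return a named vector of per-label areas.
#' @return total surface area in mm2, or a named vector.
#' @export
setGeneric("surfaceArea", function(x, byLabel = FALSE)
  standardGeneric("surfaceArea"))

#' Apply a rigid transform
#'
#' Applies `transform` to a coordinate matrix, a [PointCloud-class]
#' (normals are rotated, labels preserved) or a [TriangleMesh-class].
#'
#' @param x object to transform.
#' @param transform a [RigidTransform-class].
#' @return the transformed object, same class as `x`.
#' @export
setGeneric("applyTransform", function(x, transform)
  standardGeneric("applyTransform"))
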