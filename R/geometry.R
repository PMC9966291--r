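#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param faceLabels optional character vector, one label per face.
#' @return a [TriangleMesh-class].
#' @export
triangleMesh <- function(vertices, faces, faceLabels = character()) {
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(faces), nrow(faces), ncol(faces))
  new("TriangleMesh", vertices = vertices, faces = faces,
      faceLabels = as.character(faceLabels))
}

#' Construct a point cloud
#'
#' @param points n x 3 numeric matrix (mm).
#' @param normals optional n x 3 matrix of unit normals.
#' @param labels optional character vector, one label per point.
#' @return a [PointCloud-class].
#' @export
pointCloud <- function(points, normals = NULL, labels = NULL) {
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (is.null(normals)) normals <- matrix(numeric(), 0, 3)
  else dimnames(normals) <- NULL
  if (is.null(labels)) labels <- character()
  new("PointCloud", points = points, normals = normals,
      labels = as.character(labels))
}

#' @rdname accessors
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("faces", "TriangleMesh", function(x) x@faces)
#' @rdname accessors
setMethod("faceLabels", "TriangleMesh", function(x) x@faceLabels)
#' @rdname accessors
setMethod("coords", "PointCloud", function(x) x@points)
#' @rdname accessors
setMethod("normals", "PointCloud", function(x) x@normals)
#' @rdname accessors
setMethod("pointLabels", "PointCloud", function(x) x@labels)
#' @rdname accessors
setMethod("nPoints", "PointCloud", function(x) nrow(x@points))

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces, area %.1f mm2\n",
              nrow(object@vertices), nrow(object@faces),
              surfaceArea(object)))
  if (length(object@faceLabels))
    cat("  labels:", paste(names(table(object@faceLabels)), collapse = ", "),
        "\n")
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points%s%s\n", nrow(object@points),
              if (nrow(object@normals)) ", with normals" else "",
              if (length(object@labels)) ", labeled" else ""))
})

setMethod("show", "DeviationStats", function(object) {
  cat(sprintf(
    "DeviationStats: mean %.3g um, sd %.3g um, median %.3g um, p95 %.3g um, max %.3g um (n = %d)\n",
    object@meanUm, object@sdUm, object@medianUm, object@p95Um,
    object@maxUm, object@nPoints))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(
    "RegistrationResult: %d iterations, %sconverged, final RMS %.3g mm\n",
    object@nIterations, if (object@converged) "" else "NOT ",
    utils::tail(object@rmsTrace, 1)))
  show(object@transform)
})

#' @rdname surfaceArea
setMethod("surfaceArea", "TriangleMesh", function(x, byLabel = FALSE) {
  a <- .triAreas(x@vertices, x@faces)
  if (!byLabel) return(sum(a))
  if (!length(x@faceLabels)) .stopInvalid("mesh has no face labels")
  vapply(split(a, x@faceLabels), sum, numeric(1))
})

#' Subset a mesh by face label
#'
#' @param x a labeled [TriangleMesh-class].
#' @param labels face labels to keep.
#' @return the labeled submesh (unused vertices dropped).
#' @export
meshSubset <- function(x, labels) {
  if (!length(x@faceLabels)) .stopInvalid("mesh has no face labels")
  keep <- x@faceLabels %in% labels
  if (!any(keep)) .stopEmptySelection(sprintf(
    "no faces carry labels %s", paste(labels, collapse = ", ")))
  F <- x@faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(x@vertices))
  remap[used] <- seq_along(used)
  triangleMesh(x@vertices[used, , drop = FALSE],
               matrix(remap[F], ncol = 3), x@faceLabels[keep])
}

#' Subset a point cloud
#'
#' @param x a [PointCloud-class].
#' @param i logical or integer index over points.
#' @return the subsetted [PointCloud-class].
#' @export
subsetCloud <- function(x, i) {
  n <- x@normals
  if (nrow(n) > 0) n <- n[i, , drop = FALSE]
  l <- x@labels
  if (length(l) > 0) l <- l[i]
  new("PointCloud", points = x@points[i, , drop = FALSE],
      normals = n, labels = l)
}

#' Nearest neighbors between point clouds
#'
#' For every query point, finds the reference point attaining the minimum
#' Euclidean distance (KD-tree search). Ties are broken by the lowest
#' reference index, so results are deterministic across platforms.
#'
#' @param query,reference [PointCloud-class]s or n x 3 matrices; `reference`
#'   must be nonempty.
#' @return a list with `index` (1-based into `reference`) and `distance`
#'   (mm), each of length `nrow(query)`.
#' @export
nearestNeighbors <- function(query, reference) {
  Q <- .asPointMatrix(query, "query")
  R <- .asPointMatrix(reference, "reference")
  if (nrow(R) < 1) .stopInvalid("reference point set is empty")
  tree <- .kd_build(R)
  .kd_query(tree, Q)
}

#' Unsigned point-to-mesh distance
#'
#' Minimum unsigned Euclidean distance from each query point to any triangle
#' of the surface (interior, edge and vertex regions all handled).
#'
#' @param query a [PointCloud-class] or n x 3 matrix.
#' @param surface a [TriangleMesh-class] with at least one face.
#' @return numeric vector of distances (mm).
#' @export
pointMeshDistance <- function(query, surface) {
  Q <- .asPointMatrix(query, "query")
  if (!is(surface, "TriangleMesh")) .stopInvalid("surface must be a TriangleMesh")
  if (nrow(surface@faces) < 1) .stopInvalid("mesh has no faces")
  .point_mesh_distance(Q, surface@vertices, surface@faces)
}
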