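#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (mm).
#' @param metadata optional list of annotations.
#' @return a [RigidTransform-class].
#' @examples
#' rigidTransform()                      # identity
#' rigidTransform(translation = c(1, 0, 0))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           metadata = list()) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), metadata = metadata)
}

#' @rdname rigidTransform
#' @export
identityTransform <- function() rigidTransform()

#' @rdname accessors
setMethod("rotation", "RigidTransform", function(x) x@rotation)
#' @rdname accessors
setMethod("translation", "RigidTransform", function(x) x@translation)

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngleDeg(object)
  cat(sprintf("RigidTransform: rotation %.4g deg, translation %.4g mm\n",
              ang, sqrt(sum(object@translation^2))))
})

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` is the transform that applies `b` first, then
#' `a`.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return the composed [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  R <- a@rotation %*% b@rotation
  # re-orthonormalize to keep long compositions within the class invariant
  s <- svd(R)
  R <- s$u %*% t(s$v)
  rigidTransform(R, as.vector(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(x) {
  Rt <- t(x@rotation)
  rigidTransform(Rt, -as.vector(Rt %*% x@translation))
}

#' Rotation angle of a transform
#'
#' @param x a [RigidTransform-class].
#' @return rotation angle in degrees, in `[0, 180]`.
#' @export
rotationAngleDeg <- function(x) {
  ctheta <- (sum(diag(x@rotation)) - 1) / 2
  acos(min(1, max(-1, ctheta))) * 180 / pi
}

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
  if (ncol(x) != 3) .stopInvalid("coordinate matrix must have 3 columns")
  x %*% t(transform@rotation) +
    matrix(transform@translation, nrow(x), 3, byrow = TRUE)
})

#' @rdname applyTransform
setMethod("applyTransform", "PointCloud", function(x, transform) {
  p <- applyTransform(x@points, transform)
  n <- x@normals
  if (nrow(n) > 0) n <- n %*% t(transform@rotation)
  new("PointCloud", points = p, normals = n, labels = x@labels)
})

#' @rdname applyTransform
setMethod("applyTransform", "TriangleMesh", function(x, transform) {
  new("TriangleMesh", vertices = applyTransform(x@vertices, transform),
      faces = x@faces, faceLabels = x@faceLabels)
})

#' Homogeneous matrix representation
#'
#' Convert between a [RigidTransform-class] and its 4x4 homogeneous matrix.
#'
#' @param x a [RigidTransform-class] (for `asHomogeneousMatrix`) or a 4x4
#'   matrix (for `fromHomogeneousMatrix`).
#' @return a 4x4 matrix, or a [RigidTransform-class].
#' @export
asHomogeneousMatrix <- function(x) {
  m <- diag(4)
  m[1:3, 1:3] <- x@rotation
  m[1:3, 4] <- x@translation
  m
}

#' @rdname asHomogeneousMatrix
#' @export
fromHomogeneousMatrix <- function(x) {
  if (!is.matrix(x) || !identical(dim(x), c(4L, 4L)))
    .stopInvalid("expected a 4x4 homogeneous matrix")
  rigidTransform(x[1:3, 1:3], x[1:3, 4])
}

#' Read / write a transform as JSON
#'
#' Transforms are serialized as a 4x4 row-major homogeneous matrix under the
#' key `"matrix"`.
#'
#' @param x a [RigidTransform-class].
#' @param path file path.
#' @return `readTransformJson` returns a [RigidTransform-class];
#'   `writeTransformJson` returns `path` invisibly.
#' @export
writeTransformJson <- function(x, path) {
  m <- asHomogeneousMatrix(x)
  jsonlite::write_json(
    list(matrix = lapply(seq_len(4), function(i) m[i, ])),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTransformJson
#' @export
readTransformJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- j$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  fromHomogeneousMatrix(matrix(as.numeric(m), 4, 4, byrow = !is.matrix(j$matrix)))
}

#' Random rigid transform, uniform over bounded rotation and translation
#'
#' The rotation is drawn uniformly over the ball of axis-angle vectors with
#' angle at most `maxRotationDeg`; the translation uniformly over the ball
#' of radius `maxTranslationMm`. Used to perturb the simulated target scan.
#'
#' @param maxRotationDeg maximum rotation angle (degrees).
#' @param maxTranslationMm maximum translation norm (mm).
#' @return a [RigidTransform-class].
#' @export
randomRigidTransform <- function(maxRotationDeg = 10, maxTranslationMm = 10) {
  rotvec <- .runifBall(maxRotationDeg * pi / 180)
  tvec <- .runifBall(maxTranslationMm)
  rigidTransform(.axisAngleToMatrix(rotvec), tvec)
}

# uniform sample in the 3-ball of given radius
.runifBall <- function(radius) {
  if (radius <= 0) return(c(0, 0, 0))
  v <- stats::rnorm(3)
  n <- sqrt(sum(v^2))
  if (n == 0) return(c(0, 0, 0))
  v / n * radius * stats::runif(1)^(1 / 3)
}

.axisAngleToMatrix <- function(rotvec) {
  theta <- sqrt(sum(rotvec^2))
  if (theta < 1e-300) return(diag(3))
  k <- rotvec / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Closed-form weighted rigid superposition (Kabsch/SVD)
#'
#' Finds the proper rigid transform `T` minimizing
#' `sum(w_i * |T s_i - t_i|^2)` over paired points. This is the least-squares
#' update step inside ICP. A reflection solution (negative determinant of the
#' optimal orthogonal matrix) is corrected by negating the smallest singular
#' direction, so the result is always a proper rotation.
#'
#' @param source,target paired n x 3 matrices or [PointCloud-class]s, n >= 3.
#' @param weights optional non-negative weights of length n.
#' @return a [RigidTransform-class].
#' @examples
#' s <- matrix(rnorm(30), 10, 3)
#' tr <- randomRigidTransform(20, 5)
#' fit <- kabsch(s, applyTransform(s, tr))
#' max(abs(rotation(fit) - rotation(tr)))   # ~ 1e-15
#' @export
kabsch <- function(source, target, weights = NULL) {
  S <- .asPointMatrix(source, "source")
  T_ <- .asPointMatrix(target, "target")
  n <- nrow(S)
  if (nrow(T_) != n)
    .stopInvalid("source and target must contain the same number of points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || any(!is.finite(weights)))
    .stopInvalid("weights must be non-negative, finite, one per point")
  keep <- weights > 0
  if (sum(keep) < 3)
    .stopInvalid("at least 3 correspondences with positive weight are required")
  S <- S[keep, , drop = FALSE]
  T_ <- T_[keep, , drop = FALSE]
  w <- weights[keep] / sum(weights[keep])
  cs <- colSums(S * w)
  ct <- colSums(T_ * w)
  S0 <- sweep(S, 2, cs)
  T0 <- sweep(T_, 2, ct)
  # degenerate geometry: rotation is underdetermined for (near-)collinear sets
  sv <- svd(S0 * sqrt(w), nu = 0, nv = 0)$d
  rank <- sum(sv > max(sv) * 1e-9)
  if (rank < 2)
    .stopDegenerate(sprintf(
      "source geometry is rank %d (collinear or coincident points); rotation is underdetermined",
      rank), rank = rank)
  H <- crossprod(S0 * w, T0)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  if (d == 0) d <- 1
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  rigidTransform(R, ct - as.vector(R %*% cs))
}
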