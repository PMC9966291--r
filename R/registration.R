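#' @include AllClasses.R AllGenerics.R
NULL

#' Construct ICP parameters
#'
#' @param maxIterations iteration cap.
#' @param convergenceTolMm absolute change in RMS correspondence distance
#'   (mm) declaring convergence.
#' @param trimFraction fraction of worst correspondences rejected per
#'   iteration (`[0, 0.5]`).
#' @param pointToPlane use the point-to-plane error metric (needs reference
#'   normals); point-to-point is the default.
#' @return an [IcpParams-class].
#' @export
icpParams <- function(maxIterations = 100L, convergenceTolMm = 1e-7,
                      trimFraction = 0, pointToPlane = FALSE) {
  new("IcpParams", maxIterations = as.integer(maxIterations),
      convergenceTolMm = convergenceTolMm, trimFraction = trimFraction,
      pointToPlane = isTRUE(pointToPlane))
}

#' Deterministic rough alignment
#'
#' Emulates the manual coarse alignment step: translates the source centroid
#' onto the target centroid and aligns principal axes, with axis signs
#' disambiguated by the sign of the third moment (skewness) of the
#' coordinate distribution along each axis. Axes whose standardized
#' skewness is too small to be a reliable cue (symmetric shapes) are left
#' ambiguous, and every proper-rotation combination of their signs is
#' scored by mean nearest-neighbor distance on a deterministic subsample;
#' the cheapest candidate wins. For isotropic clouds (relative eigenvalue
#' gap below `1e-9`) the rotation is underdetermined and a centroid-only
#' translation is returned, flagged as `degenerate` in the transform
#' metadata.
#'
#' @param source,target [PointCloud-class]s with at least 10 points each.
#' @return a [RigidTransform-class] mapping source onto target.
#' @export
roughAlign <- function(source, target) {
  S <- .asPointMatrix(source, "source")
  T_ <- .asPointMatrix(target, "target")
  if (nrow(S) < 10 || nrow(T_) < 10)
    .stopInvalid("rough alignment needs at least 10 points per cloud")
  fs <- .principalFrame(S)
  ft <- .principalFrame(T_)
  if (fs$degenerate || ft$degenerate)
    return(rigidTransform(diag(3), ft$center - fs$center,
                          metadata = list(degenerate = TRUE)))
  # ambiguous axes (in either cloud) get their sign from candidate scoring
  ambiguous <- which(fs$weakSkew | ft$weakSkew)
  flipSets <- .evenFlipSets(ambiguous)
  best <- NULL
  bestCost <- Inf
  sub <- .strideSample(S, 500L)
  tree <- if (length(flipSets) > 1) .kd_build(T_) else NULL
  for (fl in flipSets) {
    U <- fs$axes
    U[, fl] <- -U[, fl]
    R <- ft$axes %*% t(U)
    s <- svd(R)
    R <- s$u %*% t(s$v)
    cand <- rigidTransform(R, ft$center - as.vector(R %*% fs$center),
                           metadata = list(degenerate = FALSE))
    if (length(flipSets) == 1) return(cand)
    cost <- mean(.kd_query(tree, applyTransform(sub, cand))$distance)
    if (cost < bestCost) {
      bestCost <- cost
      best <- cand
    }
  }
  best
}

# subsets of `axes` of even cardinality (sign flips preserving det = +1),
# in a fixed order so ties resolve deterministically
.evenFlipSets <- function(axes) {
  sets <- list(integer(0))
  if (length(axes) >= 2)
    for (pair in utils::combn(axes, 2, simplify = FALSE))
      sets[[length(sets) + 1L]] <- pair
  sets
}

.strideSample <- function(P, nMax) {
  n <- nrow(P)
  if (n <= nMax) return(P)
  P[unique(as.integer(round(seq(1, n, length.out = nMax)))), , drop = FALSE]
}

.principalFrame <- function(P) {
  ctr <- colMeans(P)
  P0 <- sweep(P, 2, ctr)
  e <- eigen(crossprod(P0) / nrow(P0), symmetric = TRUE)
  ev <- e$values
  gaps <- abs(diff(ev)) / max(ev[1], .Machine$double.eps)
  if (min(gaps) < 1e-9)
    return(list(center = ctr, degenerate = TRUE))
  U <- e$vectors
  proj <- P0 %*% U
  sk <- colMeans(proj^3)
  flip <- sk < 0
  U[, flip] <- -U[, flip]
  sk[flip] <- -sk[flip]
  stdSkew <- sk / pmax(apply(proj, 2, stats::sd)^3, .Machine$double.eps)
  weak <- stdSkew < 0.2
  if (det(U) < 0) {
    j <- which.min(stdSkew)
    U[, j] <- -U[, j]
  }
  list(center = ctr, axes = U, degenerate = FALSE, weakSkew = weak)
}

# Rough alignment of two labeled block-face extracts: faces with the same
# label correspond, so matched per-face centroids (plus points offset along
# each face's mean normal, when normals are present) give an unambiguous
# closed-form fit even for face subsets with symmetric geometry.
.roughAlignFeatures <- function(source, target) {
  if (!length(source@labels) || !length(target@labels))
    return(NULL)
  labs <- intersect(unique(source@labels), unique(target@labels))
  # a single face has genuinely unconstrained in-plane DOFs: fall through to
  # the generic principal-axis alignment
  if (length(labs) < 2) return(NULL)
  useNormals <- nrow(source@normals) > 0 && nrow(target@normals) > 0
  if (!useNormals && length(labs) < 3) return(NULL)
  h <- max(1, sqrt(sum((apply(source@points, 2, max) -
                        apply(source@points, 2, min))^2)) / 4)
  pseudo <- function(cl) {
    out <- NULL
    for (lb in labs) {
      i <- cl@labels == lb
      c_ <- colMeans(cl@points[i, , drop = FALSE])
      out <- rbind(out, c_)
      if (useNormals) {
        n_ <- colMeans(cl@normals[i, , drop = FALSE])
        n_ <- n_ / sqrt(sum(n_^2))
        out <- rbind(out, c_ + h * n_)
      }
    }
    out
  }
  ps <- pseudo(source)
  pt <- pseudo(target)
  tr <- tryCatch(kabsch(ps, pt), fidreg_error = function(e) NULL)
  if (!is.null(tr)) tr@metadata <- list(degenerate = FALSE, labeled = TRUE)
  tr
}

#' Iterative closest point alignment
#'
#' Classic point-to-point ICP: starting from `init`, alternates
#' nearest-neighbor correspondence (source moved by the current transform,
#' matched into the static target), optional trimming of the worst
#' correspondences, and a closed-form [kabsch()] update re-estimated from
#' the original source points, until the change in RMS correspondence
#' distance falls below the tolerance or the iteration cap is reached. With
#' `pointToPlane = TRUE`, the update instead solves the linearized
#' point-to-plane least-squares problem against the target normals.
#'
#' For untrimmed point-to-point ICP the recorded RMS trace is non-increasing
#' (the classical monotonic-convergence property).
#'
#' @param source a [PointCloud-class] or matrix: the moving cloud (>= 3
#'   points).
#' @param target the static cloud (>= 3 points); needs normals for the
#'   point-to-plane variant.
#' @param init initial [RigidTransform-class].
#' @param params an [IcpParams-class].
#' @return a [RegistrationResult-class]; its transform maps `source` into
#'   the `target` frame.
#' @export
icp <- function(source, target, init = identityTransform(),
                params = icpParams()) {
  validObject(params)
  S <- .asPointMatrix(source, "source")
  T_ <- .asPointMatrix(target, "target")
  if (nrow(S) < 3 || nrow(T_) < 3)
    .stopInvalid("ICP needs at least 3 points per cloud")
  if (params@pointToPlane) {
    if (!is(target, "PointCloud") || nrow(target@normals) == 0)
      .stopInvalid("point-to-plane ICP requires target normals")
    TN <- target@normals
  }
  tree <- .kd_build(T_)
  cur <- init
  trace <- numeric(0)
  converged <- FALSE
  nIter <- 0L
  for (k in seq_len(params@maxIterations + 1L)) {
    P <- applyTransform(S, cur)
    nn <- .kd_query(tree, P)
    # the monitored residual is the metric being minimized: point distance
    # for point-to-point, plane-projected distance for point-to-plane
    d <- if (params@pointToPlane) {
      abs(rowSums(TN[nn$index, , drop = FALSE] *
                  (P - T_[nn$index, , drop = FALSE])))
    } else nn$distance
    keep <- seq_along(d)
    if (params@trimFraction > 0) {
      nKeep <- max(3L, as.integer(ceiling((1 - params@trimFraction) *
                                          length(d))))
      keep <- order(d)[seq_len(nKeep)]
    }
    rms <- sqrt(mean(d[keep]^2))
    trace <- c(trace, rms)
    if (k > 1 && abs(trace[k - 1L] - rms) < params@convergenceTolMm) {
      converged <- TRUE
      break
    }
    if (k > params@maxIterations) break
    idx <- nn$index[keep]
    upd <- tryCatch({
      if (params@pointToPlane) {
        delta <- .pointToPlaneUpdate(P[keep, , drop = FALSE],
                                     T_[idx, , drop = FALSE],
                                     TN[idx, , drop = FALSE])
        composeTransforms(delta, cur)
      } else {
        kabsch(S[keep, , drop = FALSE], T_[idx, , drop = FALSE])
      }
    }, fidreg_degenerate_geometry = function(e) {
      .stopDegenerate(sprintf("%s (at ICP iteration %d)",
                              conditionMessage(e), k),
                      rank = e$rank, iteration = k)
    })
    cur <- upd
    nIter <- k
  }
  new("RegistrationResult", transform = cur, rmsTrace = trace,
      converged = converged, nIterations = nIter,
      metadata = list(params = params))
}

# linearized point-to-plane step: minimize sum((n . (p + w x p + t - q))^2).
# The normal equations are rank-deficient whenever the selected planes do
# not constrain all six DOFs (e.g. two ideal orthogonal faces leave the
# translation along their intersection free); the minimum-norm solution
# leaves such DOFs unchanged.
.pointToPlaneUpdate <- function(P, Q, N) {
  cxp <- cbind(P[, 2] * N[, 3] - P[, 3] * N[, 2],
               P[, 3] * N[, 1] - P[, 1] * N[, 3],
               P[, 1] * N[, 2] - P[, 2] * N[, 1])
  A <- cbind(cxp, N)
  b <- rowSums(N * (Q - P))
  dec <- svd(crossprod(A))
  keep <- dec$d > max(dec$d) * 1e-10
  if (!any(keep))
    .stopDegenerate("point-to-plane normal equations have rank 0", rank = 0L)
  x <- dec$v[, keep, drop = FALSE] %*%
    ((t(dec$u[, keep, drop = FALSE]) %*% crossprod(A, b)) / dec$d[keep])
  rigidTransform(.axisAngleToMatrix(x[1:3]), x[4:6])
}

#' Register two scans via selected block features
#'
#' The pipeline core: extracts the selected planar faces of the registration
#' block from both clouds, computes a rough alignment followed by ICP *on
#' the extracted features only*, and returns the resulting transform, which
#' is intended to be applied to the whole target model (transform
#' propagation). The target extract is the moving cloud; the returned
#' transform maps the target into the reference frame.
#'
#' @param reference,target labeled [PointCloud-class]s (block face labels
#'   present).
#' @param selection a [PlaneSelection-class].
#' @param params an [IcpParams-class].
#' @return a [RegistrationResult-class].
#' @export
registerViaFeatures <- function(reference, target,
                                selection = planeSelection(1:4),
                                params = icpParams()) {
  refExtract <- extractBlock(reference, selection)
  tgtExtract <- extractBlock(target, selection)
  init <- .roughAlignFeatures(tgtExtract, refExtract)
  if (is.null(init)) init <- roughAlign(tgtExtract, refExtract)
  res <- icp(tgtExtract, refExtract, init = init, params = params)
  res@metadata$selection <- selection
  res@metadata$roughDegenerate <- isTRUE(init@metadata$degenerate)
  res
}

#' Register two scans using the whole model
#'
#' Registers using *all* points (object plus block) rather than extracted
#' block features: the comparison condition in which the entire geometry
#' (~96% of the field of view) optimizes the mapping function.
#'
#' @param reference,target [PointCloud-class]s.
#' @param params an [IcpParams-class].
#' @return a [RegistrationResult-class].
#' @export
registerWholeModel <- function(reference, target, params = icpParams()) {
  init <- roughAlign(target, reference)
  res <- icp(target, reference, init = init, params = params)
  res@metadata$wholeModel <- TRUE
  res
}

#' @rdname applyTransform
#' @details `applyToModel()` is the transform-propagation step: it applies
#'   the block-derived transform to the whole target model (an alias of
#'   `applyTransform` with the argument order of the pipeline).
#' @export
applyToModel <- function(x, transform) applyTransform(x, transform)
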