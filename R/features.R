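#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a plane selection
#'
#' @param faces integer subset of `1:4` naming the selected block faces.
#'   Face 1 is the top (most parallel to the analyzed surface), face 2 the
#'   outward front, faces 3 and 4 the laterals.
#' @return a [PlaneSelection-class].
#' @export
planeSelection <- function(faces) {
  new("PlaneSelection", faces = as.integer(faces))
}

#' Construct an ROI specification
#'
#' @param label region label selecting the analyzed patch (default
#'   `"roi"`).
#' @param polygon optional k x 2 snipping polygon in the xy plane (mm);
#'   when given, it takes precedence over the label.
#' @param minPoints minimum admissible number of selected points.
#' @return a [RoiSpec-class].
#' @export
roiSpec <- function(label = "roi", polygon = NULL, minPoints = 100L) {
  if (is.null(polygon)) polygon <- matrix(numeric(), 0, 2)
  new("RoiSpec", label = label, polygon = polygon,
      minPoints = as.integer(minPoints))
}

#' Extract the selected block faces from a scan
#'
#' Returns the points of the cloud belonging to the selected planar faces of
#' the registration block. With a labeled cloud (the synthetic path) this is
#' a label filter. For unlabeled clouds a block specification plus its
#' placement pose can be supplied, and points within `toleranceMm` of the
#' selected ideal face planes (and within the face footprint) are taken.
#'
#' @param cloud a [PointCloud-class].
#' @param selection a [PlaneSelection-class].
#' @param block optional [BlockSpec-class] for the label-free path.
#' @param blockPose [RigidTransform-class] placing the cube (label-free
#'   path): the cube is centered at the origin of the pose frame.
#' @param toleranceMm point-to-plane capture tolerance for the label-free
#'   path; a practical choice is `3 * noiseSd + pointSpacing`.
#' @return the extracted [PointCloud-class].
#' @export
extractBlock <- function(cloud, selection, block = NULL,
                         blockPose = identityTransform(),
                         toleranceMm = NULL) {
  validObject(selection)
  if (length(cloud@labels)) {
    want <- paste0("block_face_", selection@faces)
    keep <- cloud@labels %in% want
    if (!any(keep))
      .stopEmptySelection(sprintf(
        "no points carry the selected face labels (%s)",
        paste(want, collapse = ", ")))
    return(subsetCloud(cloud, keep))
  }
  if (is.null(block) || is.null(toleranceMm))
    .stopInvalid(
      "unlabeled cloud: supply `block`, `blockPose` and `toleranceMm`")
  side <- blockSideMm(block)
  local <- applyTransform(cloud@points, invertTransform(blockPose))
  keep <- rep(FALSE, nrow(local))
  half <- side / 2
  for (f in selection@faces) {
    # face planes in the cube frame; see .makeCube for the convention
    ax <- switch(f, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 1L)
    sgn <- switch(f, `1` = 1, `2` = -1, `3` = 1, `4` = -1)
    onPlane <- abs(local[, ax] - sgn * half) <= toleranceMm
    others <- setdiff(1:3, ax)
    inFoot <- abs(local[, others[1]]) <= half + toleranceMm &
              abs(local[, others[2]]) <= half + toleranceMm
    keep <- keep | (onPlane & inFoot)
  }
  if (!any(keep))
    .stopEmptySelection(sprintf(
      "no points within %.3g mm of the selected face planes (%s)",
      toleranceMm, paste(selection@faces, collapse = ", ")))
  subsetCloud(cloud, keep)
}

#' Selected feature area
#'
#' Total area of the selected planar block faces: `|faces| * csaCm2`.
#'
#' @param selection a [PlaneSelection-class].
#' @param block a [BlockSpec-class].
#' @return area in cm2.
#' @export
selectedAreaCm2 <- function(selection, block) {
  validObject(selection)
  validObject(block)
  length(selection@faces) * block@csaCm2
}

#' Extract the analysis region of interest
#'
#' Applies the ROI specification (label filter or snipping polygon in the
#' xy plane) to a cloud. The same `RoiSpec` applied to reference and target
#' selects a consistent region; block points are never part of a label ROI.
#'
#' @param cloud a [PointCloud-class].
#' @param roi a [RoiSpec-class].
#' @return the ROI [PointCloud-class].
#' @export
extractRoi <- function(cloud, roi = roiSpec()) {
  validObject(roi)
  if (nrow(roi@polygon) > 0) {
    keep <- mgcv::in.out(rbind(roi@polygon, roi@polygon[1, ]),
                         cloud@points[, 1:2, drop = FALSE])
  } else {
    if (!length(cloud@labels))
      .stopInvalidRoi("cloud carries no labels; supply a snipping polygon")
    keep <- cloud@labels == roi@label
  }
  n <- sum(keep)
  if (n < roi@minPoints)
    .stopInvalidRoi(sprintf(
      "ROI selects %d points, fewer than the required %d", n, roi@minPoints))
  subsetCloud(cloud, keep)
}
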