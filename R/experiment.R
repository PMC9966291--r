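#' @include AllClasses.R AllGenerics.R
NULL

#' Feature size as a percentage of the scanner field of view
#'
#' `100 * selectedAreaCm2 / fovAreaCm2`: normalizing the selected feature
#' area to the scanner's field of view gives a scanner-independent way to
#' size a registration block (e.g. two faces of a 4 cm2 block in a 200 cm2
#' field of view are 4% FOV).
#'
#' @param selectedAreaCm2 selected feature area (cm2).
#' @param fovAreaCm2 scanner field of view (cm2).
#' @return percentage of the field of view.
#' @export
percentFov <- function(selectedAreaCm2, fovAreaCm2 = 200) {
  if (any(selectedAreaCm2 <= 0) || any(fovAreaCm2 <= 0))
    .stopInvalid("areas must be strictly positive")
  100 * selectedAreaCm2 / fovAreaCm2
}

# register one prepared pair for one selection and measure all error
# metrics; deviations are measured against the reference *surface* (the
# labeled submeshes), matching the mesh-based deviation of the scanning
# workflow rather than a cloud-to-cloud floor set by the sampling spacing
.measureCell <- function(reference, target, truth, selection, params, roi,
                         refRoiMesh, refBlockMesh) {
  refRoiPoints <- extractRoi(reference, roi)@points
  res <- registerViaFeatures(reference, target, selection, params)
  registered <- applyToModel(target, res@transform)
  roiStats <- surfaceVariation(extractRoi(registered, roi), refRoiMesh)
  markerStats <- surfaceVariation(
    extractBlock(registered, planeSelection(1:4)), refBlockMesh)
  treStats <- targetRegistrationError(res@transform, truth, refRoiPoints)
  list(roiMeanUm = roiStats@meanUm, markerMeanUm = markerStats@meanUm,
       treMeanUm = treStats@meanUm, converged = res@converged,
       nIterations = res@nIterations,
       roughDegenerate = isTRUE(res@metadata$roughDegenerate))
}

.emptyCell <- list(roiMeanUm = NA_real_, markerMeanUm = NA_real_,
                   treMeanUm = NA_real_, converged = NA,
                   nIterations = NA_integer_, roughDegenerate = NA)

#' Run the factorial registration experiment
#'
#' The full study design: for each block size, one reference scan is
#' generated and `nReplicates` independently perturbed target scans are
#' registered to it using each plane selection (nested configurations
#' `1`, `1-2`, `1-2-3`, `1-2-3-4`). The default design of 3 sizes x 4 plane
#' counts x 3 replicates yields 36 registered models. Every cell records
#' the mean ROI surface variation, the marker-surface (block self) error,
#' and the ground-truth target registration error; a failed cell is
#' recorded with its error message rather than dropped. Fully reproducible
#' from `masterSeed`.
#'
#' @param csaCm2 block sizes (cm2).
#' @param planeCounts numbers of selected planes (faces `seq_len(k)`).
#' @param nReplicates target replicates per size.
#' @param masterSeed integer master seed.
#' @param phantom base [PhantomSpec-class] (its block size is overridden).
#' @param scan a [ScanSpec-class].
#' @param params an [IcpParams-class].
#' @param roi a [RoiSpec-class].
#' @param identicalSampling reuse the reference sampling for every target
#'   (the zero-baseline condition of registering identical models) instead
#'   of independent resampling.
#' @return a long-format `data.frame`, one row per
#'   (size, plane count, replicate).
#' @export
runFactorial <- function(csaCm2 = c(4, 1, 0.25), planeCounts = 1:4,
                         nReplicates = 3L, masterSeed = 1L,
                         phantom = phantomSpec(), scan = scanSpec(),
                         params = icpParams(), roi = roiSpec(),
                         identicalSampling = FALSE) {
  rows <- list()
  for (si in seq_along(csaCm2)) {
    ph <- phantom
    ph@block <- blockSpec(csaCm2[si], pose = phantom@block@pose,
                          attachedFace = phantom@block@attachedFace)
    mesh <- makePhantom(ph)
    reference <- simulateScan(mesh, .reseed(scan, .subSeed(masterSeed, si,
                                                           100L)))
    refRoiMesh <- meshSubset(mesh, "roi")
    refBlockMesh <- meshSubset(mesh, paste0("block_face_", 1:4))
    for (r in seq_len(nReplicates)) {
      truth <- .withSeed(.subSeed(masterSeed, si * 1000L + r, 300L),
                         randomRigidTransform(scan@maxRotationDeg,
                                              scan@maxTranslationMm))
      tgtSeed <- if (identicalSampling) .subSeed(masterSeed, si, 100L)
                 else .subSeed(masterSeed, si * 1000L + r, 200L)
      targetRaw <- simulateScan(mesh, .reseed(scan, tgtSeed))
      target <- applyTransform(targetRaw, truth)
      for (k in planeCounts) {
        sel <- planeSelection(seq_len(k))
        cell <- tryCatch(
          c(.measureCell(reference, target, truth, sel, params, roi,
                         refRoiMesh, refBlockMesh),
            list(error = NA_character_)),
          error = function(e) c(.emptyCell,
                                list(error = conditionMessage(e))))
        rows[[length(rows) + 1L]] <- data.frame(
          csaCm2 = csaCm2[si], nPlanes = k,
          config = paste(seq_len(k), collapse = "-"), replicate = r,
          roiMeanUm = cell$roiMeanUm, markerMeanUm = cell$markerMeanUm,
          treMeanUm = cell$treMeanUm, converged = cell$converged,
          nIterations = cell$nIterations, error = cell$error,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Sweep planar configurations at one block size
#'
#' Registers replicated pairs using each requested face configuration (all
#' one-face selections and every two-face combination by default) and
#' summarizes the error per configuration, with a permutation test of the
#' hypothesis that the two-plane configurations perform equally.
#'
#' @param csaCm2 block size (cm2).
#' @param configurations list of integer face vectors.
#' @param nReplicates replicates per configuration.
#' @param masterSeed integer master seed.
#' @param phantom,scan,params,roi as in [runFactorial()].
#' @param nPerm permutations for the equality test.
#' @return list with `table` (per-replicate errors), `summary`
#'   (per-configuration mean/sd/median) and `equalityTwoPlane` (permutation
#'   p-value across the two-plane configurations).
#' @export
planarConfigurationSweep <- function(csaCm2 = 4,
                                     configurations = c(as.list(1:4),
                                       utils::combn(4, 2, simplify = FALSE)),
                                     nReplicates = 3L, masterSeed = 1L,
                                     phantom = phantomSpec(),
                                     scan = scanSpec(),
                                     params = icpParams(), roi = roiSpec(),
                                     nPerm = 10000L) {
  ph <- phantom
  ph@block <- blockSpec(csaCm2, pose = phantom@block@pose,
                        attachedFace = phantom@block@attachedFace)
  mesh <- makePhantom(ph)
  reference <- simulateScan(mesh, .reseed(scan, .subSeed(masterSeed, 1L,
                                                         100L)))
  refRoiMesh <- meshSubset(mesh, "roi")
  refBlockMesh <- meshSubset(mesh, paste0("block_face_", 1:4))
  rows <- list()
  for (r in seq_len(nReplicates)) {
    truth <- .withSeed(.subSeed(masterSeed, 1000L + r, 300L),
                       randomRigidTransform(scan@maxRotationDeg,
                                            scan@maxTranslationMm))
    targetRaw <- simulateScan(mesh, .reseed(scan, .subSeed(masterSeed,
                                                           1000L + r,
                                                           200L)))
    target <- applyTransform(targetRaw, truth)
    for (cf in configurations) {
      sel <- planeSelection(cf)
      cell <- tryCatch(
        c(.measureCell(reference, target, truth, sel, params, roi,
                       refRoiMesh, refBlockMesh),
          list(error = NA_character_)),
        error = function(e) c(.emptyCell, list(error = conditionMessage(e))))
      rows[[length(rows) + 1L]] <- data.frame(
        csaCm2 = csaCm2, config = paste(cf, collapse = "-"),
        nPlanes = length(cf), replicate = r, roiMeanUm = cell$roiMeanUm,
        markerMeanUm = cell$markerMeanUm, treMeanUm = cell$treMeanUm,
        converged = cell$converged, error = cell$error,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(tab, tab$config), function(d)
    data.frame(config = d$config[1], nPlanes = d$nPlanes[1],
               meanUm = mean(d$roiMeanUm), sdUm = stats::sd(d$roiMeanUm),
               medianUm = stats::median(d$roiMeanUm),
               stringsAsFactors = FALSE)))
  two <- tab[tab$nPlanes == 2, ]
  pEq <- if (nrow(two) && length(unique(two$config)) > 1) {
    m <- matrix(two$roiMeanUm[order(two$replicate, two$config)],
                nrow = length(unique(two$replicate)), byrow = TRUE)
    equalityPermutationTest(m, nPerm = nPerm,
                            seed = .subSeed(masterSeed, 7L, 9L))
  } else NA_real_
  list(table = tab, summary = agg[order(agg$nPlanes, agg$config), ],
       equalityTwoPlane = pEq)
}

#' Whole-model registration condition
#'
#' Registers a simulated pair using all points (object plus block) and
#' reports the ROI surface variation, for comparison against the
#' block-feature cells of the factorial design.
#'
#' @param pair result of [makePair()].
#' @param params an [IcpParams-class].
#' @param roi a [RoiSpec-class].
#' @return list with `stats` (a [DeviationStats-class]) and `result` (the
#'   [RegistrationResult-class]).
#' @export
wholeModelCondition <- function(pair, params = icpParams(),
                                roi = roiSpec()) {
  res <- registerWholeModel(pair$reference, pair$target, params)
  registered <- applyToModel(pair$target, res@transform)
  stats <- surfaceVariation(extractRoi(registered, roi),
                            meshSubset(pair$mesh, "roi"))
  list(stats = stats, result = res)
}

#' Summarize a factorial table
#'
#' Builds the per-cell mean +/- sd grid (rows: block size, descending;
#' columns: plane count 4, 3, 2, 1) from a [runFactorial()] table, plus the
#' derived quantities of [summarizeErrorGrid()].
#'
#' @param table a [runFactorial()] result.
#' @param value which error column to summarize.
#' @return list as in [summarizeErrorGrid()], with additional elements
#'   `grid` (cell means) and `sdGrid`.
#' @export
summarizeFactorial <- function(table, value = "roiMeanUm") {
  sizes <- sort(unique(table$csaCm2), decreasing = TRUE)
  planes <- sort(unique(table$nPlanes), decreasing = TRUE)
  cellStat <- function(f) outer(sizes, planes, Vectorize(function(s, k) {
    v <- table[[value]][table$csaCm2 == s & table$nPlanes == k]
    f(v[!is.na(v)])
  }))
  grid <- cellStat(mean)
  sdGrid <- cellStat(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  dimnames(grid) <- dimnames(sdGrid) <-
    list(size = as.character(sizes), planes = as.character(planes))
  out <- summarizeErrorGrid(grid)
  out$sdGrid <- sdGrid
  out
}

#' Arithmetic summary of a size x plane-count error grid
#'
#' Given a grid of per-cell mean errors (rows: block sizes, largest first;
#' columns: plane counts, most planes first), computes row averages (per
#' size), column averages (per plane count, the "all sizes" row), the grand
#' average, the ratios of each size's row average to the largest block's,
#' and the percentage excess of the one-plane column over each other
#' column.
#'
#' @param grid numeric matrix of cell mean errors (um).
#' @return list with `grid`, `rowAverages`, `colAverages`, `grandAverage`,
#'   `sizeRatios`, `onePlaneExcessPct`.
#' @export
summarizeErrorGrid <- function(grid) {
  if (!is.matrix(grid)) .stopInvalid("grid must be a matrix")
  rowAvg <- rowMeans(grid)
  colAvg <- colMeans(grid)
  oneCol <- ncol(grid)          # least-planes column is last
  excess <- 100 * (colAvg[oneCol] - colAvg[-oneCol]) / colAvg[-oneCol]
  list(grid = grid, rowAverages = rowAvg, colAverages = colAvg,
       grandAverage = mean(grid), sizeRatios = rowAvg / rowAvg[1],
       onePlaneExcessPct = excess)
}

#' Benchmark registration-error grid from a physical scanner study
#'
#' Mean (and sd) registration error in micrometres on the analyzed plateau
#' surface, measured with a structured-light scanner for cubic registration
#' blocks of 4, 1 and 0.25 cm2 cross-sectional area and 4/3/2/1 selected
#' planes (triplicate physical scans; 200 cm2 field of view). Included as
#' the worked-example input for [summarizeErrorGrid()]: these numbers
#' characterize a physical scanner's noise floor and are not a simulation
#' target.
#'
#' @return a 3 x 4 matrix of cell means (um), rows `large`/`medium`/`small`
#'   (4 / 1 / 0.25 cm2), columns plane counts `4`/`3`/`2`/`1`, with the
#'   cell standard deviations in attribute `"sd"`.
#' @export
referenceErrorGrid <- function() {
  m <- matrix(c(4.1, 4.6, 4.8, 9.8,
                68.9, 69.6, 71.7, 106.5,
                194.6, 191.1, 221.8, 346.7),
              nrow = 3, byrow = TRUE,
              dimnames = list(size = c("large", "medium", "small"),
                              planes = c("4", "3", "2", "1")))
  attr(m, "sd") <- matrix(c(1.5, 1.5, 0.9, 5.3,
                            57.3, 53.9, 60.0, 72.7,
                            66.9, 57.9, 62.0, 125.9),
                          nrow = 3, byrow = TRUE, dimnames = dimnames(m))
  m
}

#' Paired permutation test
#'
#' Two-sided sign-flip permutation test of the hypothesis that paired
#' samples `x` and `y` have equal means.
#'
#' @param x,y paired numeric vectors.
#' @param nPerm number of random sign assignments.
#' @param seed RNG seed.
#' @return the permutation p-value.
#' @export
pairedPermutationTest <- function(x, y, nPerm = 10000L, seed = 1L) {
  if (length(x) != length(y)) .stopInvalid("x and y must be paired")
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2) .stopInvalid("need at least 2 complete pairs")
  obs <- abs(mean(d))
  .withSeed(seed, {
    perm <- replicate(nPerm,
                      abs(mean(d * sample(c(-1, 1), length(d),
                                          replace = TRUE))))
    (1 + sum(perm >= obs)) / (nPerm + 1)
  })
}

#' Permutation test of equality across conditions
#'
#' Tests whether the column (condition) means of a replicate x condition
#' error matrix are equal, by permuting condition labels within each
#' replicate; the statistic is the variance of the condition means.
#'
#' @param m numeric matrix, rows = replicates, columns = conditions.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return the permutation p-value.
#' @export
equalityPermutationTest <- function(m, nPerm = 10000L, seed = 1L) {
  obs <- stats::var(colMeans(m))
  .withSeed(seed, {
    perm <- replicate(nPerm, {
      shuffled <- t(apply(m, 1, sample))
      stats::var(colMeans(shuffled))
    })
    (1 + sum(perm >= obs)) / (nPerm + 1)
  })
}

#' Error versus feature size in %FOV
#'
#' Scatter of per-cell mean registration error against the selected feature
#' area expressed as a percentage of the scanner field of view.
#'
#' @param table a [runFactorial()] result.
#' @param fovAreaCm2 scanner field of view (cm2).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a `data.frame` with `pctFov` and `meanUm` per cell.
#' @export
plotErrorVsFov <- function(table, fovAreaCm2 = 200, ...) {
  cells <- do.call(rbind, lapply(
    split(table, list(table$csaCm2, table$nPlanes), drop = TRUE),
    function(d) data.frame(
      csaCm2 = d$csaCm2[1], nPlanes = d$nPlanes[1],
      pctFov = percentFov(d$nPlanes[1] * d$csaCm2[1], fovAreaCm2),
      meanUm = mean(d$roiMeanUm, na.rm = TRUE))))
  graphics::plot(cells$pctFov, cells$meanUm, log = "y",
                 xlab = "selected feature area (% FOV)",
                 ylab = "mean registration error (um)",
                 pch = 19, ...)
  invisible(cells[order(cells$pctFov), ])
}
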