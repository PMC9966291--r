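---
title: "Fiducial-based registration of multi-temporal 3D surface scans"
author: "fidreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial-based registration of multi-temporal 3D surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidreg)
```

## The problem

Quantifying morphological change — mechanical wear of a joint surface,
degradation of a biomaterial — from 3D optical scans requires *registering*
the scans acquired at different time points into one frame. When the region
of interest itself changes between time points, the registration transform
must be computed from features that are guaranteed unaltered. A practical
solution is to glue a simple artificial fiducial (here, a cube) to the
object, compute the rigid transform by aligning only the fiducial between
the two scans, and then propagate that transform to the whole model. The
question this package studies is *how big the fiducial must be, and how
many of its planar faces must be selected*, for the whole-object
registration to be accurate.

`fidreg` implements the complete pipeline:

1. **Synthetic acquisition** (`makePhantom()`, `simulateScan()`,
   `makePair()`): a parametric phantom — an undulating elliptical plateau
   (the analyzed surface, labeled `"roi"`) on a tapered shaft, with a cube
   of configurable cross-sectional area (CSA) held anterior of the plateau —
   is sampled as a surface point cloud with Gaussian measurement noise,
   twice: a reference scan, and a target scan carrying a known random rigid
   perturbation (the ground truth).
2. **Feature selection** (`extractBlock()`, `extractRoi()`): the scan is
   restricted to the selected cube faces (1 = top, 2 = outward front,
   3–4 = laterals; the glued face and the bottom are never selectable), and
   the analysis region is snipped out by label or polygon.
3. **Registration** (`roughAlign()`, `icp()`, `registerViaFeatures()`):
   coarse alignment followed by iterative closest point on the extracted
   faces only; the resulting transform is applied to the whole target model
   (`applyToModel()`).
4. **Error quantification** (`surfaceVariation()`,
   `targetRegistrationError()`, `deviationMap()`): mean unsigned distance
   from the registered target's region of interest to the reference
   surface, in micrometres; in simulation additionally the true target
   registration error (TRE) against the known perturbation.
5. **The experiment** (`runFactorial()`, `planarConfigurationSweep()`,
   `wholeModelCondition()`, `percentFov()`): the factorial design over
   block sizes (4, 1, 0.25 cm²) and plane counts (1–4), the planar-
   configuration sweep, the whole-model comparison condition, and the
   normalization of feature area to the scanner's field of view (%FOV).

## The model and its numerical core

A rigid transform is $x \mapsto Rx + t$ with $R \in SO(3)$. The least-
squares update inside ICP is the weighted Kabsch/SVD superposition: given
paired points $(s_i, t_i)$ and weights $w_i$, the rotation minimizing
$\sum_i w_i \lVert R s_i + t - t_i \rVert^2$ is $R = V D U^\top$ where
$U \Sigma V^\top$ is the SVD of the weighted cross-covariance and
$D = \mathrm{diag}(1, 1, \det(VU^\top))$ — the determinant correction
guarantees a proper rotation, never a reflection. Collinear or coincident
correspondence sets make the rotation underdetermined; `kabsch()` detects
rank < 2 of the centered source and raises a classed degenerate-geometry
error naming the rank.

ICP alternates nearest-neighbor correspondence (KD-tree, ties broken by the
lowest reference index for cross-platform determinism), optional trimming
of the worst correspondences, and a full Kabsch re-fit from the original
source points. The recorded RMS correspondence distance is monotonically
non-increasing for the default untrimmed point-to-point variant (the
classical convergence argument); iteration stops when the RMS change drops
below `convergenceTolMm` (default 1e-7 mm) or after `maxIterations`
(default 100). A point-to-plane variant is available behind
`icpParams(pointToPlane = TRUE)`; its linearized normal equations are
solved by pseudo-inverse so that DOFs the selected planes do not constrain
receive no update, and — lacking a monotonicity guarantee — it may finish
in a small correspondence limit cycle rather than formally converging.

### Rough alignment and symmetric extracts

The study's workflow rough-aligns the extracted blocks manually before
ICP. `roughAlign()` emulates this deterministically: centroids are matched
and principal axes aligned, with axis signs taken from the third moment
(skewness) of the projections. Two cube-face subsets defeat a pure
skewness rule: the top+front pair has an exact 180° rotational symmetry
(and zero skewness along every principal axis), so sign choices would be
noise-driven and ICP could converge in the mirrored basin — a failure a
human operator never makes, because they can see which face is which.
Axes whose standardized skewness is below 0.2 are therefore treated as
ambiguous and every proper-rotation combination of their signs is scored
by nearest-neighbor cost on a deterministic subsample. For labeled
extracts, `registerViaFeatures()` goes one step further and initializes
from matched per-face centroids plus normal-offset pseudo-points
(closed-form Kabsch), which encodes exactly the operator's knowledge of
face identity. Isotropic clouds (relative eigenvalue gap < 1e-9) fall back
to centroid-only translation, flagged in the transform metadata.

### What a single plane cannot do

Point-to-point ICP on one plane leaves the three in-plane rigid DOFs
(two translations, one rotation about the normal) unconstrained: away from
the face boundary, sliding the plane over itself does not change the
objective. On a *bounded* face the boundary correspondences exert a weak
restoring force of order $d^2/2L$ per iteration for offset $d$ and face
side $L$ — enough to slowly erode a large offset over many iterations, but
with vanishing stiffness as $d \to 0$, so the equilibrium is wherever the
initialization put it. The degeneracy tests therefore demonstrate the pure
null space with the moving cloud cropped to the face interior (margin
larger than the injected offset), where an injected 3 mm in-plane offset
survives registration essentially unchanged while the out-of-plane
residual stays at the noise level. In the factorial study, single-plane
cells inherit an essentially arbitrary in-plane twist from the
principal-axis initialization (the in-plane eigenvalues of a square face
are degenerate), which is why their errors are orders of magnitude above
the multi-plane cells — the qualitative ordering, not the magnitude, is
the reproducible content.

## Error metrics

Registration error is the **mean unsigned surface variation**: the
distance from each registered target ROI point to the reference surface,
reported in µm (with sd, median, 95th percentile and max alongside).
Distances are unsigned point-to-mesh distances when the reference is a
surface, or nearest-point distances between clouds. The experiment driver
measures deviations against the phantom's labeled submeshes — the analog
of the scanning software's deviation against the reconstructed reference
model — because cloud-to-cloud nearest-point distances are floored at the
sampling spacing and would mask sub-spacing registration differences.
Registering two identical models perfectly yields zero surface variation,
so any deviation from zero is registration error; this zero baseline is
exercised end-to-end in the tests with identical-sampling, noise-free
pairs, where the pipeline recovers the perturbation to ~1e-11 µm.

In simulation the ground truth is known, so
`targetRegistrationError()` additionally reports the residual displacement
field $\lVert (\hat T \circ T_{\mathrm{truth}})x - x \rVert$ over the ROI —
the true registration error, uncontaminated by sampling or noise. Surface
variation under-reports tangential error on smooth surfaces (a slide along
the surface is nearly invisible to an unsigned distance); both metrics are
recorded in every factorial cell for this reason.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `fovAreaCm2` | 200 | cm² | scanner field of view; denominator of %FOV |
| `pointSpacingMm` | 0.12 | mm | sampling resolution (area density 1/spacing²) |
| `noiseSdMm` | 0.02 | mm | Gaussian measurement noise along the normal |
| `maxRotationDeg`, `maxTranslationMm` | 10, 10 | °, mm | target perturbation bounds (uniform over the ball) |
| block `csaCm2` | 4 / 1 / 0.25 | cm² | face cross-sectional area (sides 2 / 1 / 0.5 cm) |
| `standoffMm` | 10 | mm | block-to-plateau gap (free parameter; larger standoff amplifies angular error — the lever-arm property is tested) |
| `convergenceTolMm` | 1e-7 | mm | ICP stopping tolerance on RMS change |
| `trimFraction` | 0 | – | correspondence rejection (morphology is identical by construction; no outliers) |

The phantom replaces the bone replica with a parametric analog (elliptical
plateau 60 × 40 mm with ~2 mm low-frequency sinusoidal undulation, tapered
30 mm shaft). Only the methodological structure matters: an irregular
smooth analyzed surface, at a lever arm from a small planar fiducial,
inside the field of view. The noise level is a configuration knob — the
study never states a scanner noise figure — and all trend claims are
properties of orderings that hold across moderate noise levels, not of
absolute micrometre values.

## What the simulation does and does not emulate

Simulated: merged full-surface sampling at the scanner's area density,
isotropic Gaussian measurement noise along the local normal, per-region
labels (the operator's manual segmentation), independent reference/target
sampling, and a bounded random repositioning of the target. Not simulated:
structured-light physics (projector patterns, exposure, specularity),
per-view occlusion and the 12-view merge (the analysis starts at the
merged model), printing artifacts and surface microtexture, scanner
calibration drift. The last two are why absolute simulated errors are not
comparable to the physical study's micrometre values: real scans carry
both a systematic noise floor and surface texture that stabilizes
tangential DOFs. Reproduction targets are therefore orderings, ratios and
arithmetic summaries — never the printed cell values, which are bundled
(`referenceErrorGrid()`) purely as the worked-example input for
`summarizeErrorGrid()`.

## Problem sizes

The scans' default resolution (0.12 mm) yields ~700k points per scan;
the simulation studies in the tests and the acceptance script instead run
at 0.35 mm spacing (~75k points per scan, ~8k points per large-block
two-face extract), 20 replicates per condition, which keeps every study a
few minutes on one core. This is the package's chosen desk-scale study
size; the trend results sharpen, and the two-plane sliding penalty
shrinks, as spacing approaches the scanner's native resolution. The
factorial default (`nReplicates = 3`, mirroring the triplicate design with
one reference per size) is scaled to 20 replicates wherever medians and
orderings are asserted.

## Statistical choices

Repeated-measures ANOVA is deliberately out of scope; the questions asked
of the simulation are orderings and trends, for which the package provides
descriptive mean ± sd / median summaries, a paired sign-flip permutation
test (`pairedPermutationTest()`), an equality-of-conditions permutation
test across planar configurations (`equalityPermutationTest()`, variance
of condition means, labels permuted within replicates), and a Spearman
rank correlation with a permutation p-value for the spatial
error-propagation analysis (`spatialErrorTrend()`, 2000-point subsample,
999 permutations). All are seeded and assumption-light.

## Degenerate inputs and tie-breaking

* Nearest-neighbor ties: lowest reference index, deterministically.
* Kabsch with rank < 2 source geometry: classed error naming the rank;
  inside ICP the error additionally carries the iteration index.
* Fewer than 3 correspondences: invalid-input error.
* Reflections: never returned (determinant correction).
* Isotropic clouds in `roughAlign()`: centroid-only fallback, flagged.
* Empty face selections and under-populated ROIs (< 100 points): classed
  errors naming the request.
* Failed factorial cells are recorded with their condition message, never
  dropped.

## A worked example

```{r example, eval = FALSE}
ph <- phantomSpec(block = blockSpec(4))          # large block
pair <- makePair(ph, scanSpec(pointSpacingMm = 0.35, seed = 7L))
res <- registerViaFeatures(pair$reference, pair$target, planeSelection(1:2))
registered <- applyToModel(pair$target, res@transform)
surfaceVariation(extractRoi(registered), meshSubset(pair$mesh, "roi"))
targetRegistrationError(res@transform, pair$truth, extractRoi(pair$reference))

# the factorial study and its summary grid
tab <- runFactorial(nReplicates = 3L, masterSeed = 1L,
                    scan = scanSpec(pointSpacingMm = 0.35))
summarizeFactorial(tab)$grid
plotErrorVsFov(tab)
```

## Known limitations

* Absolute error magnitudes depend on the simulated noise and sampling
  density and do not reproduce a physical scanner's noise floor.
* Single-plane behavior is *more* degenerate than in the physical study,
  where surface texture and the operator's initialization constrain the
  in-plane DOFs; simulated one-plane errors are correspondingly extreme.
* The replicate variability of the physical study conflates scanner drift
  and ICP instability; the simulator exposes measurement noise as the only
  stochastic knob and cannot apportion the two.
* Automatic fiducial segmentation in unlabeled real scans (e.g. RANSAC
  plane finding) is out of scope; extraction uses labels or a known block
  pose plus tolerance.
* Non-rigid/affine registration, signed distances and volumetric wear are
  out of scope.
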