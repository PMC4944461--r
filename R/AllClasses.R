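#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' EpiSeries: a 4D functional MRI series
#'
#' Container for a preprocessed echo-planar imaging (EPI) time series:
#' a 4D intensity array indexed (x, y, z, t) together with the voxel
#' geometry, the repetition time and the voxel-to-world affine.
#'
#' Voxel indices are 0-based throughout the package API; the affine maps
#' homogeneous 0-based voxel coordinates to world millimetres.
#'
#' @slot data 4D numeric array, the fourth axis is time.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#' @slot tr numeric(1), repetition time in seconds (> 0).
#' @slot affine 4x4 voxel-to-world (mm) transform.
#' @slot space `"native"` or `"normalized"` (e.g. MNI).
#' @export
setClass("EpiSeries",
         representation(data = "array", voxelSize = "numeric",
                        tr = "numeric", affine = "matrix",
                        space = "character"))

setValidity("EpiSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, t)")
  else if (dim(object@data)[4L] < 2L)
    msg <- c(msg, "a series needs at least 2 volumes")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite values (mm)")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive value (seconds)")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (!object@space %in% c("native", "normalized"))
    msg <- c(msg, "space must be 'native' or 'normalized'")
  if (anyNA(object@data) || any(is.infinite(object@data)))
    msg <- c(msg, "intensities must be finite (no NA/NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' RoiBox: an axis-aligned region of interest
#'
#' Inclusive voxel-index bounds (0-based) of a box on an [EpiSeries] grid,
#' tagged with the eye it covers (or `"control"` for negative-control boxes).
#'
#' @slot eye `"left"`, `"right"` or `"control"`.
#' @slot bounds 2x3 matrix, rows `lo`/`hi`, columns x/y/z, inclusive 0-based.
#' @slot source `"default_mni"` or `"manual"`.
#' @export
setClass("RoiBox",
         representation(eye = "character", bounds = "matrix",
                        source = "character"))

setValidity("RoiBox", function(object) {
  msg <- character()
  if (!object@eye %in% c("left", "right", "control"))
    msg <- c(msg, "eye must be 'left', 'right' or 'control'")
  b <- object@bounds
  if (!identical(dim(b), c(2L, 3L)) || any(!is.finite(b)) ||
      any(b != round(b)))
    msg <- c(msg, "bounds must be a 2x3 matrix of integers")
  else {
    if (any(b[1L, ] > b[2L, ])) msg <- c(msg, "lo must be <= hi on every axis")
    if (any(b[1L, ] < 0)) msg <- c(msg, "bounds must be non-negative")
  }
  if (!object@source %in% c("default_mni", "manual"))
    msg <- c(msg, "source must be 'default_mni' or 'manual'")
  if (length(msg)) msg else TRUE
})

#' CmfProblem: data for a two-label continuous max-flow cut
#'
#' The fields of the convex min-cut energy
#' `E(u) = <1-u, Cs> + <u, Ct> + sum_x w(x) |grad u|(x)` over a 3D ROI:
#' the intensity subvolume, the source/sink capacity fields and the
#' non-negative regularization weight field.
#'
#' @slot image 3D intensity array (the ROI subvolume).
#' @slot cs source capacities `Cs(x) >= 0` (cost of labeling x background).
#' @slot ct sink capacities `Ct(x) >= 0` (cost of labeling x foreground).
#' @slot weight regularization field `w(x) >= 0`.
#' @export
setClass("CmfProblem",
         representation(image = "array", cs = "array", ct = "array",
                        weight = "array"))

setValidity("CmfProblem", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L) msg <- c(msg, "image must be a 3D array")
  for (nm in c("cs", "ct", "weight")) {
    f <- slot(object, nm)
    if (!identical(dim(f), d))
      msg <- c(msg, sprintf("%s must share the image grid", nm))
    else if (any(!is.finite(f)) || any(f < 0))
      msg <- c(msg, sprintf("%s must be non-negative and finite", nm))
  }
  if (length(msg)) msg else TRUE
})

#' BulbMask: a single-volume eye-bulb segmentation
#'
#' Binary mask of one eye bulb at one time point, on the ROI-local grid,
#' together with the relaxed continuous labeling it was thresholded from.
#'
#' @slot eye eye tag.
#' @slot t 0-based volume index.
#' @slot mask 3D logical array (`relaxed >= 0.5`).
#' @slot relaxed 3D labeling in `[0, 1]`, or NULL if not kept.
#' @slot voxelSize voxel size in mm.
#' @slot voxelCount number of foreground voxels.
#' @slot flagged TRUE when the mask is empty or fragmented (largest
#'   6-connected component < 90 % of foreground).
#' @export
setClass("BulbMask",
         representation(eye = "character", t = "integer", mask = "array",
                        relaxed = "arrayOrNULL", voxelSize = "numeric",
                        voxelCount = "integer", flagged = "logical"))

setValidity("BulbMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3D logical array")
  if (!is.null(object@relaxed) &&
      !identical(dim(object@relaxed), dim(object@mask)))
    msg <- c(msg, "relaxed labeling must share the mask grid")
  if (object@voxelCount != sum(object@mask))
    msg <- c(msg, "voxelCount must equal the number of mask voxels")
  if (length(msg)) msg else TRUE
})

#' BulbMaskSeries: per-volume bulb masks of one eye
#'
#' Stack of [BulbMask] results for one eye across a whole series, kept as a
#' 4D logical array on the ROI grid plus per-volume bookkeeping.
#'
#' @slot eye eye tag.
#' @slot mask 4D logical array (ROI x, y, z, t).
#' @slot roi the [RoiBox] the masks live in.
#' @slot voxelSize mm triple.
#' @slot tr seconds.
#' @slot voxelCount integer per-volume foreground counts.
#' @slot flagged logical per-volume quality flags.
#' @export
setClass("BulbMaskSeries",
         representation(eye = "character", mask = "array", roi = "RoiBox",
                        voxelSize = "numeric", tr = "numeric",
                        voxelCount = "integer", flagged = "logical"))

setValidity("BulbMaskSeries", function(object) {
  msg <- character()
  d <- dim(object@mask)
  if (length(d) != 4L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 4D logical array")
  else {
    if (length(object@flagged) != d[4L] ||
        length(object@voxelCount) != d[4L])
      msg <- c(msg, "flagged/voxelCount must have one entry per volume")
  }
  if (length(msg)) msg else TRUE
})

#' SurfaceMesh: triangulated isosurface of a bulb
#'
#' @slot vertices n x 3 matrix of vertex coordinates in mm (ROI-local frame).
#' @slot faces m x 3 integer matrix of vertex indices (1-based).
#' @slot level iso-level the surface was extracted at.
#' @export
setClass("SurfaceMesh",
         representation(vertices = "matrix", faces = "matrix",
                        level = "numeric"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L || any(!is.finite(object@vertices)))
    msg <- c(msg, "vertices must be a finite n x 3 matrix")
  if (nrow(object@vertices) < 4L)
    msg <- c(msg, "a closed surface needs at least 4 vertices")
  if (ncol(object@faces) != 3L)
    msg <- c(msg, "faces must be an m x 3 index matrix")
  else if (nrow(object@faces) > 0 &&
           (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' DiameterVector: the maximum-length chord of a bulb surface
#'
#' The vertex pair of a [SurfaceMesh] with maximal Euclidean distance, its
#' component vector, length and unit vector. The unit vector is
#' canonicalized to the `uy >= 0` hemisphere (ties: `uz >= 0`, then
#' `ux >= 0`) — the anterior direction — so that time series of the
#' orientation have no sign flips while the elevation component `uz`
#' stays signed.
#'
#' @slot p0,p1 endpoint coordinates in mm.
#' @slot u components `p1 - p0` (mm), canonicalized.
#' @slot length chord length in mm.
#' @slot unit unit vector `u / |u|`.
#' @slot eye eye tag (may be `NA`).
#' @slot t 0-based volume index (may be `NA`).
#' @export
setClass("DiameterVector",
         representation(p0 = "numeric", p1 = "numeric", u = "numeric",
                        length = "numeric", unit = "numeric",
                        eye = "character", t = "integer"))

setValidity("DiameterVector", function(object) {
  msg <- character()
  if (object@length <= 0) msg <- c(msg, "length must be > 0")
  if (abs(sqrt(sum(object@unit^2)) - 1) > 1e-9)
    msg <- c(msg, "unit vector must have norm 1")
  u <- object@unit
  canonical <- u[2L] > 1e-12 ||
    (abs(u[2L]) <= 1e-12 && (u[3L] > 1e-12 ||
                               (abs(u[3L]) <= 1e-12 && u[1L] >= -1e-12)))
  if (!canonical)
    msg <- c(msg, "unit vector must be canonicalized to the uy >= 0 hemisphere")
  if (length(msg)) msg else TRUE
})

#' IntensityTrace: mean in-bulb intensity over time
#'
#' @slot eye `"left"`, `"right"`, `"both"` or `"control"`.
#' @slot raw per-volume mean in-mask intensity (NA where flagged).
#' @slot filtered band-passed series (empty until filtering).
#' @slot rescaled normalized series in `[-1, 1]` (empty until rescaling).
#' @slot tr seconds.
#' @slot flagged per-volume flags inherited from the masks.
#' @export
setClass("IntensityTrace",
         representation(eye = "character", raw = "numeric",
                        filtered = "numeric", rescaled = "numeric",
                        tr = "numeric", flagged = "logical"))

setValidity("IntensityTrace", function(object) {
  msg <- character()
  n <- length(object@raw)
  if (length(object@flagged) != n)
    msg <- c(msg, "flagged must have one entry per volume")
  if (any(!is.finite(object@raw[!object@flagged])))
    msg <- c(msg, "raw must be finite at every unflagged volume")
  if (length(object@rescaled) &&
      (max(object@rescaled) > 1 + 1e-9 || min(object@rescaled) < -1 - 1e-9))
    msg <- c(msg, "rescaled values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' StateVector: binary per-volume eye-state labels
#'
#' @slot labels integer vector of 1 (closed) / 0 (open), one per volume.
#' @slot onsets optional transition times in seconds.
#' @slot source `"predetermined"` (ground truth/protocol) or `"predicted"`.
#' @export
setClass("StateVector",
         representation(labels = "integer", onsets = "numericOrNULL",
                        source = "character"))

setValidity("StateVector", function(object) {
  msg <- character()
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (open) or 1 (closed)")
  if (!object@source %in% c("predetermined", "predicted"))
    msg <- c(msg, "source must be 'predetermined' or 'predicted'")
  if (length(msg)) msg else TRUE
})

#' ClassifierThresholds: tail-quantile decision cuts
#'
#' Decision thresholds learned from the training fraction of a processed
#' feature trace: `lowCut` is the `tailFraction` quantile and `highCut` the
#' `1 - tailFraction` quantile of the training values.
#'
#' @slot feature which feature the cuts apply to.
#' @slot lowCut,highCut training tail boundaries (`lowCut <= highCut`).
#' @slot tailFraction tail mass used on each side (default 0.10).
#' @export
setClass("ClassifierThresholds",
         representation(feature = "character", lowCut = "numeric",
                        highCut = "numeric", tailFraction = "numeric"))

setValidity("ClassifierThresholds", function(object) {
  msg <- character()
  if (object@lowCut > object@highCut)
    msg <- c(msg, "lowCut must be <= highCut")
  if (object@tailFraction <= 0 || object@tailFraction >= 0.5)
    msg <- c(msg, "tailFraction must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: jackknife evaluation of predicted eye state
#'
#' @slot congruency percent of held-out volumes labeled correctly.
#' @slot correlations named list of Pearson correlations (features vs truth,
#'   left/right inter-eye, control ROIs).
#' @slot holdout 0-based indices of the held-out volumes.
#' @slot seed integer seed of the random split.
#' @slot details free-form list (thresholds, uncertain flags, settings).
#' @export
setClass("EvaluationReport",
         representation(congruency = "numeric", correlations = "list",
                        holdout = "integer", seed = "integer",
                        details = "list"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (length(object@congruency) &&
      (object@congruency < 0 || object@congruency > 100))
    msg <- c(msg, "congruency must lie in [0, 100]")
  r <- unlist(object@correlations, use.names = FALSE)
  r <- r[is.finite(r)]
  if (length(r) && any(abs(r) > 1 + 1e-9))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic eye phantom
#'
#' Describes a synthetic 4D EPI-like series containing two ovoid eye bulbs
#' whose elevation (Bell's phenomenon: upward rotation on lid closure) and
#' mean intensity (lower when open, because eye movement causes EPI signal
#' loss) follow a block-design state vector. Defaults reproduce the study
#' design: 600 volumes at TR 2.52 s, 27 s alternating blocks starting
#' closed, 3 mm isotropic voxels, bulb volume (4/3)*pi*abc ~= 7180 mm^3 and
#' a 28 deg closed-state elevation.
#'
#' @slot dim grid shape (voxels).
#' @slot voxelSize mm triple.
#' @slot tr seconds.
#' @slot nVolumes number of volumes.
#' @slot blockS block length in seconds.
#' @slot semiAxes bulb semi-axes (x, y, z) in mm; y is the major (optical)
#'   axis so that elevation tilts the maximum diameter.
#' @slot centerLeft,centerRight bulb centres in world mm.
#' @slot elevOpen,elevClosed bulb elevation (deg) in each state.
#' @slot intensityOpen,intensityClosed in-bulb intensity levels.
#' @slot background background intensity level.
#' @slot noiseSd additive Gaussian noise sd (per voxel).
#' @slot driftAmplitude,driftPeriod slow global sinusoidal drift (units, s).
#' @slot blinkProb probability that an eyes-open volume carries a
#'   single-volume blink artifact (intensity excursion to the closed level).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", voxelSize = "numeric", tr = "numeric",
                        nVolumes = "integer", blockS = "numeric",
                        semiAxes = "numeric", centerLeft = "numeric",
                        centerRight = "numeric", elevOpen = "numeric",
                        elevClosed = "numeric", intensityOpen = "numeric",
                        intensityClosed = "numeric", background = "numeric",
                        noiseSd = "numeric", driftAmplitude = "numeric",
                        driftPeriod = "numeric", blinkProb = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  ax <- sort(object@semiAxes, decreasing = TRUE)
  if (any(object@semiAxes <= 0))
    msg <- c(msg, "semi-axes must be positive")
  else if (ax[1L] < 1.05 * ax[2L])
    msg <- c(msg, "major semi-axis must exceed the next by >= 5 % so the maximum diameter is unique")
  if (object@noiseSd < 0) msg <- c(msg, "noise sd must be >= 0")
  if (any(c(object@intensityOpen, object@intensityClosed,
            object@background) < 0))
    msg <- c(msg, "intensity levels must be >= 0")
  if (object@blinkProb < 0 || object@blinkProb > 1)
    msg <- c(msg, "blinkProb must lie in [0, 1]")
  if (object@tr <= 0 || object@blockS < object@tr)
    msg <- c(msg, "block length must be >= tr and tr > 0")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth accompanying a phantom series
#'
#' @slot state the programmed [StateVector].
#' @slot elevation n x 2 matrix of true elevation (deg), columns left/right.
#' @slot trueLevel n x 2 matrix of true noise-free in-bulb intensity
#'   (state level + drift, blink excursions included).
#' @slot masks list `left`/`right`, each with `open`/`closed` 3D logical
#'   ground-truth masks on the full grid (geometry depends only on state).
#' @slot blink logical per-volume blink indicator.
#' @slot volumeMm3 named true bulb volumes (mm^3) per eye and state.
#' @export
setClass("PhantomTruth",
         representation(state = "StateVector", elevation = "matrix",
                        trueLevel = "matrix", masks = "list",
                        blink = "logical", volumeMm3 = "numeric"))

#' RunConfig: end-to-end pipeline settings
#'
#' @slot roi list of [RoiBox] or mm-bound specifications.
#' @slot lambda CMF regularization weight as a fraction of the ROI intensity
#'   range (see [buildCapacities]).
#' @slot tol,maxIter CMF solver controls.
#' @slot filterLow,filterHigh band-pass corners in Hz.
#' @slot filterOrder Butterworth prototype order.
#' @slot tailFraction,holdoutFraction classifier fractions in (0, 0.5).
#' @slot feature classification feature.
#' @slot smoothFwhm Gaussian smoothing FWHM in mm (0 = off).
#' @slot seed integer seed for the jackknife split.
#' @export
setClass("RunConfig",
         representation(roi = "list", lambda = "numeric", tol = "numeric",
                        maxIter = "integer", filterLow = "numeric",
                        filterHigh = "numeric", filterOrder = "integer",
                        tailFraction = "numeric", holdoutFraction = "numeric",
                        feature = "character", smoothFwhm = "numeric",
                        seed = "integer"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!(object@filterLow > 0 && object@filterLow < object@filterHigh))
    msg <- c(msg, "filter band must satisfy 0 < low < high (Hz)")
  for (nm in c("tailFraction", "holdoutFraction")) {
    v <- slot(object, nm)
    if (v <= 0 || v >= 0.5)
      msg <- c(msg, sprintf("%s must lie in (0, 0.5)", nm))
  }
  if (object@smoothFwhm < 0) msg <- c(msg, "smoothFwhm must be >= 0")
  if (!object@feature %in% c("mean_intensity", "vertical_angle",
                             "horizontal_angle", "uz", "combined"))
    msg <- c(msg, "unknown feature")
  if (length(msg)) msg else TRUE
})
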