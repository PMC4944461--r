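#' Construct an EpiSeries
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxelSize mm triple.
#' @param tr repetition time in seconds.
#' @param affine optional 4x4 voxel-to-world transform (0-based voxel
#'   indices); defaults to scaling by `voxelSize`.
#' @param space `"native"` or `"normalized"`.
#' @return an [EpiSeries-class] object.
#' @export
EpiSeries <- function(data, voxelSize, tr, affine = NULL, space = "native") {
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxelSize
  }
  new("EpiSeries", data = data, voxelSize = as.numeric(voxelSize),
      tr = as.numeric(tr), affine = affine, space = space)
}

#' Construct a RoiBox
#'
#' @param eye `"left"`, `"right"` or `"control"`.
#' @param bounds 2x3 matrix (rows lo/hi, columns x/y/z) or length-6 vector
#'   `(xlo, xhi, ylo, yhi, zlo, zhi)` of inclusive 0-based voxel indices.
#' @param source `"manual"` or `"default_mni"`.
#' @return a [RoiBox-class].
#' @export
roiBox <- function(eye, bounds, source = "manual") {
  b <- .as_bounds(bounds)
  new("RoiBox", eye = eye, bounds = b, source = source)
}

.as_bounds <- function(bounds) {
  if (is.matrix(bounds)) {
    stopifnot(identical(dim(bounds), c(2L, 3L)))
    b <- bounds
  } else {
    stopifnot(length(bounds) == 6L)
    b <- matrix(as.numeric(bounds), nrow = 2L)
  }
  storage.mode(b) <- "double"
  dimnames(b) <- list(c("lo", "hi"), c("x", "y", "z"))
  b
}

#' Construct a StateVector
#'
#' @param labels per-volume labels, 1 = eyes closed, 0 = eyes open.
#' @param onsets optional transition times in seconds.
#' @param source `"predetermined"` or `"predicted"`.
#' @return a [StateVector-class].
#' @export
stateVector <- function(labels, onsets = NULL, source = "predetermined") {
  new("StateVector", labels = as.integer(labels), onsets = onsets,
      source = source)
}

#' Load a 4D EPI series from a NIfTI-1 file
#'
#' Reads a (optionally gzipped) NIfTI-1 image, checks that it is a genuine
#' 4D series with finite intensities, and packages it as an [EpiSeries-class].
#' The space tag is `"normalized"` when the header's sform code marks MNI152
#' alignment, `"native"` otherwise.
#'
#' @param path path to the `.nii` / `.nii.gz` file.
#' @param tr optional repetition time (seconds) overriding the header; must
#'   be given when the header carries no usable TR. A > 1 % header/argument
#'   mismatch triggers a warning and the argument wins.
#' @param space optional override of the space tag.
#' @return an [EpiSeries-class].
#' @export
loadEpi <- function(path, tr = NULL, space = NULL) {
  img <- readNifti(path)
  nd <- length(img$dim)
  if (nd == 3L)
    stop("not a 4D series: ", path, " is a single 3D volume")
  if (nd != 4L) {
    extra <- img$dim[-(1:4)]
    if (all(extra == 1L)) {
      img$data <- array(img$data, dim = img$dim[1:4])
    } else stop("not a 4D series: ", path, " has ", nd, " non-trivial axes")
  }
  if (anyNA(img$data) || any(is.infinite(img$data)))
    stop("non-finite voxels in ", path)
  hdr_tr <- img$tr
  if (is.null(tr)) {
    if (!is.finite(hdr_tr) || hdr_tr <= 0)
      stop("no repetition time: header TR is absent/zero in ", path,
           " and none was supplied")
    tr <- hdr_tr
  } else if (is.finite(hdr_tr) && hdr_tr > 0 &&
             abs(hdr_tr - tr) > 0.01 * tr) {
    warning(sprintf("header TR (%.4g s) differs from supplied TR (%.4g s) by > 1 %%; using the supplied value",
                    hdr_tr, tr))
  }
  if (is.null(space))
    space <- if (img$sform_code == 4L) "normalized" else "native"
  EpiSeries(data = img$data, voxelSize = abs(img$pixdim), tr = tr,
            affine = img$affine, space = space)
}

#' Save an EpiSeries as NIfTI-1
#'
#' Written at float64 precision, so [loadEpi()] reproduces the data exactly.
#'
#' @param series an [EpiSeries-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
saveEpi <- function(series, path) {
  writeNifti(epiData(series), path, voxelSize = voxelSize(series),
             tr = repetitionTime(series), affine = epiAffine(series),
             sform_code = if (imageSpace(series) == "normalized") 4L else 1L)
}

#' The study's default MNI eye boxes
#'
#' Inclusive MNI millimetre bounds of the two eye regions, as used for
#' normalized images: right `[21, 51] x [47, 74] x [-50, -26]` and left
#' `[-48, -18] x [45, 74] x [-50, -26]`.
#'
#' @return named list of 2x3 lo/hi matrices (mm).
#' @export
defaultEyeBoundsMm <- function() {
  list(left  = .as_bounds(c(-48, -18, 45, 74, -50, -26)),
       right = .as_bounds(c(21, 51, 47, 74, -50, -26)))
}

#' Resolve an ROI specification to a voxel box
#'
#' Millimetre bounds (for normalized images) are mapped through the inverse
#' affine: all 8 corners are transformed, rounded to the nearest voxel, and
#' their bounding box is clipped to the grid — robust to affines with axis
#' flips. Voxel bounds pass through unchanged (making the operation
#' idempotent), after a range check against the grid.
#'
#' @param series an [EpiSeries-class].
#' @param spec 2x3 lo/hi matrix or length-6 vector of bounds.
#' @param eye `"left"`, `"right"` or `"control"`.
#' @param units `"mm"` (default) or `"voxel"`.
#' @return a [RoiBox-class] with 0-based inclusive voxel bounds.
#' @export
resolveRoi <- function(series, spec, eye, units = c("mm", "voxel")) {
  units <- match.arg(units)
  b <- .as_bounds(spec)
  grid <- dim(epiData(series))[1:3]
  if (units == "voxel") {
    if (any(b[1L, ] < 0) || any(b[2L, ] > grid - 1L))
      stop("empty ROI: voxel bounds fall outside the ",
           paste(grid, collapse = "x"), " grid")
    vb <- round(b)
    return(roiBox(eye, vb, source = "manual"))
  }
  if (imageSpace(series) != "normalized")
    stop("mm bounds supplied for a native-space series; resolve ROIs in voxel units or normalize first")
  A <- epiAffine(series)
  if (abs(det(A)) < 1e-12)
    stop("series affine is singular; cannot map mm bounds to voxels")
  corners <- as.matrix(expand.grid(b[, 1L], b[, 2L], b[, 3L]))
  vox <- t(solve(A) %*% rbind(t(corners), 1))[, 1:3, drop = FALSE]
  vox <- round(vox)
  lo <- pmax(apply(vox, 2L, min), 0)
  hi <- pmin(apply(vox, 2L, max), grid - 1L)
  if (any(lo > hi))
    stop("empty ROI: mm bounds map outside the image grid")
  roiBox(eye, rbind(lo, hi), source = "default_mni")
}

#' @rdname RoiBox-class
#' @param a,b two [RoiBox-class] objects.
#' @export
roiDisjoint <- function(a, b) {
  ba <- roiBounds(a); bb <- roiBounds(b)
  any(ba[2L, ] < bb[1L, ] | bb[2L, ] < ba[1L, ])
}

# ROI subvolume of one volume (0-based inclusive bounds -> R slice)
.roi_slice <- function(data, roi, t = NULL) {
  b <- roiBounds(roi)
  ix <- (b[1L, 1L]:b[2L, 1L]) + 1L
  iy <- (b[1L, 2L]:b[2L, 2L]) + 1L
  iz <- (b[1L, 3L]:b[2L, 3L]) + 1L
  if (is.null(t)) {
    data[ix, iy, iz, , drop = FALSE]
  } else {
    out <- data[ix, iy, iz, t + 1L, drop = FALSE]
    array(out, dim(out)[1:3])
  }
}

# symmetric (whole-sample) reflection of out-of-range 1-based indices
.reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx >= n, period - idx, idx)
  idx + 1L
}

#' Gaussian smoothing of an EPI series
#'
#' Convolves every volume with an isotropic Gaussian of the given full width
#' at half maximum, as is conventional in fMRI preprocessing (the study used
#' a 3 mm kernel on 3 mm voxels). Implemented as a separable convolution
#' with reflective boundary handling; the per-axis sigma in voxels is
#' `fwhm / (2 sqrt(2 log 2)) / voxelSize`. `fwhm = 0` returns the input
#' unchanged.
#'
#' @param series an [EpiSeries-class].
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @return a smoothed [EpiSeries-class].
#' @export
gaussianSmooth <- function(series, fwhm_mm) {
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm must be a single non-negative number (mm)")
  if (fwhm_mm == 0) return(series)
  a <- epiData(series)
  d <- dim(a)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxelSize(series)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    off <- (-r):r
    w <- exp(-off^2 / (2 * s^2))
    w <- w / sum(w)
    n <- d[axis]
    acc <- array(0, d)
    for (k in seq_along(off)) {
      idx <- .reflect_index(seq_len(n) + off[k], n)
      shifted <- switch(axis,
                        a[idx, , , , drop = FALSE],
                        a[, idx, , , drop = FALSE],
                        a[, , idx, , drop = FALSE])
      acc <- acc + w[k] * shifted
    }
    a <- acc
  }
  EpiSeries(a, voxelSize(series), repetitionTime(series),
            affine = epiAffine(series), space = imageSpace(series))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults follow the study:
#' 0.01-0.1 Hz band, 10 % tails, 10 % holdout, 3 mm smoothing, mean
#' intensity as the decision feature.
#'
#' @param roi list of [RoiBox-class] objects or mm-bound matrices
#'   (named `left`/`right`); empty means: use [defaultEyeBoundsMm()]
#'   (normalized series only).
#' @param lambda CMF regularization weight as a fraction of the ROI
#'   intensity range.
#' @param tol,maxIter CMF convergence controls.
#' @param filterLow,filterHigh band-pass corner frequencies in Hz.
#' @param filterOrder Butterworth prototype order.
#' @param tailFraction,holdoutFraction classifier fractions in (0, 0.5).
#' @param feature `"mean_intensity"` (default), `"vertical_angle"`,
#'   `"horizontal_angle"`, `"uz"` or `"combined"` (intensity + vertical
#'   angle majority, intensity breaking ties).
#' @param smoothFwhm Gaussian smoothing FWHM in mm (0 = off).
#' @param seed integer seed for the jackknife split.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(roi = list(), lambda = 0.1, tol = 1e-4, maxIter = 300L,
                      filterLow = 0.01, filterHigh = 0.1, filterOrder = 4L,
                      tailFraction = 0.10, holdoutFraction = 0.10,
                      feature = "mean_intensity", smoothFwhm = 3,
                      seed = 1L) {
  new("RunConfig", roi = roi, lambda = lambda, tol = tol,
      maxIter = as.integer(maxIter), filterLow = filterLow,
      filterHigh = filterHigh, filterOrder = as.integer(filterOrder),
      tailFraction = tailFraction, holdoutFraction = holdoutFraction,
      feature = feature, smoothFwhm = smoothFwhm, seed = as.integer(seed))
}

#' Read / write a pipeline configuration
#'
#' Plain-text JSON serialization of a [RunConfig-class]; ROI boxes are
#' stored as their lo/hi bounds with eye, source and units.
#'
#' @param path file path.
#' @param config a [RunConfig-class].
#' @return `readRunConfig` returns a [RunConfig-class]; `writeRunConfig`
#'   returns the path invisibly.
#' @export
writeRunConfig <- function(config, path) {
  roi <- lapply(config@roi, function(r) {
    if (is(r, "RoiBox"))
      list(eye = roiEye(r), units = "voxel", source = r@source,
           bounds = as.numeric(roiBounds(r)))
    else list(units = "mm", bounds = as.numeric(.as_bounds(r)))
  })
  x <- list(roi = roi, lambda = config@lambda, tol = config@tol,
            maxIter = config@maxIter, filterLow = config@filterLow,
            filterHigh = config@filterHigh, filterOrder = config@filterOrder,
            tailFraction = config@tailFraction,
            holdoutFraction = config@holdoutFraction,
            feature = config@feature, smoothFwhm = config@smoothFwhm,
            seed = config@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi <- list()
  if (length(x$roi)) {
    roi <- lapply(seq_along(x$roi), function(i) {
      r <- if (is.data.frame(x$roi)) as.list(x$roi[i, ]) else x$roi[[i]]
      b <- .as_bounds(unlist(r$bounds))
      if (identical(r$units, "voxel"))
        roiBox(r$eye, b, source = if (is.null(r$source)) "manual" else r$source)
      else b
    })
    names(roi) <- names(x$roi)
  }
  runConfig(roi = roi, lambda = x$lambda, tol = x$tol, maxIter = x$maxIter,
            filterLow = x$filterLow, filterHigh = x$filterHigh,
            filterOrder = x$filterOrder, tailFraction = x$tailFraction,
            holdoutFraction = x$holdoutFraction, feature = x$feature,
            smoothFwhm = x$smoothFwhm, seed = x$seed)
}
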