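#' @rdname EpiSeries-class
#' @param object,x an object.
#' @export
setGeneric("epiData", function(x) standardGeneric("epiData"))

#' @rdname EpiSeries-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname EpiSeries-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname EpiSeries-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname EpiSeries-class
#' @export
setGeneric("epiAffine", function(x) standardGeneric("epiAffine"))

#' @rdname EpiSeries-class
#' @export
setGeneric("imageSpace", function(x) standardGeneric("imageSpace"))

#' @rdname RoiBox-class
#' @export
setGeneric("roiBounds", function(x) standardGeneric("roiBounds"))

#' @rdname RoiBox-class
#' @export
setGeneric("roiEye", function(x) standardGeneric("roiEye"))

#' Per-volume quality flags
#' @param x an object carrying per-volume flags.
#' @export
setGeneric("flagged", function(x) standardGeneric("flagged"))

#' State labels as an integer vector
#' @param x a [StateVector] (or compatible object).
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

setMethod("epiData", "EpiSeries", function(x) x@data)
setMethod("voxelSize", "EpiSeries", function(x) x@voxelSize)
setMethod("repetitionTime", "EpiSeries", function(x) x@tr)
setMethod("nVolumes", "EpiSeries", function(x) dim(x@data)[4L])
setMethod("epiAffine", "EpiSeries", function(x) x@affine)
setMethod("imageSpace", "EpiSeries", function(x) x@space)

setMethod("voxelSize", "BulbMask", function(x) x@voxelSize)
setMethod("voxelSize", "BulbMaskSeries", function(x) x@voxelSize)
setMethod("nVolumes", "BulbMaskSeries", function(x) dim(x@mask)[4L])
setMethod("flagged", "BulbMaskSeries", function(x) x@flagged)
setMethod("flagged", "BulbMask", function(x) x@flagged)
setMethod("flagged", "IntensityTrace", function(x) x@flagged)

setMethod("roiBounds", "RoiBox", function(x) x@bounds)
setMethod("roiEye", "RoiBox", function(x) x@eye)

setMethod("stateLabels", "StateVector", function(x) x@labels)
setMethod("stateLabels", "numeric", function(x) as.integer(x))
setMethod("stateLabels", "integer", function(x) x)

setMethod("show", "EpiSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpiSeries: %d x %d x %d voxels, %d volumes\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  voxel size %s mm, TR %.3g s, space '%s'\n",
              paste(format(object@voxelSize), collapse = " x "),
              object@tr, object@space))
})

setMethod("show", "RoiBox", function(object) {
  b <- object@bounds
  cat(sprintf("RoiBox (%s, %s): [%d..%d] x [%d..%d] x [%d..%d] (0-based voxels)\n",
              object@eye, object@source,
              b[1L, 1L], b[2L, 1L], b[1L, 2L], b[2L, 2L], b[1L, 3L], b[2L, 3L]))
})

setMethod("show", "BulbMaskSeries", function(object) {
  cat(sprintf("BulbMaskSeries (%s eye): %d volumes, median %d voxels/mask, %d flagged\n",
              object@eye, nVolumes(object),
              as.integer(stats::median(object@voxelCount)),
              sum(object@flagged)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces (iso-level %.3g)\n",
              nrow(object@vertices), nrow(object@faces), object@level))
})

setMethod("show", "DiameterVector", function(object) {
  cat(sprintf("DiameterVector: length %.2f mm, unit (%.3f, %.3f, %.3f)\n",
              object@length, object@unit[1L], object@unit[2L], object@unit[3L]))
})

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace (%s): %d volumes%s%s, %d flagged\n",
              object@eye, length(object@raw),
              if (length(object@filtered)) ", filtered" else "",
              if (length(object@rescaled)) ", rescaled" else "",
              sum(object@flagged)))
})

setMethod("show", "StateVector", function(object) {
  cat(sprintf("StateVector (%s): %d volumes, %d closed / %d open\n",
              object@source, length(object@labels),
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

setMethod("show", "ClassifierThresholds", function(object) {
  cat(sprintf("ClassifierThresholds (%s): low %.4g, high %.4g (tails %.0f %%)\n",
              object@feature, object@lowCut, object@highCut,
              100 * object@tailFraction))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: congruency %.1f %% on %d held-out volumes (seed %d)\n",
              object@congruency, length(object@holdout), object@seed))
  if (length(object@correlations)) {
    r <- unlist(object@correlations)
    cat("  correlations:",
        paste(sprintf("%s=%.3f", names(r), r), collapse = ", "), "\n")
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid, %d volumes, TR %.3g s, %g s blocks\n",
              paste(object@dim, collapse = "x"), object@nVolumes,
              object@tr, object@blockS))
  cat(sprintf("  bulb semi-axes (%s) mm -> volume %.0f mm^3; elevation %g -> %g deg\n",
              paste(format(object@semiAxes), collapse = ", "),
              4 / 3 * pi * prod(object@semiAxes),
              object@elevOpen, object@elevClosed))
  cat(sprintf("  intensity open/closed %g/%g on background %g, noise sd %g\n",
              object@intensityOpen, object@intensityClosed,
              object@background, object@noiseSd))
})
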