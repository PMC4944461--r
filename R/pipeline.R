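# End-to-end run: ROI resolution, segmentation, feature extraction,
# filtering, threshold classification and evaluation.

#' EyeStateResult: everything one pipeline run produced
#'
#' @slot config the [RunConfig-class] used.
#' @slot rois resolved eye [RoiBox-class] objects.
#' @slot masks list of [BulbMaskSeries-class] (left, right).
#' @slot features orientation feature table ([vectorTimeseries()] rows for
#'   both eyes).
#' @slot traces list of processed [IntensityTrace-class] (left, right, both).
#' @slot featureSeries the processed series the classifier used.
#' @slot thresholds fitted [ClassifierThresholds-class].
#' @slot predicted full-run predicted [StateVector-class].
#' @slot uncertain logical mid-range flags per volume.
#' @slot split the train/test index list.
#' @slot report an [EvaluationReport-class], or NULL when no truth given.
#' @export
setClass("EyeStateResult",
         representation(config = "RunConfig", rois = "list", masks = "list",
                        features = "data.frame", traces = "list",
                        featureSeries = "numeric",
                        thresholds = "ClassifierThresholds",
                        predicted = "StateVector", uncertain = "logical",
                        split = "list", report = "ANY"))

setMethod("show", "EyeStateResult", function(object) {
  cat(sprintf("EyeStateResult: %d volumes, feature '%s'\n",
              length(object@predicted@labels), object@thresholds@feature))
  cat(sprintf("  predicted %d closed / %d open (%d uncertain)\n",
              sum(object@predicted@labels == 1L),
              sum(object@predicted@labels == 0L), sum(object@uncertain)))
  if (is(object@report, "EvaluationReport")) show(object@report)
})

.angle_feature <- function(features, eye_col, config) {
  # average the two eyes' series, then filter/rescale like an intensity trace
  agg <- stats::aggregate(features[[eye_col]],
                          by = list(t = features$t), FUN = mean)
  x <- agg$x[order(agg$t)]
  tr <- features$seconds[2L] - features$seconds[1L]
  rescaleTrace(bandpass(x, tr = tr, low = config@filterLow,
                        high = config@filterHigh, order = config@filterOrder))
}

.resolve_config_rois <- function(series, config) {
  roi <- config@roi
  if (!length(roi)) {
    if (imageSpace(series) != "normalized")
      stop("no ROI boxes configured; the default MNI boxes apply only to normalized series")
    mm <- defaultEyeBoundsMm()
    return(list(left = resolveRoi(series, mm$left, "left"),
                right = resolveRoi(series, mm$right, "right")))
  }
  nms <- names(roi)
  if (!all(c("left", "right") %in% nms))
    stop("config ROIs must be named 'left' and 'right'")
  lapply(stats::setNames(c("left", "right"), c("left", "right")), function(e) {
    r <- roi[[e]]
    if (is(r, "RoiBox")) r else resolveRoi(series, r, e)
  })
}

#' Run the full eye-state detection pipeline
#'
#' Optional Gaussian smoothing, per-volume continuous max-flow bulb
#' segmentation in both eye ROIs, maximum-diameter orientation features,
#' mean-intensity traces (left/right/both) band-passed and rescaled,
#' tail-quantile threshold fitting on a random training fraction and
#' labeling of every volume. When the true stimulus state is supplied, the
#' held-out volumes are scored (jackknife congruency) and feature/state,
#' inter-eye and control-ROI correlations are reported.
#'
#' @param series an [EpiSeries-class].
#' @param config a [RunConfig-class]; see [runConfig()].
#' @param truth optional [StateVector-class] (1 = closed, 0 = open).
#' @param controlBoxes optional list of control [RoiBox-class] objects.
#' @param verbose print progress.
#' @return an [EyeStateResult-class].
#' @export
runEyeState <- function(series, config = runConfig(), truth = NULL,
                        controlBoxes = list(), verbose = FALSE) {
  if (config@filterHigh >= 1 / (2 * repetitionTime(series)))
    stop(sprintf("filter band infeasible: high corner %.3g Hz >= Nyquist %.3g Hz",
                 config@filterHigh, 1 / (2 * repetitionTime(series))))
  work <- if (config@smoothFwhm > 0)
    gaussianSmooth(series, config@smoothFwhm) else series
  rois <- .resolve_config_rois(work, config)
  if (!roiDisjoint(rois$left, rois$right))
    stop("left and right eye ROIs overlap")

  if (verbose) message("segmenting eye bulbs ...")
  masks <- lapply(rois, function(r)
    segmentSeries(work, r, lambda = config@lambda, tol = config@tol,
                  maxIter = config@maxIter, verbose = verbose))
  features <- vectorTimeseries(masks, series = work, surface = "intensity")

  traces <- list(
    left = processTrace(meanIntensity(work, masks$left),
                        low = config@filterLow, high = config@filterHigh,
                        order = config@filterOrder),
    right = processTrace(meanIntensity(work, masks$right),
                         low = config@filterLow, high = config@filterHigh,
                         order = config@filterOrder),
    both = processTrace(meanIntensity(work, masks, eye = "both"),
                        low = config@filterLow, high = config@filterHigh,
                        order = config@filterOrder))

  vert <- .angle_feature(features, "vertical_rad", config)
  uz <- .angle_feature(features, "uz", config)
  intens <- traces$both@rescaled
  featureSeries <- switch(config@feature,
                          mean_intensity = intens,
                          combined = intens,
                          # closed eyes raise uz but lower the vertical angle;
                          # flip the angle so that high always means closed
                          vertical_angle = -vert,
                          horizontal_rad = ,
                          horizontal_angle =
                            .angle_feature(features, "horizontal_rad", config),
                          uz = uz)

  n <- nVolumes(series)
  split <- splitHoldout(n, config@holdoutFraction, config@seed)
  thr <- fitThresholds(featureSeries, split$train,
                       tailFraction = config@tailFraction,
                       feature = config@feature)
  pred <- predictStates(featureSeries, thr)
  uncertain <- attr(pred, "uncertain")
  if (config@feature == "combined") {
    thr2 <- fitThresholds(-vert, split$train,
                          tailFraction = config@tailFraction,
                          feature = "vertical_angle")
    pred2 <- predictStates(-vert, thr2)
    # majority of two rules with intensity breaking ties keeps the intensity
    # labels; the angle rule still narrows the uncertainty flags
    uncertain <- uncertain & attr(pred2, "uncertain")
  }

  report <- NULL
  if (!is.null(truth)) {
    y <- stateLabels(truth)
    corr <- list(
      intensity_both = stateCorrelation(intens, y),
      intensity_left = stateCorrelation(traces$left@rescaled, y),
      intensity_right = stateCorrelation(traces$right@rescaled, y),
      vertical_angle = stateCorrelation(vert, y),
      uz = stateCorrelation(uz, y),
      interEye_intensity = stats::cor(traces$left@rescaled,
                                      traces$right@rescaled),
      interEye_uz = stats::cor(features$uz[features$eye == "left"],
                               features$uz[features$eye == "right"]))
    if (length(controlBoxes))
      corr <- c(corr, as.list(controlRoiCheck(series, controlBoxes, y,
                                              eyeBoxes = rois,
                                              low = config@filterLow,
                                              high = config@filterHigh,
                                              order = config@filterOrder)))
    report <- new("EvaluationReport",
                  congruency = congruency(pred, y, test = split$test),
                  correlations = corr, holdout = as.integer(split$test),
                  seed = config@seed,
                  details = list(
                    thresholds = c(low = thr@lowCut, high = thr@highCut),
                    tailFraction = config@tailFraction,
                    holdoutFraction = config@holdoutFraction,
                    uncertain_holdout = sum(uncertain[split$test + 1L]),
                    congruency_all = congruency(pred, y)))
  }
  new("EyeStateResult", config = config, rois = rois, masks = masks,
      features = features, traces = traces, featureSeries = featureSeries,
      thresholds = thr, predicted = pred, uncertain = uncertain,
      split = split, report = report)
}

#' Evaluate predicted against known states
#'
#' @param predicted a [StateVector-class] or 0/1 vector (full run).
#' @param truth a [StateVector-class] or 0/1 vector.
#' @param test optional 0-based held-out indices; default scores all
#'   volumes.
#' @param seed seed recorded in the report.
#' @return an [EvaluationReport-class].
#' @export
evaluateStates <- function(predicted, truth, test = NULL, seed = 0L) {
  p <- stateLabels(predicted)
  y <- stateLabels(truth)
  if (is.null(test)) test <- seq_along(y) - 1L
  corr <- tryCatch(list(predicted = stateCorrelation(as.numeric(p), y)),
                   error = function(e) list())
  new("EvaluationReport", congruency = congruency(p, y, test = test),
      correlations = corr, holdout = as.integer(test),
      seed = as.integer(seed), details = list())
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEyeStateReport <- function(report, path) {
  x <- list(congruency_percent = report@congruency,
            correlations = report@correlations,
            holdout_indices = report@holdout, seed = report@seed,
            details = report@details)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-volume predictions as TSV
#'
#' Columns: t, seconds, feature value, predicted, truth (if given),
#' uncertain.
#'
#' @param result an [EyeStateResult-class].
#' @param path output path.
#' @param truth optional [StateVector-class].
#' @return the path, invisibly.
#' @export
writePredictions <- function(result, path, truth = NULL) {
  n <- length(result@featureSeries)
  tr <- result@traces$both@tr
  df <- data.frame(t = seq_len(n) - 1L, seconds = (seq_len(n) - 1L) * tr,
                   feature = result@featureSeries,
                   predicted = stateLabels(result@predicted),
                   uncertain = result@uncertain)
  if (!is.null(truth)) df$truth <- stateLabels(truth)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
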