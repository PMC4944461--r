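# Threshold classification of eye state with jackknife evaluation.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random train/holdout split of a run
#'
#' Selects `holdoutFraction` of the volume indices uniformly at random
#' without replacement (the study's 90/10 jackknife); reproducible under
#' the seed, which does not disturb the caller's RNG state.
#'
#' @param n number of volumes (>= 20).
#' @param holdoutFraction fraction held out, in (0, 0.5); default 0.10.
#' @param seed integer seed.
#' @return list with sorted 0-based `train` and `test` index vectors.
#' @export
splitHoldout <- function(n, holdoutFraction = 0.10, seed = 1L) {
  if (n < 20L) stop("n too small for a holdout split (need >= 20)")
  if (holdoutFraction <= 0 || holdoutFraction >= 0.5)
    stop("holdoutFraction must lie in (0, 0.5)")
  k <- round(n * holdoutFraction)
  test <- .with_seed(seed, sort(sample.int(n, k))) - 1L
  list(train = setdiff(seq_len(n) - 1L, test), test = test)
}

#' Fit tail-quantile decision thresholds
#'
#' The training distribution's `tailFraction` and `1 - tailFraction`
#' quantiles (linear interpolation between order statistics) become the
#' open/closed decision cuts: eyes closed raise both the mean bulb
#' intensity and the bulb elevation, so high values mean closed.
#'
#' @param trace processed (rescaled) feature series, full length.
#' @param train 0-based training indices.
#' @param tailFraction tail mass, default 0.10.
#' @param feature label stored on the result.
#' @return a [ClassifierThresholds-class].
#' @export
fitThresholds <- function(trace, train, tailFraction = 0.10,
                          feature = "mean_intensity") {
  vals <- trace[train + 1L]
  if (length(vals) < 10L) stop("need >= 10 training points")
  if (diff(range(vals)) <= 0) stop("constant training values")
  q <- stats::quantile(vals, c(tailFraction, 1 - tailFraction),
                       names = FALSE, type = 7)
  new("ClassifierThresholds", feature = feature, lowCut = q[1L],
      highCut = q[2L], tailFraction = tailFraction)
}

#' Predict eye state from a feature trace
#'
#' Values at or above the high cut are labeled closed (1), at or below the
#' low cut open (0); mid-range values are assigned to the nearer cut
#' (exact midpoint goes to closed) and flagged as uncertain, so every
#' volume receives a label. The rule is invariant under any strictly
#' increasing transform applied jointly to trace and cuts.
#'
#' @param trace processed feature series.
#' @param thresholds a [ClassifierThresholds-class].
#' @param test optional 0-based indices to label (default: all volumes).
#' @return a [StateVector-class] (`source = "predicted"`) of
#'   `length(test)` labels, with attribute `uncertain` (logical) marking
#'   mid-range assignments.
#' @export
predictStates <- function(trace, thresholds, test = NULL) {
  idx <- if (is.null(test)) seq_along(trace) else test + 1L
  v <- trace[idx]
  lo <- thresholds@lowCut
  hi <- thresholds@highCut
  lab <- integer(length(v))
  lab[v >= hi] <- 1L
  mid <- v > lo & v < hi
  lab[mid] <- as.integer((v[mid] - lo) >= (hi - v[mid]))
  out <- stateVector(lab, source = "predicted")
  attr(out, "uncertain") <- mid
  out
}

#' Percent agreement with the known eye state
#'
#' @param predicted,truth [StateVector-class] objects (or 0/1 vectors) of
#'   equal length over the evaluated volumes, or full-length vectors with
#'   `test` selecting the held-out subset of `truth`.
#' @param test optional 0-based indices into `truth` (used when `predicted`
#'   covers only the held-out volumes or the full run).
#' @return congruency in percent.
#' @export
congruency <- function(predicted, truth, test = NULL) {
  p <- stateLabels(predicted)
  y <- stateLabels(truth)
  if (!is.null(test)) {
    y <- y[test + 1L]
    if (length(p) != length(y)) p <- stateLabels(predicted)[test + 1L]
  }
  if (length(p) != length(y)) stop("predicted and truth lengths differ")
  if (!length(y)) stop("empty test set")
  100 * mean(p == y)
}

#' Pearson correlation between a feature series and the eye state
#'
#' @param feature numeric series.
#' @param truth a [StateVector-class] or 0/1 vector.
#' @return sample Pearson correlation coefficient.
#' @export
stateCorrelation <- function(feature, truth) {
  y <- as.numeric(stateLabels(truth))
  if (length(feature) != length(y)) stop("lengths differ")
  if (stats::sd(feature) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(feature, y)
}

#' Negative-control ROI check
#'
#' Processes the mean-intensity trace of each control box exactly like a
#' bulb trace (band-pass, rescale) and correlates it with the known state.
#' Regions without eye tissue should correlate weakly (the study reports
#' |r| < 0.2); a strong correlation indicates leakage or a systematic
#' artifact. Boxes overlapping an eye ROI are refused.
#'
#' @param series an [EpiSeries-class].
#' @param controlBoxes list of control [RoiBox-class] objects.
#' @param truth a [StateVector-class] or 0/1 vector.
#' @param eyeBoxes optional list of eye [RoiBox-class] objects for the
#'   overlap check.
#' @param low,high,order band-pass settings.
#' @return named numeric vector of correlations (NA where the control trace
#'   is constant, with a warning).
#' @export
controlRoiCheck <- function(series, controlBoxes, truth, eyeBoxes = NULL,
                            low = 0.01, high = 0.1, order = 4L) {
  if (is(controlBoxes, "RoiBox")) controlBoxes <- list(controlBoxes)
  out <- numeric(0)
  for (i in seq_along(controlBoxes)) {
    box <- controlBoxes[[i]]
    for (eb in eyeBoxes)
      if (!roiDisjoint(box, eb))
        stop("control ROI overlaps the ", roiEye(eb), " eye ROI")
    raw <- meanIntensity(series, box)
    r <- tryCatch({
      if (stats::sd(raw@raw, na.rm = TRUE) == 0)
        stop("constant input: correlation undefined")
      trace <- processTrace(raw, low = low, high = high, order = order)
      stateCorrelation(trace@rescaled, truth)
    },
                  error = function(e) {
                    warning("control ROI ", i, " non-informative: ",
                            conditionMessage(e))
                    NA_real_
                  })
    nm <- if (!is.null(names(controlBoxes)[i]) &&
              nzchar(names(controlBoxes)[i]))
      names(controlBoxes)[i] else paste0("control", i)
    out[nm] <- r
  }
  out
}
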