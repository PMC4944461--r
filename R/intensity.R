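# Mean in-bulb MR intensity over time, BOLD-band temporal filtering,
# rescaling and half-range categorization.
#
# The zero-phase band-pass is a Butterworth design (analog prototype ->
# band transform -> bilinear) applied forward and backward, implemented
# here because no signal-processing package is available in the target
# library set.

.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

.polyval <- function(p, x) {
  y <- 0 + 0i
  for (c1 in p) y <- y * x + c1
  y
}

#' Butterworth band-pass coefficients
#'
#' Digital band-pass of prototype order `order` (so `2 * order` poles) with
#' corner frequencies in Hz, via bilinear transform with frequency
#' prewarping; unit gain at the geometric center frequency.
#'
#' @param low,high corner frequencies (Hz), `0 < low < high < fs/2`.
#' @param fs sampling frequency (Hz), i.e. `1 / tr`.
#' @param order prototype (half) order; default 4.
#' @return list with numerator `b` and denominator `a` (decreasing powers
#'   of z).
#' @export
butterBandpass <- function(low, high, fs, order = 4L) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop(sprintf("band infeasible: need 0 < low < high < Nyquist = %.4g Hz",
                 fs / 2))
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # prototype poles
  pb <- c(vapply(p, function(pp) {
    disc <- sqrt((pp * bw / 2)^2 - w0^2)
    c(pp * bw / 2 + disc, pp * bw / 2 - disc)
  }, complex(2)))
  fs2 <- 2 * fs
  pz <- (fs2 + pb) / (fs2 - pb)
  zz <- c(rep(1 + 0i, order), rep(-1 + 0i, order))  # zeros at s = 0 and inf
  b <- Re(.poly_from_roots(zz))
  a <- Re(.poly_from_roots(pz))
  zc <- exp(1i * 2 * pi * sqrt(low * high) / fs)
  g <- Mod(.polyval(a, zc) / .polyval(b, zc))
  list(b = b * g, a = a)
}

.lfilter <- function(b, a, x, zi = NULL) {
  m <- max(length(a), length(b))
  b <- c(b, numeric(m - length(b))) / a[1L]
  a <- c(a, numeric(m - length(a))) / a[1L]
  z <- if (is.null(zi)) numeric(m - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (m > 2L)
      z[1:(m - 2L)] <- b[2:(m - 1L)] * x[i] + z[2:(m - 1L)] - a[2:(m - 1L)] * y[i]
    z[m - 1L] <- b[m] * x[i] - a[m] * y[i]
  }
  y
}

# steady-state initial filter state for a unit-amplitude input
.lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b))
  b <- c(b, numeric(m - length(b))) / a[1L]
  a <- c(a, numeric(m - length(a))) / a[1L]
  n <- m - 1L
  comp <- matrix(0, n, n)                    # companion matrix of a
  comp[1L, ] <- -a[2:m]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1L))] <- 1
  solve(diag(n) - t(comp), b[2:m] - a[2:m] * b[1L])
}

#' Zero-phase filtering
#'
#' Applies an IIR filter forward and backward (squared magnitude response,
#' zero phase) with odd-reflection padding of three filter lengths and
#' steady-state initial conditions, so run boundaries produce no transient.
#'
#' @param b,a filter coefficients, e.g. from [butterBandpass()].
#' @param x numeric series.
#' @return the filtered series.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, ext, zi = zi * ext[1L])
  y <- rev(y)
  y <- .lfilter(b, a, y, zi = zi * y[1L])
  y <- rev(y)
  y[(padlen + 1L):(padlen + n)]
}

#' Band-pass filter a trace in the BOLD band
#'
#' Zero-phase Butterworth band-pass, defaulting to the 0.01-0.1 Hz band the
#' study used to remove slow scanner drift and fast noise while keeping the
#' 27 s block alternation (54 s period, 0.0185 Hz). Missing values are
#' linearly interpolated before filtering.
#'
#' @param trace numeric series (raw mean intensities or angles).
#' @param tr repetition time in seconds.
#' @param low,high band corners in Hz.
#' @param order Butterworth prototype order.
#' @return the filtered series (zero mean by construction).
#' @export
bandpass <- function(trace, tr, low = 0.01, high = 0.1, order = 4L) {
  if (length(trace) < 16L)
    stop("series too short to filter (need >= 16 samples)")
  fs <- 1 / tr
  coef <- butterBandpass(low, high, fs, order)
  filtfilt(coef$b, coef$a, .interp_na(trace))
}

#' Rescale a filtered trace to [-1, 1]
#'
#' Mean-centers the series, then divides by the maximum absolute value, so
#' the extreme of larger magnitude maps to +/-1 and the mean is exactly 0.
#' (The fully symmetric normalization "0 = mean, +1 = max, -1 = min" is
#' over-constrained for asymmetric series; this realization satisfies all
#' three constraints whenever they are jointly satisfiable.)
#'
#' @param trace numeric series; must not be constant.
#' @return the rescaled series.
#' @export
rescaleTrace <- function(trace) {
  if (anyNA(trace)) trace <- .interp_na(trace)
  if (diff(range(trace)) <= 0) stop("constant input: cannot rescale")
  x <- trace - mean(trace)
  x / max(abs(x))
}

#' Half-range categorization
#'
#' Labels 1 (eyes closed) where the value lies strictly above
#' `min + (max - min) / 2`, else 0 — the study's discretization of the
#' intensity trace. Invariant under positive affine transforms of the
#' series; boundary values go to 0.
#'
#' @param trace numeric series; must not be constant.
#' @return integer vector of 0/1 labels.
#' @export
halfRangeCategorize <- function(trace) {
  if (anyNA(trace)) trace <- .interp_na(trace)
  rng <- range(trace)
  if (diff(rng) <= 0) stop("constant input: half-range undefined")
  as.integer(trace > rng[1L] + diff(rng) / 2)
}

#' Mean in-bulb intensity over time
#'
#' For each volume, the arithmetic mean of the series intensities at that
#' volume's own mask voxels (each image is segmented independently, so the
#' mask follows the bulb). `"both"` averages the left and right per-eye
#' means. A control [RoiBox-class] may be given instead of masks, in which
#' case the whole box is averaged. Volumes with an empty or flagged mask
#' yield NA and are flagged.
#'
#' @param series an [EpiSeries-class].
#' @param masks a [BulbMaskSeries-class], a list of two of them (for
#'   `eye = "both"`), or a [RoiBox-class].
#' @param eye trace tag; defaults to the tag of `masks`.
#' @return an [IntensityTrace-class] with the `raw` slot set.
#' @export
meanIntensity <- function(series, masks, eye = NULL) {
  tr <- repetitionTime(series)
  if (is(masks, "RoiBox")) {
    sub <- .roi_slice(epiData(series), masks)
    raw <- colMeans(matrix(sub, ncol = dim(sub)[4L]))
    return(new("IntensityTrace",
               eye = if (is.null(eye)) "control" else eye,
               raw = raw, filtered = numeric(), rescaled = numeric(),
               tr = tr, flagged = logical(length(raw))))
  }
  if (is.list(masks)) {
    traces <- lapply(masks, function(m) meanIntensity(series, m))
    raw <- rowMeans(do.call(cbind, lapply(traces, function(x) x@raw)))
    flg <- Reduce(`|`, lapply(traces, function(x) x@flagged))
    return(new("IntensityTrace", eye = if (is.null(eye)) "both" else eye,
               raw = raw, filtered = numeric(), rescaled = numeric(),
               tr = tr, flagged = flg))
  }
  stopifnot(is(masks, "BulbMaskSeries"))
  if (nVolumes(series) != nVolumes(masks))
    stop("masks are not aligned with the series volumes")
  sub <- .roi_slice(epiData(series), masks@roi)
  nt <- dim(sub)[4L]
  M <- matrix(sub, ncol = nt)
  W <- matrix(masks@mask, ncol = nt)
  cnt <- colSums(W)
  raw <- ifelse(cnt > 0, colSums(M * W) / pmax(cnt, 1L), NA_real_)
  flg <- masks@flagged | cnt == 0L
  raw[flg & cnt == 0L] <- NA_real_
  new("IntensityTrace", eye = if (is.null(eye)) masks@eye else eye,
      raw = raw, filtered = numeric(), rescaled = numeric(),
      tr = tr, flagged = flg)
}

#' Filter and rescale an intensity trace
#'
#' Fills the `filtered` (band-passed) and `rescaled` slots of an
#' [IntensityTrace-class]; flagged volumes are linearly interpolated before
#' filtering and stay flagged.
#'
#' @param trace an [IntensityTrace-class].
#' @param low,high band corners in Hz.
#' @param order Butterworth prototype order.
#' @return the completed [IntensityTrace-class].
#' @export
processTrace <- function(trace, low = 0.01, high = 0.1, order = 4L) {
  filt <- bandpass(trace@raw, trace@tr, low = low, high = high, order = order)
  trace@filtered <- filt
  trace@rescaled <- rescaleTrace(filt)
  trace
}

#' Write a trace table as TSV
#'
#' One row per volume: t, seconds, eye, raw, filtered, rescaled,
#' half_range_label, flagged.
#'
#' @param trace a processed [IntensityTrace-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTraceTable <- function(trace, path) {
  n <- length(trace@raw)
  df <- data.frame(t = seq_len(n) - 1L, seconds = (seq_len(n) - 1L) * trace@tr,
                   eye = trace@eye, raw = trace@raw,
                   filtered = if (length(trace@filtered)) trace@filtered else NA,
                   rescaled = if (length(trace@rescaled)) trace@rescaled else NA,
                   half_range_label = if (length(trace@rescaled))
                     halfRangeCategorize(trace@rescaled) else NA,
                   flagged = trace@flagged)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
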