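test_that("mean intensity reduces masks to their in-mask average", {
  ph <- small_phantom(nVolumes = 20L)
  rois <- defaultPhantomRois(ph$spec)
  bms <- truth_mask_series(ph, "left", rois$left)
  # constant series: the mean is the constant, whatever the mask
  const <- EpiSeries(array(100, c(dim(epiData(ph$series))[1:3], 20L)),
                     c(3, 3, 3), 2.52)
  tr_const <- meanIntensity(const, bms)
  expect_equal(tr_const@raw, rep(100, 20L))

  # phantom with closed-state intensity 1.1x the open state: the raw trace
  # alternates with the state vector (full-length design; the noise sd is
  # calibrated for a ~0.9 pre-filter correlation at 600 volumes)
  ph600 <- small_phantom(nVolumes = 600L)
  rois600 <- defaultPhantomRois(ph600$spec)
  bms600 <- list(truth_mask_series(ph600, "left", rois600$left),
                 truth_mask_series(ph600, "right", rois600$right))
  tr600 <- meanIntensity(ph600$series, bms600)
  expect_gt(stateCorrelation(tr600@raw, stateLabels(ph600$truth@state)), 0.9)

  tr <- meanIntensity(ph$series, bms)
  st <- stateLabels(ph$truth@state)

  # "both" averages the per-eye means
  bmsR <- truth_mask_series(ph, "right", rois$right)
  both <- meanIntensity(ph$series, list(bms, bmsR))
  expect_equal(both@raw, (tr@raw + meanIntensity(ph$series, bmsR)@raw) / 2)
  expect_identical(both@eye, "both")

  # an empty mask at one volume yields a flagged missing value
  bad <- bms
  bad@mask[, , , 3] <- FALSE
  bad@voxelCount[3] <- 0L
  tb <- meanIntensity(ph$series, bad)
  expect_true(tb@flagged[3])
  expect_true(is.na(tb@raw[3]))
})

test_that("disjoint masks on independent noise are uncorrelated", {
  set.seed(99)
  n <- 600L
  dat <- array(rnorm(8 * 4 * 4 * n), c(8, 4, 4, n))
  es <- EpiSeries(dat, c(3, 3, 3), 2.52)
  left <- meanIntensity(es, roiBox("control", c(0, 2, 0, 3, 0, 3)))
  right <- meanIntensity(es, roiBox("control", c(5, 7, 0, 3, 0, 3)))
  expect_lt(abs(stats::cor(left@raw, right@raw)), 0.2)
})

test_that("band-pass keeps the block frequency and removes DC", {
  tr <- 2.52
  n <- 600L
  t <- (seq_len(n) - 1) * tr
  expect_lt(max(abs(bandpass(rep(5, n), tr))), 1e-6 * 5)
  sine <- sin(2 * pi * t / 54)              # the 27 s half-block period
  out <- bandpass(sine, tr)
  expect_gte(max(abs(out[100:500])), 0.8)
  expect_lte(max(abs(out[100:500])), 1.05)
  # linearity
  x <- rnorm(n); y <- rnorm(n)
  expect_equal(bandpass(2 * x + 3 * y, tr),
               2 * bandpass(x, tr) + 3 * bandpass(y, tr), tolerance = 1e-9)
  # infeasible band for the sampling rate
  expect_error(bandpass(x, tr, low = 0.01, high = 0.3), "band infeasible")
  expect_error(bandpass(x[1:8], tr), "too short")
})

test_that("zero-phase filtering matches the analytic Butterworth response", {
  # |H(f)|^2 of the squared-magnitude (forward-backward) band-pass at the
  # analog frequencies, via the bilinear prewarped response
  tr <- 2.52; fs <- 1 / tr
  co <- butterBandpass(0.01, 0.1, fs, 4L)
  gain_at <- function(f) {
    z <- exp(2i * pi * f / fs)
    num <- sum(co$b * z^-(seq_along(co$b) - 1))
    den <- sum(co$a * z^-(seq_along(co$a) - 1))
    Mod(num / den)^2
  }
  n <- 2400L
  t <- (seq_len(n) - 1) * tr
  for (f in c(0.0185, 0.05, 0.12)) {
    out <- filtfilt(co$b, co$a, sin(2 * pi * f * t))
    expect_equal(max(abs(out[800:1600])), gain_at(f), tolerance = 0.02)
  }
})

test_that("rescaling pins the mean at zero and the larger extreme at 1", {
  expect_equal(rescaleTrace(c(-2, 0, 2)), c(-1, 0, 1))
  expect_equal(rescaleTrace(c(0, 1, 2)), c(-1, 0, 1))
  set.seed(4)
  for (rep in 1:10) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    r <- rescaleTrace(x)
    expect_lt(abs(mean(r)), 1e-9)
    expect_equal(max(abs(r)), 1, tolerance = 1e-12)
    expect_equal(rescaleTrace(r), r, tolerance = 1e-12)   # idempotent
  }
  expect_error(rescaleTrace(rep(3, 10)), "constant")
})

test_that("half-range categorization binarizes at the midpoint", {
  expect_identical(halfRangeCategorize(c(0, 10, 1, 9)), c(0L, 1L, 0L, 1L))
  expect_identical(halfRangeCategorize(c(0, 5, 10))[2], 0L)  # boundary -> open
  set.seed(8)
  x <- rnorm(100)
  lab <- halfRangeCategorize(x)
  expect_identical(halfRangeCategorize(3 * x + 7), lab)  # affine invariant
  expect_error(halfRangeCategorize(rep(1, 5)), "constant")
})

test_that("the processed phantom trace reproduces the state labels", {
  ph <- small_phantom(nVolumes = 600L)
  rois <- defaultPhantomRois(ph$spec)
  bms <- list(truth_mask_series(ph, "left", rois$left),
              truth_mask_series(ph, "right", rois$right))
  trc <- processTrace(meanIntensity(ph$series, bms))
  st <- stateLabels(ph$truth@state)
  expect_gt(mean(halfRangeCategorize(trc@rescaled) == st), 0.9)
  expect_gt(stateCorrelation(trc@rescaled, st), 0.9)
  expect_lte(max(trc@rescaled), 1 + 1e-9)
  expect_gte(min(trc@rescaled), -1 - 1e-9)
})
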