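test_that("the jackknife split is a reproducible partition", {
  sp <- splitHoldout(600L, 0.10, seed = 3L)
  expect_identical(length(sp$test), 60L)
  expect_identical(length(sp$train), 540L)
  expect_identical(sort(c(sp$train, sp$test)), 0:599)
  expect_identical(splitHoldout(600L, 0.10, seed = 3L), sp)
  expect_false(identical(splitHoldout(600L, 0.10, seed = 4L)$test, sp$test))
  expect_error(splitHoldout(10L), "too small")
  expect_error(splitHoldout(100L, 0.7), "holdoutFraction")
})

test_that("threshold fitting takes the training tail quantiles", {
  th <- fitThresholds(as.numeric(1:100), train = 0:99, tailFraction = 0.10)
  # linear interpolation between order statistics
  expect_equal(th@lowCut, 10.9)
  expect_equal(th@highCut, 90.1)
  # tails approaching one half collapse both cuts onto the median
  sym <- c(1:50, 51:100)
  th2 <- fitThresholds(as.numeric(sym), 0:99, tailFraction = 0.499)
  expect_equal(th2@lowCut, stats::median(sym), tolerance = 0.2)
  expect_equal(th2@highCut, stats::median(sym), tolerance = 0.2)
  expect_error(fitThresholds(rep(1, 100), 0:99), "constant")
  expect_error(fitThresholds(1:100, 0:5), ">= 10")
})

test_that("state prediction assigns tails and mid-range values", {
  th <- new("ClassifierThresholds", feature = "mean_intensity",
            lowCut = -0.5, highCut = 0.5, tailFraction = 0.1)
  p <- predictStates(c(0.9, -0.9, 0, 0.2, -0.2, 0.5, -0.5), th)
  expect_identical(stateLabels(p), c(1L, 0L, 1L, 1L, 0L, 1L, 0L))
  expect_identical(attr(p, "uncertain"),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # invariant under a strictly increasing transform of trace and cuts
  f <- function(x) exp(x)
  th2 <- new("ClassifierThresholds", feature = "mean_intensity",
             lowCut = f(-0.5), highCut = f(0.5), tailFraction = 0.1)
  x <- seq(-1, 1, length.out = 41)
  # exp is increasing but not midpoint-preserving; tails only
  tails <- abs(x) >= 0.5
  expect_identical(stateLabels(predictStates(f(x), th2))[tails],
                   stateLabels(predictStates(x, th))[tails])
})

test_that("congruency counts held-out agreement in percent", {
  x <- stateVector(rep(c(1, 0), 30))
  expect_equal(congruency(x, x), 100)
  inv <- stateVector(1L - stateLabels(x))
  expect_equal(congruency(inv, x), 0)
  pred <- stateLabels(x)
  pred[1:3] <- 1L - pred[1:3]
  expect_equal(congruency(stateVector(pred), x), 95)   # 57 of 60
  expect_error(congruency(x, x, test = integer()), "empty test set")
})

test_that("state correlation behaves like a Pearson coefficient", {
  y <- stateVector(rep(c(1, 0), each = 10))
  expect_equal(stateCorrelation(as.numeric(stateLabels(y)), y), 1)
  expect_equal(stateCorrelation(-as.numeric(stateLabels(y)), y), -1)
  expect_error(stateCorrelation(rep(1, 20), y), "constant")
  # independent noise at n = 600: |r| below 0.12 in at least 95 % of runs
  set.seed(31)
  truth <- stateVector(defaultBlockDesign(600L, 2.52)@labels)
  rs <- replicate(100, abs(stateCorrelation(rnorm(600), truth)))
  expect_gte(mean(rs < 0.12), 0.95)
})

test_that("control ROI checks refuse overlap and report degenerate traces", {
  ph <- small_phantom(nVolumes = 60L)
  rois <- defaultPhantomRois(ph$spec)
  st <- ph$truth@state
  r <- controlRoiCheck(ph$series, list(bg = rois$control), st,
                       eyeBoxes = rois[c("left", "right")])
  expect_lt(abs(r[["bg"]]), 0.2)
  expect_error(
    controlRoiCheck(ph$series, list(rois$left), st,
                    eyeBoxes = rois[c("left", "right")]),
    "overlaps")
  # constant region: non-informative, NA with a warning
  const <- EpiSeries(array(5, c(6, 6, 6, 60)), c(3, 3, 3), 2.52)
  expect_warning(
    rc <- controlRoiCheck(const, list(roiBox("control", c(0, 2, 0, 2, 0, 2))),
                          st),
    "non-informative")
  expect_true(is.na(rc[["control1"]]))
})

test_that("evaluation reports serialize to JSON", {
  truth <- stateVector(rep(c(1, 0), 30))
  pred <- stateLabels(truth)
  pred[5] <- 1L - pred[5]
  rep_ <- evaluateStates(pred, truth, seed = 2L)
  expect_equal(rep_@congruency, 100 * 59 / 60)
  f <- tempfile(fileext = ".json")
  writeEyeStateReport(rep_, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$congruency_percent, rep_@congruency)
  expect_identical(back$seed, 2L)
  unlink(f)
})
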