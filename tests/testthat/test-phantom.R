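test_that("the block design alternates on the acquisition clock", {
  st <- defaultBlockDesign(600L, 2.52, 27)
  lab <- stateLabels(st)
  expect_identical(lab[1], 1L)                      # starts closed
  runs <- rle(lab)$lengths
  expect_true(all(runs %in% c(10L, 11L)))           # 27 / 2.52 ~= 10.7
  expect_lt(abs(mean(lab) - 0.5), 11 / 600)         # balanced to one block
  # block length equal to TR strictly alternates
  expect_identical(stateLabels(defaultBlockDesign(6L, 2, 2)),
                   c(1L, 0L, 1L, 0L, 1L, 0L))
  expect_error(defaultBlockDesign(10L, 2.52, 1), "block length")
})

test_that("phantom truth matches its stated geometry", {
  ph <- small_phantom(nVolumes = 20L)
  tv <- ph$truth@volumeMm3
  expect_true(all(abs(tv - 7180) / 7180 < 0.03))    # adult eyeball volume
  expect_true(all(ph$truth@elevation[stateLabels(ph$truth@state) == 1L, ] == 28))
  expect_true(all(ph$truth@elevation[stateLabels(ph$truth@state) == 0L, ] == 0))
  # closed state is brighter by construction
  expect_gt(ph$spec@intensityClosed, ph$spec@intensityOpen)
  # left and right bulbs never overlap
  expect_false(any(ph$truth@masks$left$closed & ph$truth@masks$right$closed))
})

test_that("phantom generation is reproducible and honest about determinism", {
  a <- makePhantom(phantomSpec(nVolumes = 8L, seed = 5L))
  b <- makePhantom(phantomSpec(nVolumes = 8L, seed = 5L))
  expect_identical(epiData(a$series), epiData(b$series))
  c <- makePhantom(phantomSpec(nVolumes = 8L, seed = 6L))
  expect_false(identical(epiData(a$series), epiData(c$series)))

  # zero effect, zero noise, zero drift, zero blinks: all volumes identical
  quiet <- makePhantom(phantomSpec(nVolumes = 6L, noiseSd = 0,
                                   driftAmplitude = 0, blinkProb = 0,
                                   elevClosed = 0, intensityClosed = 800))
  d <- epiData(quiet$series)
  for (ti in 2:6) expect_identical(d[, , , ti], d[, , , 1])
})

test_that("phantom rejects impossible geometry", {
  expect_error(makePhantom(phantomSpec(dim = c(12L, 10L, 10L))),
               "do not fit")
  expect_error(phantomSpec(semiAxes = c(12, 12, 12)), "major semi-axis")
})

test_that("phantom truth files are plain TSV", {
  ph <- small_phantom(nVolumes = 20L)
  f <- tempfile(fileext = ".tsv")
  writePhantomTruth(ph$truth, f)
  df <- utils::read.delim(f)
  expect_identical(nrow(df), 20L)
  expect_identical(df$state, stateLabels(ph$truth@state))
  expect_true(all(c("elevation_left", "mean_intensity_right") %in% names(df)))
  unlink(f)
})

test_that("more noise cannot improve state recovery", {
  # congruency of the half-range labels from the true-mask intensity trace,
  # as a cheap proxy for the full pipeline, over three noise levels
  cong_at <- function(sd) {
    mean(vapply(1:3, function(s) {
      ph <- small_phantom(nVolumes = 120L, seed = 100L + s, noiseSd = sd)
      rois <- defaultPhantomRois(ph$spec)
      bms <- list(truth_mask_series(ph, "left", rois$left),
                  truth_mask_series(ph, "right", rois$right))
      trc <- processTrace(meanIntensity(ph$series, bms))
      st <- stateLabels(ph$truth@state)
      mean(halfRangeCategorize(trc@rescaled) == st)
    }, numeric(1)))
  }
  c0 <- cong_at(0)
  c1 <- cong_at(400)
  c2 <- cong_at(1500)
  expect_gte(c0 + 0.02, c1)
  expect_gte(c1 + 0.02, c2)
  expect_gt(c0, c2)
})
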