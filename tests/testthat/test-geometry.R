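closed_mesh <- function(mesh) {
  e <- rbind(mesh@faces[, 1:2], mesh@faces[, 2:3], mesh@faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

test_that("isosurface of a single voxel is a tight closed surface", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  s <- extractSurface(m, c(1, 1, 1))
  expect_gte(nrow(s@vertices), 4L)
  expect_true(all(sqrt(rowSums(sweep(s@vertices, 2, c(1, 1, 1))^2)) <= 0.5))
  expect_true(closed_mesh(s))
  expect_error(extractSurface(array(FALSE, c(3, 3, 3))), "no surface")
})

test_that("isosurface of a digitized sphere sits on the sphere", {
  d <- c(25, 25, 25)
  g <- expand.grid(x = 0:24, y = 0:24, z = 0:24)
  sph <- array(sqrt((g$x - 12)^2 + (g$y - 12)^2 + (g$z - 12)^2) <= 9, d)
  s <- extractSurface(sph, c(1, 1, 1))
  r <- sqrt(rowSums(sweep(s@vertices, 2, c(12, 12, 12))^2))
  expect_true(all(abs(r - 9) <= 1))          # within one voxel of the radius
  expect_true(closed_mesh(s))
})

test_that("isosurface commutes with mirroring", {
  set.seed(3)
  m <- array(runif(6 * 7 * 8) > 0.6, c(6, 7, 8))
  s1 <- extractSurface(m, c(1, 1, 1))
  s2 <- extractSurface(m[6:1, , ], c(1, 1, 1))
  v2 <- s2@vertices
  v2[, 1] <- 5 - v2[, 1]
  expect_identical(sort(apply(round(s1@vertices, 9), 1, paste, collapse = ",")),
                   sort(apply(round(v2, 9), 1, paste, collapse = ",")))
})

test_that("maximum diameter equals the brute-force all-pairs maximum", {
  v <- rbind(c(0, 0, 0), c(0, 0, 2))
  dv <- maxDiameter(v)
  expect_equal(dv@u, c(0, 0, 2))
  expect_equal(dv@length, 2)
  expect_equal(dv@unit, c(0, 0, 1))

  set.seed(17)
  for (rep in 1:8) {
    n <- sample(c(50, 200, 500), 1)
    V <- matrix(rnorm(3 * n), ncol = 3)
    dv <- maxDiameter(V)
    expect_equal(dv@length, max(stats::dist(V)), tolerance = 1e-12)
  }
})

test_that("diameter orientation and length match the analytic ellipsoid", {
  g <- expand.grid(x = 0:30, y = 0:30, z = 0:30)
  ell <- array(((g$x - 15) / 12)^2 + ((g$y - 15) / 10)^2 +
                 ((g$z - 15) / 9.5)^2 <= 1, c(31, 31, 31))
  dv <- maxDiameter(extractSurface(ell, c(1, 1, 1)))
  expect_lte(abs(dv@length - 24), 1)         # one voxel of the 24 mm axis
  # angle to the true major axis (x) within 5 degrees
  expect_lt(acos(abs(dv@unit[1])) * 180 / pi, 5)
})

test_that("diameter length is rotation invariant and the unit is canonical", {
  set.seed(23)
  V <- matrix(rnorm(300), ncol = 3)
  len <- maxDiameter(V)@length
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(maxDiameter(V %*% R)@length, len, tolerance = 1e-9)
  for (rep in 1:20) {
    u <- maxDiameter(matrix(rnorm(60), ncol = 3))@unit
    expect_true(u[2] > 1e-12 ||
                  (abs(u[2]) <= 1e-12 && (u[3] > 1e-12 ||
                                            (abs(u[3]) <= 1e-12 && u[1] >= 0))))
    expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-9)
  }
})

test_that("axis angles follow the direction cosines", {
  a <- axisAngles(new("DiameterVector", p0 = c(0, 0, 0), p1 = c(1, 0, 0),
                      u = c(1, 0, 0), length = 1, unit = c(1, 0, 0),
                      eye = "left", t = 0L))
  expect_equal(a[["horizontal"]], 0)
  expect_equal(a[["vertical"]], pi / 2)
  b <- axisAngles(c(0, 0, 1))
  expect_equal(b[["horizontal"]], pi / 2)
  expect_equal(b[["vertical"]], 0)
  set.seed(5)
  for (rep in 1:20) {
    u <- rnorm(3)
    ang <- axisAngles(u)
    expect_true(all(ang >= 0 & ang <= pi))
    expect_lte(cos(ang[["horizontal"]])^2 + cos(ang[["vertical"]])^2,
               1 + 1e-9)
  }
})

test_that("orientation time series track the phantom state", {
  ph <- small_phantom(nVolumes = 40L)
  rois <- defaultPhantomRois(ph$spec)
  sm <- gaussianSmooth(ph$series, 3)
  masks <- lapply(rois[c("left", "right")],
                  function(r) segmentSeries(sm, r))
  f <- vectorTimeseries(masks, series = sm, surface = "intensity")
  expect_identical(nrow(f), 80L)
  st <- stateLabels(ph$truth@state)
  for (eye in c("left", "right")) {
    uz <- f$uz[f$eye == eye]
    # uz alternates between two levels near the programmed elevations
    expect_lt(abs(mean(uz[st == 0]) - sin(0)), 0.15)
    expect_lt(abs(mean(uz[st == 1]) - sin(28 * pi / 180)), 0.15)
    expect_gt(stateCorrelation(uz, st), 0.5)
  }
  # static phantom (all volumes identical) gives a constant series
  const <- EpiSeries(epiData(sm)[, , , c(1, 1, 1)], voxelSize(sm),
                     repetitionTime(sm))
  mc <- segmentSeries(const, rois$left)
  fc <- vectorTimeseries(mc, series = const, surface = "intensity")
  expect_equal(fc$uz, rep(fc$uz[1], 3))
  expect_equal(fc$length_mm, rep(fc$length_mm[1], 3))
})

test_that("flagged volumes are interpolated and re-flagged", {
  ph <- small_phantom(nVolumes = 20L)
  rois <- defaultPhantomRois(ph$spec)
  bms <- segmentSeries(gaussianSmooth(ph$series, 3), rois$left)
  bms@flagged[5] <- TRUE
  f <- vectorTimeseries(bms)
  expect_true(f$flagged[5])
  expect_false(anyNA(f$uz))
  expect_equal(f$uz[5], (f$uz[4] + f$uz[6]) / 2, tolerance = 1e-9)
  bad <- bms
  bad@flagged[] <- TRUE
  expect_error(vectorTimeseries(bad), "all volumes flagged")
})

test_that("recovered elevation responds monotonically to programmed elevation", {
  elevs <- c(0, 14, 28, 40)
  rec <- vapply(elevs, function(e) {
    ph <- small_phantom(nVolumes = 24L, seed = 11L, elevClosed = e,
                        noiseSd = 100)
    rois <- defaultPhantomRois(ph$spec)
    sm <- gaussianSmooth(ph$series, 3)
    bms <- segmentSeries(sm, rois$left)
    f <- vectorTimeseries(bms, series = sm, surface = "intensity")
    st <- stateLabels(ph$truth@state)
    mean(f$uz[st == 1])
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})
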