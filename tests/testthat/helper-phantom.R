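# Shared phantom fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# small phantom for unit tests (default design, shorter run)
small_phantom <- function(nVolumes = 60L, seed = 7L, ...) {
  key <- paste0("small_", nVolumes, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixtures[[key]])) {
    spec <- phantomSpec(nVolumes = nVolumes, seed = seed, ...)
    .fixtures[[key]] <- c(makePhantom(spec), list(spec = spec))
  }
  .fixtures[[key]]
}

# ground-truth masks packaged as a BulbMaskSeries on an ROI grid, so
# intensity extraction can be tested independently of the segmenter
truth_mask_series <- function(ph, eye, roi) {
  n <- length(stateLabels(ph$truth@state))
  b <- roiBounds(roi)
  rd <- as.integer(b[2L, ] - b[1L, ] + 1L)
  m4 <- array(FALSE, c(rd, n))
  for (ti in seq_len(n)) {
    full <- trueMask(ph$truth, eye, ti - 1L)
    m4[, , , ti] <- full[(b[1L, 1L]:b[2L, 1L]) + 1L,
                         (b[1L, 2L]:b[2L, 2L]) + 1L,
                         (b[1L, 3L]:b[2L, 3L]) + 1L]
  }
  new("BulbMaskSeries", eye = roiEye(roi), mask = m4, roi = roi,
      voxelSize = voxelSize(ph$series), tr = repetitionTime(ph$series),
      voxelCount = as.integer(colSums(matrix(m4, ncol = n))),
      flagged = logical(n))
}

# the full default 600-volume phantom run (segmentation + features +
# traces), shared by the acceptance tests; ~1 min to build
full_phantom_run <- function() {
  if (is.null(.fixtures$full_run)) {
    ph <- makePhantom(phantomSpec())
    rois <- defaultPhantomRois(phantomSpec())
    cfg <- runConfig(roi = rois[c("left", "right")], seed = 1L)
    res <- runEyeState(ph$series, cfg, truth = ph$truth@state,
                       controlBoxes = list(control = rois$control))
    .fixtures$full_run <- list(ph = ph, rois = rois, cfg = cfg, res = res)
  }
  .fixtures$full_run
}
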