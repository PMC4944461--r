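# Synthetic 4D EPI phantom: two ovoid eye bulbs whose elevation and mean
# intensity follow a block-design state vector, with noise, slow drift and
# optional single-volume blink artifacts.

#' Construct a phantom specification
#'
#' Defaults encode the emulated study design: 600 volumes at TR 2.52 s,
#' 27 s alternating blocks starting with closed eyes, 3 mm isotropic voxels.
#' The bulbs are ellipsoids with semi-axes (10.5, 14, 11.66) mm — volume
#' (4/3) pi abc ~= 7180 mm^3, the adult eyeball mean, with the
#' anterior-posterior (y) axis as the unique major axis so the maximum
#' diameter tracks gaze elevation. Closure rotates each bulb 28 deg upward
#' (Bell's phenomenon) and raises the in-bulb intensity from 800 to 880
#' (eye movement with open lids causes EPI signal loss). The voxel noise sd
#' of 200 is calibrated so the pre-filter correlation between the true mean
#' intensity trace (~266 bulb voxels) and the state vector is ~0.9, the
#' regime of the study's group results; drift is a slow global sinusoid
#' well below the pass band. Blinks hit 2 % of eyes-open volumes: only a
#' blink overlapping the acquisition of the eye-containing slices perturbs
#' a volume, so most blinks leave no trace.
#'
#' @param dim grid shape in voxels.
#' @param voxelSize,tr,nVolumes,blockS acquisition geometry and design.
#' @param semiAxes,centerLeft,centerRight bulb geometry (mm).
#' @param elevOpen,elevClosed state elevations (deg).
#' @param intensityOpen,intensityClosed,background intensity levels.
#' @param noiseSd,driftAmplitude,driftPeriod,blinkProb noise model.
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(36L, 20L, 22L), voxelSize = c(3, 3, 3),
                        tr = 2.52, nVolumes = 600L, blockS = 27,
                        semiAxes = c(10.5, 14, 11.66),
                        centerLeft = c(24, 28.5, 31.5),
                        centerRight = c(81, 28.5, 31.5),
                        elevOpen = 0, elevClosed = 28,
                        intensityOpen = 800, intensityClosed = 880,
                        background = 200, noiseSd = 200,
                        driftAmplitude = 20, driftPeriod = 300,
                        blinkProb = 0.02, seed = 42L) {
  new("PhantomSpec", dim = as.integer(dim), voxelSize = voxelSize, tr = tr,
      nVolumes = as.integer(nVolumes), blockS = blockS, semiAxes = semiAxes,
      centerLeft = centerLeft, centerRight = centerRight,
      elevOpen = elevOpen, elevClosed = elevClosed,
      intensityOpen = intensityOpen, intensityClosed = intensityClosed,
      background = background, noiseSd = noiseSd,
      driftAmplitude = driftAmplitude, driftPeriod = driftPeriod,
      blinkProb = blinkProb, seed = as.integer(seed))
}

#' Block-design state vector
#'
#' Alternating eyes-closed / eyes-open labels, switching every `block_s`
#' seconds of acquisition time (so runs are 10 or 11 volumes long for the
#' study's 27 s blocks at TR 2.52 s), starting with closed eyes.
#'
#' @param nVolumes number of volumes.
#' @param tr repetition time (seconds).
#' @param block_s block length in seconds (>= tr).
#' @param startClosed start with the closed state (default TRUE).
#' @return a [StateVector-class] (`source = "predetermined"`).
#' @export
defaultBlockDesign <- function(nVolumes, tr, block_s = 27,
                               startClosed = TRUE) {
  if (block_s < tr) stop("block length must be >= tr")
  i <- seq_len(nVolumes) - 1L
  block <- floor(i * tr / block_s)
  lab <- as.integer(block %% 2 == 0)
  if (!startClosed) lab <- 1L - lab
  stateVector(lab, onsets = unique(block)[-1L] * block_s,
              source = "predetermined")
}

# voxels whose centre falls inside an ellipsoid rotated about the x-axis
.digitize_bulb <- function(dim, voxelSize, center, semiAxes, elev_deg) {
  .bulb_fill(dim, voxelSize, center, semiAxes, elev_deg, supersample = 1L) > 0.5
}

# fraction of each voxel inside the rotated ellipsoid, estimated by
# supersampling; supersample = 1 reduces to the centre-inside rule
.bulb_fill <- function(dim, voxelSize, center, semiAxes, elev_deg,
                       supersample = 4L) {
  th <- elev_deg * pi / 180
  ss <- supersample
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  acc <- array(0, dim)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    cx <- ((seq_len(dim[1L]) - 1L) + ox) * voxelSize[1L] - center[1L]
    cy <- ((seq_len(dim[2L]) - 1L) + oy) * voxelSize[2L] - center[2L]
    cz <- ((seq_len(dim[3L]) - 1L) + oz) * voxelSize[3L] - center[3L]
    X <- array(cx, dim)
    Y <- array(rep(cy, each = dim[1L]), dim)
    Z <- array(rep(cz, each = dim[1L] * dim[2L]), dim)
    Yb <- Y * cos(th) + Z * sin(th)      # inverse rotation into bulb frame
    Zb <- -Y * sin(th) + Z * cos(th)
    acc <- acc + ((X / semiAxes[1L])^2 + (Yb / semiAxes[2L])^2 +
                    (Zb / semiAxes[3L])^2 <= 1)
  }
  acc / ss^3
}

#' Generate a synthetic eye phantom
#'
#' Builds the 4D series described by a [PhantomSpec-class]: for each volume
#' both bulbs are ellipsoids rotated about the x-axis by the state's
#' elevation, rendered with partial-volume edges (each voxel interpolates
#' between background and the state's bulb level by the fraction of the
#' voxel inside the ellipsoid, as on real EPI where border voxels mix
#' vitreous and orbital signal); the ground-truth masks use the
#' centre-inside rule so they stay testable against the analytic ellipsoid
#' volume. Then
#' a global sinusoidal drift, i.i.d. Gaussian voxel noise, and — during
#' eyes-open volumes — occasional single-volume blink artifacts (the bulb
#' intensity of that volume alone jumps to the closed level while the
#' geometry stays open) are added. Fully reproducible under the spec seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `series` (an [EpiSeries-class]) and `truth`
#'   (a [PhantomTruth-class]).
#' @export
makePhantom <- function(spec) {
  d <- spec@dim
  vs <- spec@voxelSize
  half <- spec@semiAxes + 2 * vs             # rotated extent upper bound
  for (ctr in list(spec@centerLeft, spec@centerRight)) {
    if (any(ctr - half < 0) || any(ctr + half > (d - 1L) * vs))
      stop("bulbs do not fit inside the grid with a 2-voxel margin")
  }
  masks <- list()
  fills <- list()
  for (eye in c("left", "right")) {
    ctr <- if (eye == "left") spec@centerLeft else spec@centerRight
    fills[[eye]] <- list(
      open = .bulb_fill(d, vs, ctr, spec@semiAxes, spec@elevOpen),
      closed = .bulb_fill(d, vs, ctr, spec@semiAxes, spec@elevClosed))
    # ground-truth masks use the centre-inside rule (testable against the
    # analytic ellipsoid volume)
    masks[[eye]] <- list(
      open = .digitize_bulb(d, vs, ctr, spec@semiAxes, spec@elevOpen),
      closed = .digitize_bulb(d, vs, ctr, spec@semiAxes, spec@elevClosed))
  }
  if (any(masks$left$open & masks$right$open) ||
      any(masks$left$closed & masks$right$closed))
    stop("bulbs overlap")

  nt <- spec@nVolumes
  state <- defaultBlockDesign(nt, spec@tr, spec@blockS)
  lab <- stateLabels(state)

  .with_seed(spec@seed, {
    blink <- stats::runif(nt) < spec@blinkProb & lab == 0L
    tsec <- (seq_len(nt) - 1L) * spec@tr
    drift <- spec@driftAmplitude * sin(2 * pi * tsec / spec@driftPeriod)
    level <- ifelse(lab == 1L | blink, spec@intensityClosed,
                    spec@intensityOpen) + drift
    elev <- ifelse(lab == 1L, spec@elevClosed, spec@elevOpen)

    data <- array(0, c(d, nt))
    for (ti in seq_len(nt)) {
      st <- if (lab[ti] == 1L) "closed" else "open"
      # partial-volume rendering: boundary voxels take intermediate values,
      # emulating the partial-volume edge of the real vitreous on EPI
      frac <- fills$left[[st]] + fills$right[[st]]
      data[, , , ti] <- spec@background + drift[ti] +
        frac * (level[ti] - spec@background - drift[ti])
    }
    if (spec@noiseSd > 0)
      data <- data + array(stats::rnorm(length(data), sd = spec@noiseSd),
                           dim(data))
  })

  series <- EpiSeries(data, voxelSize = vs, tr = spec@tr, space = "native")
  vox_mm3 <- prod(vs)
  truth <- new("PhantomTruth", state = state,
               elevation = cbind(left = elev, right = elev),
               trueLevel = cbind(left = level, right = level),
               masks = masks, blink = blink,
               volumeMm3 = c(left_open = sum(masks$left$open) * vox_mm3,
                             left_closed = sum(masks$left$closed) * vox_mm3,
                             right_open = sum(masks$right$open) * vox_mm3,
                             right_closed = sum(masks$right$closed) * vox_mm3))
  list(series = series, truth = truth)
}

#' Default ROI boxes for the phantom grid
#'
#' Eye boxes of +/- 5 voxels around each bulb centre and a control box of
#' comparable size in the bulb-free region between the eyes.
#'
#' @param spec a [PhantomSpec-class].
#' @return named list of [RoiBox-class]: left, right, control.
#' @export
defaultPhantomRois <- function(spec = phantomSpec()) {
  cl <- round(spec@centerLeft / spec@voxelSize)
  cr <- round(spec@centerRight / spec@voxelSize)
  box <- function(ctr, eye, r = 5L)
    roiBox(eye, rbind(ctr - r, ctr + r))
  ctrl_lo <- c(cl[1L] + 6L, cl[2L] - 6L, cl[3L] - 6L)
  ctrl_hi <- c(cr[1L] - 6L, cl[2L] + 5L, cl[3L] + 5L)
  list(left = box(cl, "left"), right = box(cr, "right"),
       control = roiBox("control", rbind(ctrl_lo, ctrl_hi)))
}

#' Ground-truth mask of one eye at one volume
#'
#' @param truth a [PhantomTruth-class].
#' @param eye `"left"` or `"right"`.
#' @param t 0-based volume index.
#' @return 3D logical array on the full phantom grid.
#' @export
trueMask <- function(truth, eye, t) {
  st <- if (stateLabels(truth@state)[t + 1L] == 1L) "closed" else "open"
  truth@masks[[eye]][[st]]
}

#' Write phantom ground truth as TSV
#'
#' Columns: t, state, blink, elevation_left, elevation_right,
#' mean_intensity_left, mean_intensity_right.
#'
#' @param truth a [PhantomTruth-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePhantomTruth <- function(truth, path) {
  n <- length(stateLabels(truth@state))
  df <- data.frame(t = seq_len(n) - 1L, state = stateLabels(truth@state),
                   blink = as.integer(truth@blink),
                   elevation_left = truth@elevation[, "left"],
                   elevation_right = truth@elevation[, "right"],
                   mean_intensity_left = truth@trueLevel[, "left"],
                   mean_intensity_right = truth@trueLevel[, "right"])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
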