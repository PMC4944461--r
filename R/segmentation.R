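# Eye-bulb segmentation: two-label continuous max-flow (convex min-cut)
# inside each ROI, per volume, plus volumetry.

# forward difference along one axis, reflective (Neumann) boundary:
# last slice difference is 0
.fwd_diff <- function(u, axis) {
  d <- dim(u)
  n <- d[axis]
  g <- array(0, d)
  if (n == 1L) return(g)
  hd <- seq_len(n - 1L)
  tl <- hd + 1L
  switch(axis,
         g[hd, , ] <- u[tl, , ] - u[hd, , ],
         g[, hd, ] <- u[, tl, ] - u[, hd, ],
         g[, , hd] <- u[, , tl] - u[, , hd])
  g
}

# divergence = -adjoint of .fwd_diff
.divergence <- function(qx, qy, qz) {
  d <- dim(qx)
  dv <- qx + qy + qz
  if (d[1L] > 1L) dv[2:d[1L], , ] <- dv[2:d[1L], , ] - qx[1:(d[1L] - 1L), , ]
  if (d[2L] > 1L) dv[, 2:d[2L], ] <- dv[, 2:d[2L], ] - qy[, 1:(d[2L] - 1L), ]
  if (d[3L] > 1L) dv[, , 2:d[3L]] <- dv[, , 2:d[3L]] - qz[, , 1:(d[3L] - 1L)]
  dv
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a 256-bin histogram spanning the
#' data range. The split is equivariant under positive affine intensity
#' rescaling (bins are placed relative to the range).
#'
#' @param x numeric vector or array of intensities.
#' @param nbins histogram resolution.
#' @return the threshold value (upper class is strictly above it).
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) <= 0) stop("constant input: no intensity split exists")
  h <- tabulate(pmin(pmax(floor((x - rng[1L]) / diff(rng) * nbins) + 1L, 1L),
                     nbins), nbins)
  p <- h / sum(h)
  centers <- rng[1L] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nbins]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-nbins])
  rng[1L] + k / nbins * diff(rng)
}

#' Build continuous max-flow capacities from intensities
#'
#' The data model behind the cut: voxels near the foreground intensity level
#' are cheap to keep in the bulb, voxels near the background level cheap to
#' exclude. Source capacity `Cs(x) = |I(x) - bg|` (cost of labeling x
#' background), sink capacity `Ct(x) = |I(x) - fg|`, and a constant
#' regularization field `w(x) = lam`. When levels are not supplied they
#' default to the class means of the Otsu split of the ROI histogram; the
#' brighter class is the bulb (the vitreous is bright on EPI).
#'
#' @param subvolume 3D intensity array (the ROI).
#' @param fg_level,bg_level foreground/background intensity levels; both
#'   NULL means estimate via Otsu.
#' @param lam regularization weight; NULL means `0.1 * diff(range(subvolume))`.
#' @return a [CmfProblem-class].
#' @export
buildCapacities <- function(subvolume, fg_level = NULL, bg_level = NULL,
                            lam = NULL) {
  stopifnot(length(dim(subvolume)) == 3L)
  if (is.null(fg_level) || is.null(bg_level)) {
    if (diff(range(subvolume)) <= 0)
      stop("constant subvolume: no split exists; supply explicit fg/bg levels")
    thr <- otsuThreshold(subvolume)
    hi <- subvolume > thr
    if (!any(hi) || all(hi))
      stop("degenerate Otsu split; supply explicit fg/bg levels")
    if (is.null(fg_level)) fg_level <- mean(subvolume[hi])
    if (is.null(bg_level)) bg_level <- mean(subvolume[!hi])
  }
  if (fg_level == bg_level)
    stop("fg_level and bg_level must differ")
  if (is.null(lam)) {
    rng <- diff(range(subvolume))
    lam <- 0.1 * (if (rng > 0) rng else abs(fg_level - bg_level))
  }
  d <- dim(subvolume)
  new("CmfProblem", image = subvolume,
      cs = abs(subvolume - bg_level),
      ct = abs(subvolume - fg_level),
      weight = array(lam, d))
}

#' Energy of a labeling under the continuous max-flow model
#'
#' Evaluates `E(u) = <1-u, Cs> + <u, Ct> + sum_x w(x) |grad u|(x)` with the
#' solver's own discretization (forward differences, anisotropic total
#' variation, reflective boundaries). Valid for relaxed labelings in
#' `[0, 1]` and for binary masks alike, so thresholded solutions can be
#' compared against exact discrete minimum cuts.
#'
#' @param problem a [CmfProblem-class].
#' @param u labeling array on the problem grid (numeric or logical).
#' @return the energy (scalar).
#' @export
cmfEnergy <- function(problem, u) {
  u <- array(as.numeric(u), dim(problem@image))
  data_term <- sum((1 - u) * problem@cs + u * problem@ct)
  tv <- sum(problem@weight *
              (abs(.fwd_diff(u, 1L)) + abs(.fwd_diff(u, 2L)) +
                 abs(.fwd_diff(u, 3L))))
  data_term + tv
}

.mask_quality <- function(mask3d) {
  n_fg <- sum(mask3d)
  if (n_fg == 0L)
    return(list(mask = mask3d, frac = 0, flagged = TRUE))
  comp <- .connected_labels(mask3d)
  sizes <- tabulate(comp$labels)
  big <- which.max(sizes)
  frac <- sizes[big] / n_fg
  keep <- array(FALSE, dim(mask3d))
  keep[comp$which[comp$labels == big]] <- TRUE
  # besides fragmentation, flag implausible bulb sizes: a bulb occupies a
  # modest fraction of its ROI box (~20 % for the study geometry); (near-)
  # empty or box-filling masks mean the ROI holds no segmentable bulb
  roi_frac <- sizes[big] / length(mask3d)
  list(mask = keep, frac = frac,
       flagged = frac < 0.9 || roi_frac > 0.5 || roi_frac < 0.02)
}

# 6-connected component labels of the TRUE voxels (igraph backend)
.connected_labels <- function(mask3d) {
  d <- dim(mask3d)
  lin <- which(mask3d)
  id <- array(0L, d)
  id[lin] <- seq_along(lin)
  pos <- arrayInd(lin, d)
  edges <- NULL
  strides <- c(1L, d[1L], d[1L] * d[2L])
  for (axis in 1:3) {
    ok <- pos[, axis] < d[axis]
    nb <- lin[ok] + strides[axis]
    both <- mask3d[nb]
    if (any(both))
      edges <- rbind(edges, cbind(id[lin[ok][both]], id[nb[both]]))
  }
  if (is.null(edges)) {
    labels <- seq_along(lin)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(lin) - igraph::vcount(g)))
    labels <- igraph::components(g)$membership
  }
  list(which = lin, labels = labels)
}

#' Continuous max-flow segmentation of one subvolume
#'
#' Solves the convex relaxation of the two-label min-cut energy with a
#' first-order augmented-Lagrangian scheme (fixed steps; flow variables
#' `ps`, `pt`, spatial flow `q` with the anisotropic constraint
#' `|q_i| <= w`, labeling `u` as the multiplier). Capacities are rescaled
#' internally to unit magnitude for conditioning, which leaves the minimizer
#' unchanged. Each sweep the primal energy of the clipped labeling is
#' evaluated and the best iterate so far is retained, so the reported
#' energy trace is non-increasing and the returned labeling is never worse
#' than any intermediate one. Iterations stop when the mean absolute
#' labeling change per voxel drops below `tol`, or at `maxIter` with a
#' warning.
#'
#' The relaxed labeling is thresholded at 0.5 (ties to foreground). The
#' attributes `energyTrace`, `iterations` and `converged` carry solver
#' diagnostics.
#'
#' @param problem a [CmfProblem-class].
#' @param tol mean absolute labeling change per voxel at which to stop.
#' @param maxIter maximum number of sweeps.
#' @param eye,t tags stored on the result.
#' @return a [BulbMask-class] (relaxed + thresholded; no connected-component
#'   filtering — see [segmentSeries()] for the post-filter).
#' @export
cmfSegment <- function(problem, tol = 1e-4, maxIter = 300L,
                       eye = "left", t = 0L) {
  stopifnot(tol > 0, maxIter >= 1L)
  d <- dim(problem@image)
  sc <- max(problem@cs, problem@ct, problem@weight, 1e-12)
  cs <- problem@cs / sc
  ct <- problem@ct / sc
  w <- problem@weight / sc
  cc <- 0.35
  steps <- 0.11

  u <- array(as.numeric(cs >= ct), d)
  ps <- pmin(cs, ct)
  pt <- ps
  qx <- array(0, d); qy <- array(0, d); qz <- array(0, d)
  dv <- array(0, d)

  best_u <- pmin(pmax(u, 0), 1)
  best_e <- cmfEnergy(problem, best_u)
  etrace <- best_e
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(maxIter)) {
    iters <- it
    err_field <- dv - ps + pt - u / cc
    qx <- pmin(pmax(qx + steps * .fwd_diff(err_field, 1L), -w), w)
    qy <- pmin(pmax(qy + steps * .fwd_diff(err_field, 2L), -w), w)
    qz <- pmin(pmax(qz + steps * .fwd_diff(err_field, 3L), -w), w)
    dv <- .divergence(qx, qy, qz)
    ps <- pmin(cs, dv + pt + (1 - u) / cc)
    pt <- pmin(ct, ps - dv + u / cc)
    r <- dv - ps + pt
    u <- u - cc * r

    uc <- pmin(pmax(u, 0), 1)
    e <- cmfEnergy(problem, uc)
    if (e < best_e) {
      best_e <- e
      best_u <- uc
    }
    etrace <- c(etrace, best_e)
    if (mean(abs(cc * r)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("CMF did not converge in %d iterations (mean change %.2g > tol %.2g)",
                    maxIter, mean(abs(cc * (dv - ps + pt))), tol))

  mask <- best_u >= 0.5
  qual <- .mask_quality(mask)
  res <- new("BulbMask", eye = eye, t = as.integer(t), mask = mask,
             relaxed = best_u, voxelSize = c(1, 1, 1),
             voxelCount = as.integer(sum(mask)),
             flagged = qual$flagged || sum(mask) == 0L)
  attr(res, "energyTrace") <- etrace
  attr(res, "iterations") <- iters
  attr(res, "converged") <- converged
  res
}

#' Segment the eye bulb in every volume of a series
#'
#' Runs Otsu-initialized continuous max-flow inside the ROI of each volume,
#' keeps only the largest 6-connected component of each thresholded mask,
#' and records a per-volume quality flag (empty mask, fragmented mask with
#' largest component < 90 % of foreground, implausible bulb size with the
#' retained component filling > 50 % or < 2 % of the ROI box, or a failed
#' intensity split).
#' Intensity levels are re-estimated per volume, which makes the
#' segmentation invariant to global intensity rescaling and robust to slow
#' scanner drift.
#'
#' @param series an [EpiSeries-class].
#' @param roi a resolved [RoiBox-class].
#' @param lambda regularization weight as a fraction of the per-volume ROI
#'   intensity range.
#' @param tol,maxIter solver controls, see [cmfSegment()].
#' @param verbose print progress every 100 volumes.
#' @return a [BulbMaskSeries-class].
#' @export
segmentSeries <- function(series, roi, lambda = 0.1, tol = 1e-4,
                          maxIter = 300L, verbose = FALSE) {
  dat <- epiData(series)
  nt <- dim(dat)[4L]
  b <- roiBounds(roi)
  rd <- as.integer(b[2L, ] - b[1L, ] + 1L)
  masks <- array(FALSE, c(rd, nt))
  flags <- logical(nt)
  counts <- integer(nt)
  for (ti in seq_len(nt)) {
    sub <- array(.roi_slice(dat, roi, t = ti - 1L), rd)
    prob <- tryCatch(
      buildCapacities(sub, lam = lambda * diff(range(sub))),
      error = function(e) NULL)
    if (is.null(prob)) {
      flags[ti] <- TRUE
      next
    }
    bm <- withCallingHandlers(
      cmfSegment(prob, tol = tol, maxIter = maxIter,
                 eye = roiEye(roi), t = ti - 1L),
      warning = function(w) invokeRestart("muffleWarning"))
    qual <- .mask_quality(bm@mask)
    masks[, , , ti] <- qual$mask
    counts[ti] <- sum(qual$mask)
    flags[ti] <- qual$flagged || counts[ti] == 0L
    if (verbose && ti %% 100L == 0L)
      message("segmented ", ti, "/", nt, " volumes (", roiEye(roi), ")")
  }
  if (all(flags))
    stop("segmentation failed: every volume is flagged in the ",
         roiEye(roi), " ROI")
  new("BulbMaskSeries", eye = roiEye(roi), mask = masks, roi = roi,
      voxelSize = voxelSize(series), tr = repetitionTime(series),
      voxelCount = counts, flagged = flags)
}

#' Bulb volume in cubic millimetres
#'
#' `voxel_count * prod(voxelSize)`; with the study's 3 mm isotropic voxels
#' the conversion factor is 27 mm^3 per voxel.
#'
#' @param mask a [BulbMask-class], [BulbMaskSeries-class] or logical array.
#' @param voxelSize mm triple (taken from the object when omitted).
#' @return volume(s) in mm^3 (one value per volume for a series).
#' @export
setGeneric("bulbVolume", function(mask, voxelSize) standardGeneric("bulbVolume"))

#' @rdname bulbVolume
setMethod("bulbVolume", signature(mask = "BulbMask", voxelSize = "numeric"),
          function(mask, voxelSize) mask@voxelCount * prod(voxelSize))

#' @rdname bulbVolume
setMethod("bulbVolume", signature(mask = "BulbMaskSeries", voxelSize = "missing"),
          function(mask, voxelSize) mask@voxelCount * prod(mask@voxelSize))

#' @rdname bulbVolume
setMethod("bulbVolume", signature(mask = "array", voxelSize = "numeric"),
          function(mask, voxelSize) sum(mask != 0) * prod(voxelSize))

#' Per-volume volumetry table
#'
#' @param bms a [BulbMaskSeries-class].
#' @return data.frame with columns eye, t, voxel_count, volume_mm3, flagged.
#' @export
volumetryTable <- function(bms) {
  data.frame(eye = bms@eye, t = seq_len(nVolumes(bms)) - 1L,
             voxel_count = bms@voxelCount,
             volume_mm3 = bulbVolume(bms),
             flagged = bms@flagged)
}

#' Write per-volume bulb masks as a 4D NIfTI-1 binary volume
#'
#' The ROI-local masks are embedded into the full series grid (one file per
#' eye, uint8).
#'
#' @param bms a [BulbMaskSeries-class].
#' @param series the [EpiSeries-class] the masks were computed on.
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
writeBulbMasks <- function(bms, series, path) {
  d <- dim(epiData(series))
  full <- array(0L, d)
  b <- roiBounds(bms@roi)
  full[(b[1L, 1L]:b[2L, 1L]) + 1L, (b[1L, 2L]:b[2L, 2L]) + 1L,
       (b[1L, 3L]:b[2L, 3L]) + 1L, ] <- as.integer(bms@mask)
  writeNifti(full, path, voxelSize = voxelSize(series),
             tr = repetitionTime(series), affine = epiAffine(series),
             sform_code = if (imageSpace(series) == "normalized") 4L else 1L,
             datatype = 2L)
}
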