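# Bulb shape analysis: isosurface extraction, maximum-diameter vector,
# axis angles.
#
# The isosurface is a marching-cubes construction generated from first
# principles: on every face of every mixed 2x2x2 sample cell, marching-
# squares segments connect the crossing points (ambiguous faces pair the
# segments so that inside corners are separated -- a fixed, orientation-free
# rule, hence watertight across neighboring cells); the segments close into
# cycles inside each cell, which are fan-triangulated. All vertices lie on
# lattice (axis) edges. The 256-entry case table is derived once at first
# use and cached.

.mc_env <- new.env(parent = emptyenv())

.mc_geometry <- function() {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 edges: corner pairs at Hamming distance 1, ordered by axis
  edges <- NULL
  for (axis in 1:3)
    for (c1 in 1:8)
      if (corners[c1, axis] == 0L) {
        c2 <- which(colSums(abs(t(corners) - (corners[c1, ] +
                                                (1:3 == axis)))) == 0)
        edges <- rbind(edges, c(c1, c2, axis))
      }
  colnames(edges) <- c("a", "b", "axis")
  # 6 faces: 4 corners in cyclic order plus their 4 boundary edges
  faces <- list()
  for (axis in 1:3)
    for (val in 0:1) {
      cs <- which(corners[, axis] == val)
      other <- setdiff(1:3, axis)
      ctr <- colMeans(corners[cs, , drop = FALSE])
      ang <- atan2(corners[cs, other[2L]] - ctr[other[2L]],
                   corners[cs, other[1L]] - ctr[other[1L]])
      cs <- cs[order(ang)]
      fe <- integer(4L)
      for (k in 1:4) {
        p <- sort(c(cs[k], cs[k %% 4L + 1L]))
        fe[k] <- which(edges[, 1L] == p[1L] & edges[, 2L] == p[2L])
      }
      faces[[length(faces) + 1L]] <- list(corners = cs, edges = fe)
    }
  list(corners = corners, edges = edges, faces = faces)
}

# marching-squares segments on one face: values in {0,1} for the 4 cyclic
# corners; returns pairs of local edge slots (edge k joins corner k and k+1)
.ms_segments <- function(v) {
  nfg <- sum(v)
  if (nfg == 0L || nfg == 4L) return(NULL)
  cut <- which(v != v[c(2:4, 1L)] | v != v[c(4L, 1:3)])
  adj <- function(ci) c((ci - 2L) %% 4L + 1L, ci)  # edges touching corner ci
  if (nfg == 1L) return(list(adj(which(v == 1L))))
  if (nfg == 3L) return(list(adj(which(v == 0L))))
  fg <- which(v == 1L)
  if (diff(fg) == 2L)                      # diagonal: isolate each fg corner
    return(list(adj(fg[1L]), adj(fg[2L])))
  # adjacent pair: the two cut edges form one segment
  cut <- which(v != v[c(2:4, 1L)])
  list(cut)
}

.mc_case_table <- function() {
  if (!is.null(.mc_env$table)) return(.mc_env$table)
  geo <- .mc_geometry()
  tab <- vector("list", 256L)
  for (case in 0:255) {
    v <- as.integer(bitwAnd(bitwShiftR(case, 0:7), 1L))
    segs <- NULL
    for (f in geo$faces) {
      for (s in .ms_segments(v[f$corners]))
        segs <- rbind(segs, f$edges[s])
    }
    if (is.null(segs)) {
      tab[[case + 1L]] <- matrix(integer(), ncol = 3L)
      next
    }
    # trace cycles: every crossing edge appears in exactly two segments
    tris <- NULL
    used <- rep(FALSE, nrow(segs))
    while (any(!used)) {
      i <- which(!used)[1L]
      used[i] <- TRUE
      cyc <- segs[i, ]
      repeat {
        tail <- cyc[length(cyc)]
        nxt <- which(!used & (segs[, 1L] == tail | segs[, 2L] == tail))
        if (!length(nxt)) break
        j <- nxt[1L]
        used[j] <- TRUE
        other <- if (segs[j, 1L] == tail) segs[j, 2L] else segs[j, 1L]
        if (other == cyc[1L]) break
        cyc <- c(cyc, other)
      }
      if (length(cyc) >= 3L)
        for (k in 2:(length(cyc) - 1L))
          tris <- rbind(tris, c(cyc[1L], cyc[k], cyc[k + 1L]))
    }
    tab[[case + 1L]] <- if (is.null(tris)) matrix(integer(), ncol = 3L) else tris
  }
  .mc_env$table <- tab
  .mc_env$geometry <- geo
  tab
}

#' Extract the isosurface of a bulb mask
#'
#' Marching-cubes-style triangulated surface at the given level of the
#' binary mask (default) or of the relaxed labeling. The volume is padded
#' with background so the surface is closed; vertices are scaled by
#' `voxelSize` into mm in the ROI-local frame (coordinate of voxel index i
#' is `i * voxelSize`). All vertices lie on lattice edges; for a binary
#' mask each vertex sits exactly half a voxel from the inside sample.
#'
#' @param mask a [BulbMask-class], or a 3D logical/numeric array.
#' @param voxelSize mm triple.
#' @param level iso-level (default 0.5).
#' @param useRelaxed for a [BulbMask-class]: interpolate on the relaxed
#'   labeling instead of the binary mask.
#' @return a [SurfaceMesh-class].
#' @export
extractSurface <- function(mask, voxelSize = c(1, 1, 1), level = 0.5,
                           useRelaxed = FALSE) {
  if (is(mask, "BulbMask")) {
    vals <- if (useRelaxed && !is.null(mask@relaxed)) mask@relaxed else
      mask@mask * 1
  } else vals <- mask * 1
  stopifnot(length(dim(vals)) == 3L)
  if (!any(vals >= level)) stop("no surface: the mask is empty")

  d <- dim(vals)
  D <- d + 2L
  P <- array(0, D)
  P[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- vals
  B <- P >= level

  tab <- .mc_case_table()
  geo <- .mc_env$geometry

  # global vertex ids on crossing lattice edges, one id array per axis
  ids <- vector("list", 3L)
  verts <- NULL
  nv <- 0L
  for (axis in 1:3) {
    n <- D[axis]
    hd <- switch(axis,
                 P[1:(n - 1L), , , drop = FALSE],
                 P[, 1:(n - 1L), , drop = FALSE],
                 P[, , 1:(n - 1L), drop = FALSE])
    tl <- switch(axis,
                 P[2:n, , , drop = FALSE],
                 P[, 2:n, , drop = FALSE],
                 P[, , 2:n, drop = FALSE])
    cut <- which((hd >= level) != (tl >= level))
    ed <- dim(hd)
    idar <- array(0L, ed)
    idar[cut] <- nv + seq_along(cut)
    ids[[axis]] <- idar
    if (length(cut)) {
      pos <- arrayInd(cut, ed)              # padded index of the head sample
      v1 <- hd[cut]; v2 <- tl[cut]
      tt <- (level - v1) / (v2 - v1)
      tt[!is.finite(tt)] <- 0.5
      coord <- pos - 2                      # 0-based original voxel index
      coord[, axis] <- coord[, axis] + tt
      verts <- rbind(verts, coord)
      nv <- nv + length(cut)
    }
  }
  verts <- sweep(verts, 2L, voxelSize, `*`)
  colnames(verts) <- c("x", "y", "z")

  # classify cells and emit triangles per case
  Dc <- D - 1L
  case_arr <- array(1L, Dc)
  for (c1 in 1:8) {
    o <- geo$corners[c1, ]
    blk <- B[(1:Dc[1L]) + o[1L], (1:Dc[2L]) + o[2L], (1:Dc[3L]) + o[3L],
             drop = FALSE]
    case_arr <- case_arr + as.integer(blk) * as.integer(2^(c1 - 1L))
  }
  mixed <- which(case_arr > 1L & case_arr < 256L)
  faces <- NULL
  if (length(mixed)) {
    cells <- arrayInd(mixed, Dc)
    ccase <- case_arr[mixed]
    for (cs in unique(ccase)) {
      tris <- tab[[cs]]
      if (!nrow(tris)) next
      sel <- cells[ccase == cs, , drop = FALSE]
      # resolve each case edge to global vertex ids for all cells at once
      eid <- matrix(0L, nrow(sel), 12L)
      for (e in sort(unique(as.integer(tris)))) {
        ca <- geo$edges[e, 1L]
        axis <- geo$edges[e, 3L]
        o <- geo$corners[ca, ]
        idar <- ids[[axis]]
        lin <- (sel[, 1L] + o[1L]) +
          dim(idar)[1L] * ((sel[, 2L] + o[2L]) - 1L) +
          dim(idar)[1L] * dim(idar)[2L] * ((sel[, 3L] + o[3L]) - 1L)
        eid[, e] <- idar[lin]
      }
      for (r in seq_len(nrow(tris)))
        faces <- rbind(faces, cbind(eid[, tris[r, 1L]], eid[, tris[r, 2L]],
                                    eid[, tris[r, 3L]]))
    }
  }
  if (is.null(faces)) faces <- matrix(integer(), ncol = 3L)
  new("SurfaceMesh", vertices = verts, faces = faces, level = level)
}

# a diameter is an unordered pair, so u is defined up to sign; fix the
# hemisphere by the anterior (y) component first: the bulb's major axis
# points out of the orbit for any physiological gaze, so uy keeps one sign
# while uz may legitimately hover around 0 with the eyes open -- folding on
# uz instead would rectify that noise into a positive elevation bias
.canonical_u <- function(u) {
  s <- sign(u[2L])
  if (s == 0) s <- sign(u[3L])
  if (s == 0) s <- sign(u[1L])
  if (s == 0) s <- 1
  u * s
}

#' Maximum-diameter vector of a surface
#'
#' The vertex pair with maximal Euclidean distance, found by an exhaustive
#' (blocked) all-pairs scan, so the result equals the brute-force maximum
#' exactly. A diameter is an unordered pair, so its direction is defined up
#' to sign; the unit vector is canonicalized to the `uy >= 0` hemisphere
#' (ties: `uz >= 0`, then `ux >= 0`). The bulb's major axis points
#' anteriorly for any physiological gaze, so fixing the anterior sign keeps
#' orientation time series free of sign flips while leaving the
#' physiologically meaningful `uz` (elevation) component signed — folding
#' on `uz` instead would rectify its noise into a positive bias whenever
#' the eyes are open and the true elevation is near 0.
#' Ties in length (within 1e-9 mm) resolve to the pair whose canonical unit
#' vector is lexicographically largest by (y, z, x).
#'
#' @param mesh a [SurfaceMesh-class] (or an n x 3 vertex matrix).
#' @param eye,t optional tags stored on the result.
#' @return a [DiameterVector-class].
#' @export
maxDiameter <- function(mesh, eye = NA_character_, t = NA_integer_) {
  V <- if (is(mesh, "SurfaceMesh")) mesh@vertices else as.matrix(mesh)
  V <- unique(V)
  n <- nrow(V)
  if (n < 2L) stop("degenerate mesh: fewer than 2 distinct vertices")
  r2 <- rowSums(V^2)
  bs <- 512L
  blocks <- seq(1L, n, by = bs)
  pair_d2 <- function(ii) outer(r2[ii], r2, `+`) -
    2 * V[ii, , drop = FALSE] %*% t(V)
  best <- -Inf
  for (i0 in blocks) {
    ii <- i0:min(i0 + bs - 1L, n)
    best <- max(best, pair_d2(ii))
  }
  dmax <- sqrt(max(best, 0))
  # second pass: gather every pair within the 1e-9 mm tie band of the max
  cand <- NULL
  thr <- max((dmax - 1e-9)^2, 0)
  for (i0 in blocks) {
    ii <- i0:min(i0 + bs - 1L, n)
    w <- which(pair_d2(ii) >= thr - 1e-12, arr.ind = TRUE)
    if (nrow(w)) cand <- rbind(cand, cbind(ii[w[, 1L]], w[, 2L]))
  }
  # ties within 1e-9 mm in length: lexicographically largest canonical unit
  dcand <- sqrt(rowSums((V[cand[, 1L], , drop = FALSE] -
                           V[cand[, 2L], , drop = FALSE])^2))
  cand <- cand[dmax - dcand <= 1e-9, , drop = FALSE]
  pick <- 1L
  if (nrow(cand) > 1L) {
    units <- t(apply(cand, 1L, function(pr)
      .canonical_u(V[pr[2L], ] - V[pr[1L], ]) /
        sqrt(sum((V[pr[2L], ] - V[pr[1L], ])^2))))
    ord <- order(units[, 2L], units[, 3L], units[, 1L], decreasing = TRUE)
    pick <- ord[1L]
  }
  p0 <- as.numeric(V[cand[pick, 1L], ])
  p1 <- as.numeric(V[cand[pick, 2L], ])
  u <- p1 - p0
  len <- sqrt(sum(u^2))
  uc <- .canonical_u(u)
  if (!all(uc == u)) {                     # swap endpoints to match the sign
    tmp <- p0; p0 <- p1; p1 <- tmp
    u <- uc
  }
  new("DiameterVector", p0 = p0, p1 = p1, u = u, length = len,
      unit = u / len, eye = eye, t = as.integer(t))
}

#' Axis angles of a diameter vector
#'
#' The horizontal angle is measured between the unit vector and the
#' positive x-axis, the vertical angle between the unit vector and the
#' positive z-axis, both as `acos(u . axis)` in radians after
#' canonicalization; eye closure (upward bulb rotation, Bell's phenomenon)
#' lowers the vertical angle toward 0.
#'
#' @param v a [DiameterVector-class] (or a unit 3-vector).
#' @return named numeric: `horizontal`, `vertical` (radians, in `[0, pi]`).
#' @export
axisAngles <- function(v) {
  u <- if (is(v, "DiameterVector")) v@unit else .canonical_u(v / sqrt(sum(v^2)))
  clamp <- function(x) pmin(pmax(x, -1), 1)
  c(horizontal = acos(clamp(u[1L])), vertical = acos(clamp(u[3L])))
}

# separable Gaussian on a 3D field, sigma in voxels, replicated edges;
# used to regularize the intensity field before isosurface extraction
.smooth_field <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- (-r):r
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    n <- dim(a)[axis]
    acc <- array(0, dim(a))
    for (k in seq_along(off)) {
      idx <- pmin(pmax(seq_len(n) + off[k], 1L), n)
      acc <- acc + w[k] * switch(axis, a[idx, , ], a[, idx, ], a[, , idx])
    }
    a <- acc
  }
  a
}

# dilate a binary 3D mask by `iter` steps of the 6-neighborhood
.dilate6 <- function(m, iter = 2L) {
  d <- dim(m)
  for (k in seq_len(iter)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1L], , ]
    out[-d[1L], , ] <- out[-d[1L], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2L], ]
    out[, -d[2L], ] <- out[, -d[2L], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3L]]
    out[, , -d[3L]] <- out[, , -d[3L]] | m[, , -1]
    m <- out
  }
  m
}

#' Orientation time series of a segmented eye
#'
#' Reduces every per-volume bulb mask to its maximum-diameter unit vector
#' and axis angles. Flagged volumes yield missing values which are then
#' linearly interpolated (constant extrapolation at the run ends) so that
#' temporal filters see a regularly sampled series; the `flagged` column
#' records which rows are interpolated.
#'
#' With `surface = "mask"` the isosurface is taken on the binary mask. With
#' `surface = "intensity"` (used by the pipeline when the series is
#' available) it is taken on the ROI intensity field at the midpoint
#' between the in-mask and out-of-mask mean levels, restricted to a
#' 2-voxel dilation of the mask: partial-volume boundary voxels then
#' localize the bulb border at sub-voxel precision, which stabilizes the
#' maximum-diameter orientation — on a voxel-resolution binary surface the
#' longest chord of a near-spheroid bulb is directionally degenerate.
#'
#' @param masks a [BulbMaskSeries-class], or a list of them (rows are
#'   concatenated).
#' @param series the [EpiSeries-class] the masks came from (required for
#'   `surface = "intensity"`).
#' @param surface `"mask"` (default) or `"intensity"`.
#' @param useRelaxed passed to [extractSurface()] (mask surfaces only).
#' @return data.frame with columns eye, t, seconds, ux, uy, uz, length_mm,
#'   horizontal_rad, vertical_rad, flagged.
#' @export
vectorTimeseries <- function(masks, series = NULL,
                             surface = c("mask", "intensity"),
                             useRelaxed = FALSE) {
  surface <- match.arg(surface)
  if (is.list(masks))
    return(do.call(rbind, lapply(masks, vectorTimeseries, series = series,
                                 surface = surface,
                                 useRelaxed = useRelaxed)))
  stopifnot(is(masks, "BulbMaskSeries"))
  if (surface == "intensity" && is.null(series))
    stop("surface = 'intensity' needs the series")
  sub4 <- if (surface == "intensity")
    .roi_slice(epiData(series), masks@roi) else NULL
  nt <- nVolumes(masks)
  if (all(masks@flagged))
    stop("all volumes flagged for the ", masks@eye, " eye")
  out <- data.frame(eye = masks@eye, t = seq_len(nt) - 1L,
                    seconds = (seq_len(nt) - 1L) * masks@tr,
                    ux = NA_real_, uy = NA_real_, uz = NA_real_,
                    length_mm = NA_real_, horizontal_rad = NA_real_,
                    vertical_rad = NA_real_, flagged = masks@flagged)
  for (ti in seq_len(nt)) {
    if (masks@flagged[ti]) next
    m3 <- array(masks@mask[, , , ti], dim(masks@mask)[1:3])
    if (surface == "intensity") {
      field <- array(sub4[, , , ti], dim(m3))
      bg <- mean(field[!m3])
      fg <- mean(field[m3])
      field[!.dilate6(m3, 2L)] <- bg
      # 0.7-voxel regularization: suppresses voxel noise on the level set
      # without eroding the bulb's anisotropy
      field <- .smooth_field(field, 0.7)
      mesh <- extractSurface(field, voxelSize = masks@voxelSize,
                             level = (fg + bg) / 2)
    } else {
      mesh <- extractSurface(m3, voxelSize = masks@voxelSize,
                             useRelaxed = useRelaxed)
    }
    dv <- maxDiameter(mesh, eye = masks@eye, t = ti - 1L)
    ang <- axisAngles(dv)
    out[ti, c("ux", "uy", "uz")] <- dv@unit
    out$length_mm[ti] <- dv@length
    out$horizontal_rad[ti] <- ang[["horizontal"]]
    out$vertical_rad[ti] <- ang[["vertical"]]
  }
  for (col in c("ux", "uy", "uz", "length_mm", "horizontal_rad",
                "vertical_rad"))
    out[[col]] <- .interp_na(out[[col]])
  out
}

# linear interpolation of interior NAs, constant extrapolation at the ends
.interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Write an orientation feature table as TSV
#'
#' @param features data.frame from [vectorTimeseries()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
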