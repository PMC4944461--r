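# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Only what the package needs: 3D/4D scalar images, little- or big-endian,
# dtypes uint8 / int16 / int32 / float32 / float64, scl_slope/inter, sform
# affine, TR in pixdim[4]. Written because no NIfTI package is available in
# the target library set.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 image
#'
#' Low-level reader returning the raw array plus the header fields the
#' package uses. Most users want [loadEpi()] instead.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `dim`, `pixdim`, `tr`
#'   (seconds, 0 when absent), `affine` (4x4), `sform_code`, `qform_code`,
#'   `datatype`.
#' @export
readNifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .open_nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)

  parse_hdr <- function(raw, endian) {
    rc <- rawConnection(raw)
    on.exit(close(rc))
    rd <- function(what, n, size, signed = TRUE)
      readBin(rc, what, n = n, size = size, signed = signed, endian = endian)
    h <- list()
    h$sizeof_hdr <- rd("integer", 1L, 4L)
    invisible(rd("raw", 36L, 1L))                  # unused fields through byte 39
    h$dim <- rd("integer", 8L, 2L)
    invisible(rd("double", 3L, 4L))                # intent parameters
    invisible(rd("integer", 1L, 2L))               # intent_code
    h$datatype <- rd("integer", 1L, 2L)
    h$bitpix <- rd("integer", 1L, 2L)
    invisible(rd("integer", 1L, 2L))               # slice_start
    h$pixdim <- rd("double", 8L, 4L)
    h$vox_offset <- rd("double", 1L, 4L)
    h$scl_slope <- rd("double", 1L, 4L)
    h$scl_inter <- rd("double", 1L, 4L)
    invisible(rd("integer", 1L, 2L))               # slice_end
    invisible(rd("raw", 2L, 1L))                   # slice_code, xyzt_units
    invisible(rd("double", 4L, 4L))                # cal_max..toffset
    invisible(rd("integer", 2L, 4L))               # glmax, glmin
    invisible(rd("raw", 104L, 1L))                 # descrip, aux_file
    h$qform_code <- rd("integer", 1L, 2L)
    h$sform_code <- rd("integer", 1L, 2L)
    invisible(rd("double", 6L, 4L))                # quaternion fields
    h$srow <- matrix(rd("double", 12L, 4L), nrow = 3L, byrow = TRUE)
    invisible(rd("raw", 16L, 1L))                  # intent_name
    h$magic <- rawToChar(rd("raw", 4L, 1L)[1:3])
    h
  }

  endian <- "little"
  hdr <- parse_hdr(hdr_raw, endian)
  if (hdr$sizeof_hdr != 348L) {
    endian <- "big"
    hdr <- parse_hdr(hdr_raw, endian)
    if (hdr$sizeof_hdr != 348L)
      stop("not a NIfTI-1 file (bad header size): ", path)
  }
  if (!hdr$magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  if (hdr$magic == "ni1")
    stop("two-file (.hdr/.img) NIfTI is not supported: ", path)

  dt <- .nifti_dtypes[[as.character(hdr$datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", hdr$datatype, " in ", path)

  ndim <- hdr$dim[1L]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim[0] in ", path)
  shape <- pmax(hdr$dim[2L:(1L + ndim)], 1L)
  nvox <- prod(shape)

  # a gz connection cannot seek; consume up to the data offset
  skip <- hdr$vox_offset - 348
  if (skip > 0) invisible(readBin(con, "raw", n = as.integer(skip)))
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    vals <- vals * hdr$scl_slope + hdr$scl_inter

  affine <- diag(4)
  if (hdr$sform_code > 0L) {
    affine[1:3, ] <- hdr$srow
  } else {
    diag(affine)[1:3] <- hdr$pixdim[2:4]
  }
  # header floats are float32; present them at that precision
  list(data = array(vals, dim = shape), dim = shape,
       pixdim = signif(hdr$pixdim[2:4], 7),
       tr = if (ndim >= 4L && is.finite(hdr$pixdim[5L]))
         signif(hdr$pixdim[5L], 7) else 0,
       affine = affine, sform_code = hdr$sform_code,
       qform_code = hdr$qform_code, datatype = hdr$datatype)
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D/4D array as a single-file little-endian NIfTI-1 image.
#'
#' @param data numeric (or logical) array, 3 or 4 dimensional.
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param voxelSize mm triple.
#' @param tr repetition time in seconds (stored in `pixdim[4]`; ignored for
#'   3D images).
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices);
#'   defaults to a scaling by `voxelSize`.
#' @param sform_code NIfTI sform code (1 = scanner anatomical, 4 = MNI152).
#' @param datatype NIfTI datatype code: 64 (float64, default, lossless for
#'   R numerics) , 16 (float32) or 2 (uint8, e.g. for binary masks).
#' @return the path, invisibly.
#' @export
writeNifti <- function(data, path, voxelSize = c(1, 1, 1), tr = 0,
                       affine = NULL, sform_code = 1L, datatype = 64L) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxelSize
  }
  if (!as.character(datatype) %in% c("2", "16", "64"))
    stop("supported write datatypes: 2 (uint8), 16 (float32), 64 (float64)")
  bitpix <- c(`2` = 8L, `16` = 32L, `64` = 64L)[[as.character(datatype)]]

  con <- .open_nifti_con(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  dimv <- integer(8L)
  dimv[1L] <- nd
  dimv[2L:(1L + nd)] <- dim(data)
  dimv[(2L + nd):8L] <- 1L

  wr(348L, 4L)                                   # sizeof_hdr
  wraw(35L)                                      # data_type..regular
  wraw(1L)                                       # dim_info
  wr(dimv, 2L)
  wr(c(0, 0, 0), 4L)                             # intent_p1..3
  wr(0L, 2L)                                     # intent_code
  wr(as.integer(datatype), 2L)
  wr(bitpix, 2L)
  wr(0L, 2L)                                     # slice_start
  wr(c(1, voxelSize, tr, 0, 0, 0), 4L)           # pixdim (qfac first)
  wr(352, 4L)                                    # vox_offset
  wr(c(1, 0), 4L)                                # scl_slope, scl_inter
  wr(0L, 2L)                                     # slice_end
  wraw(1L)                                       # slice_code
  writeBin(as.raw(10L), con)                     # xyzt_units: mm | sec
  wr(c(0, 0, 0, 0), 4L)                          # cal_max..toffset
  wr(c(0L, 0L), 4L)                              # glmax, glmin
  wraw(104L)                                     # descrip, aux_file
  wr(0L, 2L)                                     # qform_code
  wr(as.integer(sform_code), 2L)
  wr(c(0, 0, 0, 0, 0, 0), 4L)                    # quaternion fields
  wr(as.numeric(t(affine[1:3, ])), 4L)           # srow_x/y/z
  wraw(16L)                                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)    # magic
  wraw(4L)                                       # extension indicator

  vals <- as.numeric(data)
  if (datatype == 2L) {
    writeBin(as.raw(pmin(pmax(round(vals), 0), 255)), con)
  } else {
    wr(vals, if (datatype == 16L) 4L else 8L)
  }
  invisible(path)
}
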