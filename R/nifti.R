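# Minimal NIfTI-1 I/O (single-file uncompressed .nii).
#
# Only the subset of the format this pipeline needs is supported: 3D/4D
# images, datatypes uint8/int16/int32/float32/float64, sform or qform (or
# pixdim fallback) affines, scl_slope/scl_inter scaling, both endiannesses
# on read. Written files are little-endian float64 (volumes) or int32
# (labels) with an sform affine, so write/read round-trips are bit-exact.

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

#' Read a NIfTI-1 image
#'
#' Reads an uncompressed single-file NIfTI-1 image (`.nii`) into a plain
#' list. The affine is taken from the sform if set, else the qform, else a
#' diagonal `pixdim` fallback; it maps 0-based voxel indices `(i,j,k,1)` to
#' world millimetres (RAS+).
#'
#' @param path Path to a `.nii` file.
#' @return A list with elements `data` (numeric array, 3D or 4D), `affine`
#'   (4x4 matrix), `tr` (repetition time in seconds, `pixdim[4]`; may be 0
#'   when the header carries none), and `datatype` (NIfTI code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  seek(con, 40L)
  dim    <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  bitpix   <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope  <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter  <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 252L)
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  quat <- readBin(con, "double", 6L, size = 4L, endian = endian)
  srow <- readBin(con, "double", 12L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop("unsupported NIfTI magic (only single-file 'n+1' is handled): ", path)

  nd <- dim[1]
  if (nd < 3L || nd > 4L)
    stop("expected a 3D or 4D image, got ", nd, "D: ", path)
  shape <- dim[2:(1 + nd)]
  n <- prod(shape)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)

  seek(con, as.integer(round(vox_offset)))
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- if (sform_code > 0L) {
    rbind(matrix(srow, nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    .affine_from_quaternion(quat, pixdim)
  } else {
    diag(c(abs(pixdim[2:4]), 1))
  }
  list(data = array(vals, dim = shape), affine = affine,
       tr = if (nd == 4L) pixdim[5] else 0, datatype = datatype)
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D array as an uncompressed little-endian single-file
#' NIfTI-1 image with an sform affine. Numeric data are stored as float64
#' and integer data as int32 so that a read-back reproduces the array
#' bit-exactly.
#'
#' @param data 3D or 4D numeric or integer array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, mm).
#' @param path Output path (`.nii`).
#' @param tr Repetition time in seconds, stored in `pixdim[4]` (4D only).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, tr = 0) {
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("data must be a 3D or 4D array")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  integerish <- is.integer(data)
  datatype <- if (integerish) 8L else 64L
  bitpix   <- if (integerish) 32L else 64L

  dimfield <- rep(1L, 8L); dimfield[1] <- nd
  dimfield[2:(1 + nd)] <- dim(data)
  vx <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, vx, if (nd == 4L) tr else 0, 0, 0, 0)

  con <- file(path, "wb")
  on.exit(close(con))
  wi4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wi2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf4 <- function(x) writeBin(as.double(x),  con, size = 4L, endian = "little")
  pad <- function(n) writeBin(raw(n), con)

  wi4(348L); pad(36L)                       # sizeof_hdr, unused
  wi2(dimfield)                             # dim[8]
  wf4(c(0, 0, 0)); wi2(0L)                  # intent_p1-3, intent_code
  wi2(datatype); wi2(bitpix); wi2(0L)       # datatype, bitpix, slice_start
  wf4(pixdim)                               # pixdim[8]
  wf4(352); wf4(1); wf4(0)                  # vox_offset, scl_slope, scl_inter
  wi2(0L); pad(2L)                          # slice_end, slice_code + xyzt
  seek(con, 123L); writeBin(as.raw(10L), con)  # xyzt_units = mm | sec
  wf4(c(0, 0, 0, 0)); wi4(c(0L, 0L))        # cal/slice_dur/toffset, glmax/min
  pad(80L + 24L)                            # descrip, aux_file
  wi2(0L); wi2(2L)                          # qform_code = 0, sform_code = 2
  wf4(rep(0, 6))                            # quaternion + qoffset
  wf4(t(affine[1:3, , drop = FALSE]))       # srow_x, srow_y, srow_z
  pad(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  pad(4L)                                   # extension flag
  if (integerish) {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L)
  readBin(rev(b), "integer", 1L, size = 4L)
}

# qform: quaternion (b,c,d) + offsets, qfac in pixdim[1]
.affine_from_quaternion <- function(quat, pixdim) {
  b <- quat[1]; c <- quat[2]; d <- quat[3]
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a*a+b*b-c*c-d*d, 2*(b*c-a*d),     2*(b*d+a*c),
    2*(b*c+a*d),     a*a+c*c-b*b-d*d, 2*(c*d-a*b),
    2*(b*d-a*c),     2*(c*d+a*b),     a*a+d*d-b*b-c*c), 3, 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  S <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  rbind(cbind(S, quat[4:6]), c(0, 0, 0, 1))
}
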