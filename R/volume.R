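# Core volumetric containers: 4D BOLD volumes and 3D label/mask volumes on
# a shared voxel grid. All world coordinates are RAS+ millimetres; voxel
# indices are 0-based in the affine convention (world = A %*% c(i,j,k,1)).

#' Construct a 4D BOLD volume
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world transform (RAS+ mm, 0-based voxels).
#' @param tr Repetition time in seconds.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, affine, tr) {
  if (length(dim(data)) != 4L) stop("expected 4D data array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) stop("volume contains ", nbad, " non-finite voxel value(s)")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  structure(list(data = data, affine = affine, tr = as.double(tr)),
            class = "volume4d")
}

# trusted fast-path constructor for internal pipelines: skips the
# whole-array finite scan (inputs were validated at the I/O boundary)
new_volume4d <- function(data, affine, tr) {
  structure(list(data = data, affine = affine, tr = as.double(tr)),
            class = "volume4d")
}

#' Construct a 3D label volume
#'
#' Non-negative integer labels on a voxel grid; 0 is background. A binary
#' mask is a label volume with labels in \{0, 1\}.
#'
#' @param data 3D array of non-negative integers (numeric accepted and
#'   coerced).
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, affine) {
  if (length(dim(data)) != 3L) stop("expected 3D data array")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (any(!is.finite(data))) stop("labels must be finite")
  if (any(data < 0)) stop("labels must be >= 0 (0 = background)")
  if (any(data != round(data))) stop("labels must be integers")
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = affine), class = "label_volume")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d %dx%dx%d, %d frames, tr=%gs>\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume %dx%dx%d, %d foreground voxel(s), %d label(s)>\n",
              d[1], d[2], d[3], sum(x$data > 0),
              length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

#' Load a 4D BOLD volume from a NIfTI file
#'
#' @param path Path to a 4D `.nii` file.
#' @param tr Optional repetition time (seconds) overriding the header
#'   `pixdim[4]`; required when the header carries none.
#' @return A [volume4d].
#' @export
load_volume4d <- function(path, tr = NULL) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 4L)
    stop("expected 4D image, got ", length(dim(img$data)), "D: ", path)
  tr_use <- if (!is.null(tr)) tr else img$tr
  if (is.null(tr_use) || !is.finite(tr_use) || tr_use <= 0)
    stop("repetition time absent from header; pass tr explicitly: ", path)
  volume4d(img$data, img$affine, tr_use)
}

#' Load a 3D label volume from a NIfTI file
#'
#' @param path Path to a 3D `.nii` file of integer labels.
#' @return A [label_volume].
#' @export
load_label_volume <- function(path) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 3L)
    stop("expected 3D label image, got ", length(dim(img$data)), "D: ", path)
  label_volume(img$data, img$affine)
}

#' Write a volume to NIfTI
#'
#' @param vol A [volume4d] or [label_volume].
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "volume4d")) {
    write_nifti(vol$data, vol$affine, path, tr = vol$tr)
  } else if (inherits(vol, "label_volume")) {
    write_nifti(vol$data, vol$affine, path)
  } else stop("vol must be a volume4d or label_volume")
}

#' Check that two volumes share a voxel grid
#'
#' Shapes must be identical and affines must agree within `tol`; grids are
#' never silently resampled.
#'
#' @param a,b Volumes ([volume4d] or [label_volume]).
#' @param tol Elementwise affine tolerance.
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
assert_same_grid <- function(a, b, tol = 1e-4) {
  da <- dim(a$data)[1:3]; db <- dim(b$data)[1:3]
  if (!identical(da, db))
    stop("grid shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  if (max(abs(a$affine - b$affine)) > tol)
    stop("affine mismatch exceeds tolerance ", tol)
  invisible(TRUE)
}

# Extract the T x V matrix of time series for voxels where mask > 0.
# Column order follows which(mask > 0) (column-major voxel order).
mask_timeseries <- function(vol, mask) {
  assert_same_grid(vol, mask)
  idx <- which(mask$data > 0L)
  if (length(idx) == 0L) stop("empty mask")
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[idx, , drop = FALSE])
}

# Voxel axis whose world direction is (anti)parallel to x, and whether the
# grid is symmetric about the world x = 0 plane along that axis.
lr_axis <- function(vol, tol = 1e-4) {
  A <- vol$affine
  xrow <- abs(A[1, 1:3])
  ax <- which.max(xrow)
  if (xrow[ax] < 2 * max(xrow[-ax]) || xrow[ax] < tol)
    stop("no voxel axis is clearly aligned with the world left-right axis")
  n <- dim(vol$data)[ax]
  # x(world) at voxel 0 and voxel n-1 along ax must be mirror images
  x0 <- A[1, 4]
  x1 <- A[1, ax] * (n - 1) + A[1, 4]
  if (abs(x0 + x1) > tol)
    stop("grid is not symmetric about the world x = 0 plane; ",
         "refusing an asymmetric flip (|x_first + x_last| = ",
         format(abs(x0 + x1)), " mm)")
  ax
}
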