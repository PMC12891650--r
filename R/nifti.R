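# Minimal NIfTI-1 I/O.
#
# The package needs single-file .nii/.nii.gz volumes with a correct affine
# and nothing else, so it carries a small self-contained NIfTI-1 reader and
# writer (sform preferred, qform quaternion fallback, pixdim last resort;
# little- and big-endian; common integer/float datatypes). Round-trips are
# cross-checked against nibabel in the test suite.

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

#' Construct a binary volume mask
#'
#' Container for a 3D binary segmentation: a voxel array, the voxel spacing
#' and a 4x4 affine mapping 0-based voxel indices (i, j, k) to world
#' millimetres. Voxel centers are the geometric carriers: array element
#' `[i+1, j+1, k+1]` (R is 1-based) sits at `affine %*% c(i, j, k, 1)`.
#'
#' @param voxels 3D array; any nonzero value is foreground.
#' @param spacing length-3 positive voxel size in mm. Defaults to the column
#'   norms of the affine, or 1 mm if neither is given.
#' @param affine 4x4 voxel-index-to-world matrix. Defaults to
#'   `diag(c(spacing, 1))`.
#' @return Object of class `"volume_mask"` with fields `voxels` (0/1 integer
#'   array), `spacing`, `affine`, `usable` (FALSE when no foreground voxel)
#'   and `n_foreground`.
#' @export
volume_mask <- function(voxels, spacing = NULL, affine = NULL) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  if (is.null(spacing))
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  vox <- array(as.integer(voxels != 0), dim = dim(voxels))
  nfg <- sum(vox)
  structure(list(voxels = vox, spacing = spacing, affine = affine,
                 usable = nfg > 0L, n_foreground = nfg),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Binary volume mask %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  foreground voxels: %d%s\n", x$n_foreground,
              if (x$usable) "" else "  [NOT USABLE: empty mask]"))
  invisible(x)
}

#' World coordinates of foreground voxel centers
#'
#' @param mask a [volume_mask()].
#' @return n x 3 matrix of world-mm voxel-center coordinates of all
#'   foreground voxels.
#' @export
voxel_centers_world <- function(mask) {
  stopifnot(inherits(mask, "volume_mask"))
  idx <- which(mask$voxels != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3))
  ijk0 <- cbind(idx - 1, 1)  # 0-based homogeneous indices
  out <- ijk0 %*% t(mask$affine)
  out[, 1:3, drop = FALSE]
}

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 segmentation mask
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`) and binarizes it:
#' any nonzero voxel becomes foreground. The affine is taken from the sform
#' when present, else reconstructed from the qform quaternion, else from the
#' pixdim diagonal. 4D volumes with a singleton fourth dimension are
#' accepted.
#'
#' @param path file path.
#' @return A [volume_mask()]; `usable` is `FALSE` (with a warning) for an
#'   all-zero volume.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  rd <- function(what, n, size, at, signed = TRUE, endian) {
    readBin(hdr_raw[(at + 1L):(at + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd("integer", 1, 4, 0, endian = endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, 0, endian = endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  dim_field <- rd("integer", 8, 2, 40, endian = endian)
  ndim <- dim_field[1]
  if (ndim < 3L) stop("volume must be 3D, got ", ndim, "D: ", path)
  dims <- dim_field[2:(ndim + 1L)]
  if (ndim > 3L) {
    if (any(dims[4:ndim] != 1L))
      stop("only 3D volumes supported (non-singleton higher dims): ", path)
    dims <- dims[1:3]
  }
  datatype <- rd("integer", 1, 2, 70, endian = endian)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  pixdim <- rd("double", 8, 4, 76, endian = endian)
  vox_offset <- rd("double", 1, 4, 108, endian = endian)
  scl_slope <- rd("double", 1, 4, 112, endian = endian)
  scl_inter <- rd("double", 1, 4, 116, endian = endian)
  qform_code <- rd("integer", 1, 2, 252, endian = endian)
  sform_code <- rd("integer", 1, 2, 254, endian = endian)

  affine <- NULL
  if (sform_code > 0L) {
    srow <- rbind(rd("double", 4, 4, 280, endian = endian),
                  rd("double", 4, 4, 296, endian = endian),
                  rd("double", 4, 4, 312, endian = endian))
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- rd("double", 1, 4, 256, endian = endian)
    c_ <- rd("double", 1, 4, 260, endian = endian)
    d <- rd("double", 1, 4, 264, endian = endian)
    qoff <- c(rd("double", 1, 4, 268, endian = endian),
              rd("double", 1, 4, 272, endian = endian),
              rd("double", 1, 4, 276, endian = endian))
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ + a * d), 2 * (b * d - a * c_),
                  2 * (b * c_ - a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d + a * b),
                  2 * (b * d + a * c_), 2 * (c_ * d - a * b), a^2 + d^2 - b^2 - c_^2),
                nrow = 3)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sp <- abs(pixdim[2:4]); sp[sp == 0] <- 1
    affine <- rbind(cbind(R %*% diag(sp * c(1, 1, qfac)), qoff), c(0, 0, 0, 1))
  } else {
    sp <- abs(pixdim[2:4]); sp[sp == 0] <- 1
    affine <- diag(c(sp, 1))
  }

  nvox <- prod(dims)
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated voxel data: ", path)
  if (is.finite(scl_slope) && is.finite(scl_inter) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  m <- volume_mask(array(vals, dim = dims), affine = affine)
  if (!m$usable) warning("mask is empty (no foreground voxels): ", path)
  m
}

#' Write a volume mask as NIfTI-1
#'
#' Writes the binary mask as an uncompressed `.nii` (or gzip-compressed
#' `.nii.gz`) single-file NIfTI-1 volume, uint8 data, with the mask affine
#' stored in both sform and qform-free form (sform_code = 2, "aligned").
#'
#' @param mask a [volume_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "volume_mask"))
  dims <- dim(mask$voxels)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  pad <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                      # sizeof_hdr
  pad(36L)                          # data_type..dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)  # dim
  pad(14L)                          # intent_p1..p3, intent_code
  wi(2L, 2L)                        # datatype = uint8
  wi(8L, 2L)                        # bitpix
  wi(0L, 2L)                        # slice_start
  wf(c(1, mask$spacing, 0, 0, 0, 0))   # pixdim
  wf(352)                           # vox_offset
  wf(c(1, 0))                       # scl_slope, scl_inter
  wi(0L, 2L); pad(2L)               # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max..toffset
  wi(c(0L, 0L), 4L)                 # glmax, glmin
  pad(104L)                         # descrip, aux_file
  wi(0L, 2L)                        # qform_code
  wi(2L, 2L)                        # sform_code
  wf(c(0, 0, 0, 0, 0, 0))           # quaternion + qoffset (unused)
  wf(mask$affine[1, ]); wf(mask$affine[2, ]); wf(mask$affine[3, ])
  pad(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  pad(4L)                           # extension flag
  writeBin(as.raw(mask$voxels != 0L), con)
  invisible(path)
}
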