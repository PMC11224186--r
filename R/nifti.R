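# Minimal single-file NIfTI-1 I/O. No NIfTI reader/writer exists in the
# installed R stack, so the subset this package needs is implemented here:
# single-file .nii / .nii.gz, little-endian, datatypes uint8 / int16 /
# int32 / float32 / float64, 3D, no extensions. The affine is written as a
# diagonal scaling (voxel spacings) and is preserved but not interpreted.

.NIFTI_DTYPES <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                      `4` = list(what = "integer", size = 2L, signed = TRUE),
                      `8` = list(what = "integer", size = 4L, signed = TRUE),
                      `16` = list(what = "double", size = 4L, signed = TRUE),
                      `64` = list(what = "double", size = 8L, signed = TRUE))

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D array as NIfTI-1
#'
#' @param x a 3D array, a [ct_volume()] (written as int16 HU), or a logical
#'   mask (written as uint8).
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @param pixdim voxel spacings (3 values, mm); for a `ct_volume` derived
#'   from its geometry (isotropic in-plane pixel of area `pixel_area`).
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = NULL, datatype = NULL) {
  if (inherits(x, "ct_volume")) {
    if (is.null(pixdim))
      pixdim <- c(rep(sqrt(x$pixel_area), 2), x$slice_thickness)
    if (is.null(datatype)) datatype <- 4L
    arr <- x$hu
  } else {
    arr <- x
    if (is.null(pixdim)) pixdim <- c(1, 1, 1)
    if (is.null(datatype)) datatype <- if (is.logical(arr)) 2L else 64L
  }
  if (length(dim(arr)) != 3L) stop("need a 3D array", call. = FALSE)
  dt <- .NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  wi(348L, 4)                               # sizeof_hdr
  writeBin(raw(36L), con)                   # unused / dim_info
  wi(c(3L, dim(arr), 1L, 1L, 1L, 1L), 2)    # dim[8]
  wf(c(0, 0, 0))                            # intent_p1..p3
  wi(0L, 2)                                 # intent_code
  wi(datatype, 2)                           # datatype
  wi(8L * dt$size, 2)                       # bitpix
  wi(0L, 2)                                 # slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))              # pixdim[8], qfac = 1
  wf(352)                                   # vox_offset
  wf(c(1, 0))                               # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2L), con)         # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                            # cal_max, cal_min, slice_duration
  wf(0)                                     # toffset
  wi(c(0L, 0L), 4)                          # glmax, glmin
  writeBin(raw(104L), con)                  # descrip + aux_file
  wi(c(0L, 1L), 2)                          # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                   # quaternions + qoffsets
  wf(c(pixdim[1], 0, 0, 0))                 # srow_x
  wf(c(0, pixdim[2], 0, 0))                 # srow_y
  wf(c(0, 0, pixdim[3], 0))                 # srow_z
  writeBin(raw(16L), con)                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                    # extension flag
  if (dt$what == "integer")
    writeBin(as.integer(as.vector(arr)), con, size = dt$size, endian = "little")
  else
    writeBin(as.double(as.vector(arr)), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a single-file NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file written by [write_nifti()] or any
#'   tool emitting plain single-file little-endian NIfTI-1.
#' @return list with `data` (numeric/integer array), `dim`, `pixdim` and
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L)
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  dim8 <- ri(40L, 2L, 8L)
  nd <- dim8[1]
  dims <- dim8[2:(1 + max(nd, 1L))]
  datatype <- ri(70L, 2L)
  dt <- .NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  pixdim <- rf(76L, 8L)[2:4]
  vox_offset <- rf(108L)
  scl <- rf(112L, 2L)
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  dim(data) <- dims
  list(data = data, dim = dims, pixdim = pixdim, datatype = datatype)
}

#' Read a CT volume from NIfTI
#'
#' Wraps [read_nifti()] into a [ct_volume()], rounding to integer HU and
#' clamping to the scanner range \[-1024, 3071\].
#'
#' @inheritParams read_nifti
#' @param pixel_area,slice_thickness voxel geometry overrides (mm^2, mm);
#'   derived from the file's pixdim when omitted.
#' @param phase,peep_label acquisition labels for the volume.
#' @return a [ct_volume()].
#' @export
read_ct_nifti <- function(path, pixel_area = NULL, slice_thickness = NULL,
                          phase = "end_expiration", peep_label = "low") {
  nii <- read_nifti(path)
  if (is.null(pixel_area)) pixel_area <- prod(nii$pixdim[1:2])
  if (is.null(slice_thickness)) slice_thickness <- nii$pixdim[3]
  hu <- pmin(pmax(round(nii$data), -1024), 3071)
  ct_volume(storage_int(hu), pixel_area, slice_thickness, phase, peep_label)
}
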