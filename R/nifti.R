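#' Minimal NIfTI-1 input/output
#'
#' Self-contained reader/writer for uncompressed single-file NIfTI-1 (.nii)
#' volumes, little-endian, supporting uint8/int16/int32/float32/float64 data.
#' This covers the package's image interchange needs (perfusion volumes and
#' integer territory atlases on a shared grid); it is not a general NIfTI
#' library (no .nii.gz, no extensions, no full quaternion handling — the
#' sform carries a diagonal voxel-scaling affine).
#'
#' @name nifti_io
NULL

NIFTI_TYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE)     # float64
)

#' Write a 3D array as NIfTI-1
#'
#' @param vol 3D numeric or integer array
#' @param path output path (.nii)
#' @param voxel_dim voxel size in mm, length 3
#' @param datatype one of "float32", "float64", "int16", "int32", "uint8";
#'   integer arrays default to int16, numeric to float32
#' @return the path, invisibly
#' @export
write_nifti <- function(vol, path, voxel_dim = c(1, 1, 1), datatype = NULL) {
  stopifnot(length(dim(vol)) == 3L, length(voxel_dim) == 3L)
  if (is.null(datatype)) {
    datatype <- if (is.integer(vol)) "int16" else "float32"
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 cf_stop("cf_format", "unsupported datatype '%s'", datatype))
  info <- NIFTI_TYPES[[as.character(code)]]
  bitpix <- info$size * 8L
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wint(348L, 4)                         # sizeof_hdr
  writeBin(raw(35), con)                # data_type[10], db_name[18], extents,
                                        # session_error, regular
  writeBin(as.raw(0L), con)             # dim_info
  wint(c(3L, dim(vol), 1L, 1L, 1L, 1L), 2)   # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2)         # intent_p1..3 (floats), intent_code
  wint(code, 2); wint(bitpix, 2); wint(0L, 2)        # datatype, bitpix, slice_start
  wflt(c(1, voxel_dim, 1, 1, 1, 1))     # pixdim[8] (qfac=1)
  wflt(352)                             # vox_offset
  wflt(1); wflt(0)                      # scl_slope, scl_inter
  wint(0L, 2); writeBin(as.raw(c(0L, 0L)), con)      # slice_end, slice_code, xyzt_units
  wflt(c(0, 0, 0, 0))                   # cal_max, cal_min, slice_duration, toffset
  wint(c(0L, 0L), 4)                    # glmax, glmin
  writeBin(raw(104), con)               # descrip[80] + aux_file[24]
  wint(c(0L, 1L), 2)                    # qform_code=0, sform_code=1
  wflt(c(0, 0, 0, 0, 0, 0))             # quatern b,c,d + qoffset x,y,z
  wflt(c(voxel_dim[1], 0, 0, 0))        # srow_x
  wflt(c(0, voxel_dim[2], 0, 0))        # srow_y
  wflt(c(0, 0, voxel_dim[3], 0))        # srow_z
  writeBin(raw(16), con)                # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)     # magic
  writeBin(raw(4), con)                 # extension flag
  if (info$what == "integer") {
    writeBin(as.integer(vol), con, size = info$size, endian = "little")
  } else {
    writeBin(as.numeric(vol), con, size = info$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to an uncompressed .nii file
#' @return list with `data` (3D array), `voxel_dim` (mm), `datatype_code`
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) cf_stop("cf_format", "truncated NIfTI header: %s", path)
  rint <- function(off, size, n = 1L, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  }
  rflt <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  }
  if (rint(0L, 4L) != 348L) cf_stop("cf_format", "bad NIfTI header size: %s", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) cf_stop("cf_format", "bad NIfTI magic: %s", path)
  dims <- rint(40L, 2L, 8L)
  ndim <- dims[1]
  if (ndim < 3L) dims <- c(ndim, dims[2:(1 + ndim)], rep(1L, 3 - ndim), dims[-(1:4)])
  shape <- dims[2:4]
  code <- rint(70L, 2L)
  info <- NIFTI_TYPES[[as.character(code)]]
  if (is.null(info)) cf_stop("cf_format", "unsupported NIfTI datatype %d", code)
  pixdim <- rflt(76L, 8L)[2:4]
  vox_offset <- rflt(108L)
  scl_slope <- rflt(112L); scl_inter <- rflt(116L)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(shape)
  dat <- readBin(con, info$what, n = n, size = info$size, endian = "little",
                 signed = info$signed)
  if (length(dat) < n) cf_stop("cf_format", "truncated NIfTI data: %s", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    dat <- dat * scl_slope + scl_inter
  }
  list(data = array(dat, dim = shape), voxel_dim = pixdim, datatype_code = code)
}
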