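# NIfTI-1 single-file (.nii / .nii.gz) reader and writer, little-endian,
# implemented over base R connections. Only what the pipeline needs: 3D
# volumes, common datatypes, scl_slope/scl_inter scaling, diagonal sform.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

#' Write a 3D volume as a NIfTI-1 file
#'
#' Voxels are stored as float64 so that a round-trip through
#' [read_nifti()] is bit-exact. The affine is diagonal, scaled by the
#' voxel spacing (sform code 1).
#'
#' @param vol a `volume_sample` or a 3D numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing mm voxel spacing (ignored when `vol` is a `volume_sample`).
#' @return the path, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, "volume_sample")) {
    spacing <- vol$spacing
    vox <- vol$voxels
  } else vox <- vol
  stopifnot(length(dim(vox)) == 3L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    b <- charToRaw(s)
    writeBin(c(b, raw(len - length(b))), con)
  }
  wi(348L, 4)                 # sizeof_hdr
  wc("", 10); wc("", 18)      # data_type, db_name
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3L, dim(vox), 1L, 1L, 1L, 1L), 2)       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)   # intent_p1..3, intent_code
  wi(64L, 2); wi(64L, 2)      # datatype float64, bitpix
  wi(0L, 2)                   # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                # pixdim[8]
  wf(352); wf(1); wf(0)       # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1); writeBin(as.raw(2L), con)  # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))           # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)            # glmax, glmin
  wc("synthetic volume", 80); wc("", 24)       # descrip, aux_file
  wi(0L, 2); wi(1L, 2)        # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))     # quatern b,c,d + qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0))  # srow_x
  wf(c(0, spacing[2], 0, 0))  # srow_y
  wf(c(0, 0, spacing[3], 0))  # srow_z
  wc("", 16); wc("n+1", 4)    # intent_name, magic
  writeBin(raw(4), con)       # header extension flag
  writeBin(as.numeric(vox), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports `.nii` and `.nii.gz`, both endiannesses, the common scalar
#' datatypes, and applies `scl_slope`/`scl_inter` when set. Only 3D images
#' (or higher-dimensional images whose trailing dims are singleton) are
#' accepted.
#'
#' @param path file path.
#' @return list with `voxels` (3D array), `spacing`, `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  con <- gzfile(path, "rb")  # transparently handles uncompressed files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file: ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  gi <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size,
                                       endian = endian)
  gf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], "double",
                                 n = n, size = 4L, endian = endian)
  dimv <- gi(40, 8, 2)
  ndim <- dimv[1]
  dims <- dimv[2:(1 + max(ndim, 1))]
  if (ndim < 3 || (ndim > 3 && prod(dims[4:ndim]) != 1))
    stop("unsupported format: only 3D NIfTI volumes are handled")
  dims <- dims[1:3]
  datatype <- gi(70, 1, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported format: NIfTI datatype ", datatype)
  pixdim <- gf(76, 8)
  vox_offset <- gf(108, 1)
  scl_slope <- gf(112, 1)
  scl_inter <- gf(116, 1)
  nvox <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI data in ", path)
  vals <- as.numeric(vals)
  if (datatype == 512L) vals[vals < 0] <- vals[vals < 0] + 65536
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(voxels = array(vals, dim = dims), spacing = abs(pixdim[2:4]),
       datatype = datatype)
}
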