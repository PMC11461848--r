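# Minimal DICOM slice-series support: explicit-VR little-endian parsing
# (plus implicit-VR fallback for the dataset), uncompressed single-frame
# grayscale slices, and a writer used to build synthetic fixtures. Slices
# are stacked along the normal of ImageOrientationPatient, ordered by the
# projection of ImagePositionPatient, ties broken by InstanceNumber.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_tag <- function(group, elem) sprintf("%04x,%04x", group, elem)

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_elements <- function(raw, start, explicit) {
  pos <- start
  n <- length(raw)
  out <- list()
  rd_u16 <- function(p) readBin(raw[p:(p + 1)], "integer", size = 2L,
                                signed = FALSE, endian = "little")
  rd_u32 <- function(p) {
    v <- readBin(raw[p:(p + 3)], "integer", size = 4L, endian = "little")
    if (v < 0) stop("unsupported format: undefined/huge DICOM element length")
    v
  }
  while (pos + 7 <= n) {
    group <- rd_u16(pos); elem <- rd_u16(pos + 2)
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[(pos + 4):(pos + 5)])
      if (vr %in% LONG_VRS) {
        len <- rd_u32(pos + 8); hdr <- 12L
      } else {
        len <- rd_u16(pos + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- rd_u32(pos + 4); hdr <- 8L
    }
    if (pos + hdr + len - 1 > n) stop("unsupported format: truncated DICOM element")
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1)] else raw(0)
    out[[dcm_tag(group, elem)]] <- list(vr = vr, bytes = body)
    pos <- pos + hdr + len
    if (group == 0x7fe0 && elem == 0x0010) break
  }
  list(elements = out, end = pos)
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(el$bytes), useBytes = TRUE))
}
dcm_num <- function(el) if (is.null(el)) NULL else
  as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
dcm_u16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", size = 2L, signed = FALSE, endian = "little")
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 200 || rawToChar(raw[129:132]) != "DICM")
    stop("unsupported format: ", path, " is not a DICOM part-10 file")
  # scan the file-meta group (always explicit VR) one element at a time
  pos <- 133L
  ts <- NULL
  rd_u16 <- function(p) readBin(raw[p:(p + 1)], "integer", size = 2L,
                                signed = FALSE, endian = "little")
  repeat {
    if (pos + 7 > length(raw)) break
    group <- rd_u16(pos)
    if (group != 0x0002) break
    elem <- rd_u16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4L,
                     endian = "little")
      hdr <- 12L
    } else {
      len <- rd_u16(pos + 6)
      hdr <- 8L
    }
    if (elem == 0x0010 && len > 0)
      ts <- trimws(gsub("\\x00", "", rawToChar(raw[(pos + hdr):(pos + hdr + len - 1)]),
                        useBytes = TRUE))
    pos <- pos + hdr + len
  }
  ts <- ts %||% TS_EXPLICIT_LE
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
    stop("unsupported format: transfer syntax ", ts)
  ds <- parse_dicom_elements(raw, pos, explicit = identical(ts, TS_EXPLICIT_LE))
  e <- ds$elements
  rows <- dcm_u16(e[["0028,0010"]]); cols <- dcm_u16(e[["0028,0011"]])
  bits <- dcm_u16(e[["0028,0100"]])
  pixrep <- if (!is.null(e[["0028,0103"]])) dcm_u16(e[["0028,0103"]]) else 0L
  px <- e[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("unsupported format: missing image data in ", path)
  vals <- if (bits == 8) {
    as.numeric(readBin(px$bytes, "integer", n = rows * cols, size = 1L,
                       signed = pixrep == 1L))
  } else {
    v <- readBin(px$bytes, "integer", n = rows * cols, size = 2L,
                 signed = TRUE, endian = "little")
    v <- as.numeric(v)
    if (pixrep == 0L) v[v < 0] <- v[v < 0] + 65536
    v
  }
  slope <- dcm_num(e[["0028,1053"]]) %||% 1
  inter <- dcm_num(e[["0028,1052"]]) %||% 0
  list(pixels = matrix(vals * slope + inter, nrow = rows, ncol = cols),
       position = dcm_num(e[["0020,0032"]]) %||% c(0, 0, 0),
       orientation = dcm_num(e[["0020,0037"]]) %||% c(1, 0, 0, 0, 1, 0),
       instance = dcm_num(e[["0020,0013"]]) %||% 0,
       pixel_spacing = dcm_num(e[["0028,0030"]]) %||% c(1, 1),
       slice_thickness = dcm_num(e[["0018,0050"]]) %||% 1)
}

#' Read a DICOM slice series from a directory
#'
#' All slices must share in-plane geometry and orientation. The stack is
#' ordered by the projection of ImagePositionPatient onto the slice normal,
#' with InstanceNumber breaking ties.
#'
#' @param dir directory containing one series of `.dcm`/DICOM files.
#' @return list with `voxels` (depth, height, width), `spacing`.
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("missing input: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("missing input: no files in ", dir)
  slices <- lapply(sort(files), read_dicom_file)
  geom <- vapply(slices, function(s)
    paste(nrow(s$pixels), ncol(s$pixels),
          paste(round(s$orientation, 6), collapse = ","), sep = "|"), "")
  if (length(unique(geom)) != 1)
    stop("inconsistent slice geometry across DICOM series")
  ori <- slices[[1]]$orientation
  normal <- c(ori[2] * ori[6] - ori[3] * ori[5],
              ori[3] * ori[4] - ori[1] * ori[6],
              ori[1] * ori[5] - ori[2] * ori[4])
  proj <- vapply(slices, function(s) sum(s$position * normal), 0)
  inst <- vapply(slices, function(s) s$instance[1], 0)
  ord <- order(proj, inst)
  slices <- slices[ord]
  k <- length(slices)
  rows <- nrow(slices[[1]]$pixels); cols <- ncol(slices[[1]]$pixels)
  vox <- array(0, dim = c(k, rows, cols))
  for (i in seq_len(k)) vox[i, , ] <- slices[[i]]$pixels
  dz <- if (k > 1) abs(diff(sort(proj)))[1] else slices[[1]]$slice_thickness
  if (!is.finite(dz) || dz == 0) dz <- slices[[1]]$slice_thickness
  list(voxels = vox, spacing = c(dz, slices[[1]]$pixel_spacing))
}

dcm_element <- function(group, elem, vr, bytes) {
  if (length(bytes) %% 2 == 1)
    bytes <- c(bytes, if (vr == "UI") as.raw(0) else charToRaw(" "))
  hdr <- c(writeBin(as.integer(group), raw(), size = 2L, endian = "little"),
           writeBin(as.integer(elem), raw(), size = 2L, endian = "little"),
           charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, raw(2),
      writeBin(length(bytes), raw(), size = 4L, endian = "little"), bytes)
  } else {
    c(hdr, writeBin(length(bytes), raw(), size = 2L, endian = "little"), bytes)
  }
}
dcm_el_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))

#' Write a volume as a synthetic DICOM slice series
#'
#' Emits one explicit-VR little-endian secondary-capture file per axial
#' slice, with 16-bit signed pixels (voxel values are rounded). Intended
#' for building small synthetic fixtures and round-trip tests.
#'
#' @param vol `volume_sample` or 3D array (depth, height, width).
#' @param dir output directory (created if needed).
#' @param spacing mm spacing triple when `vol` is a plain array.
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(vol, dir, spacing = c(1, 1, 1)) {
  if (inherits(vol, "volume_sample")) {
    spacing <- vol$spacing
    vox <- vol$voxels
  } else vox <- vol
  stopifnot(length(dim(vox)) == 3L)
  vals <- round(vox)
  if (any(vals < -32768 | vals > 32767))
    stop("voxel values out of int16 range for DICOM writer")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vox)
  for (z in seq_len(d[1])) {
    px <- writeBin(as.integer(vals[z, , ]), raw(), size = 2L, endian = "little")
    ds <- c(
      dcm_el_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      dcm_el_str(0x0008, 0x0018, "UI", sprintf("1.2.826.0.1.999999.%d", z)),
      dcm_el_str(0x0018, 0x0050, "DS", format(spacing[1])),
      dcm_el_str(0x0020, 0x0013, "IS", as.character(z)),
      dcm_el_str(0x0020, 0x0032, "DS",
                 sprintf("0\\0\\%s", format((z - 1) * spacing[1]))),
      dcm_el_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_element(0x0028, 0x0002, "US",
                  writeBin(1L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0010, "US",
                  writeBin(d[2], raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0011, "US",
                  writeBin(d[3], raw(), size = 2L, endian = "little")),
      dcm_el_str(0x0028, 0x0030, "DS",
                 sprintf("%s\\%s", format(spacing[2]), format(spacing[3]))),
      dcm_element(0x0028, 0x0100, "US",
                  writeBin(16L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0101, "US",
                  writeBin(16L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0102, "US",
                  writeBin(15L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028, 0x0103, "US",
                  writeBin(1L, raw(), size = 2L, endian = "little")),
      dcm_element(0x7fe0, 0x0010, "OW", px))
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_el_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE))
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta), raw(), size = 4L,
                                   endian = "little")), meta)
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", z)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(dir)
}
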