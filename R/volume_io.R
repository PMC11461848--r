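#' Labeled 3D volume container
#'
#' @param voxels 3D numeric array, indexed (depth, height, width), 0-based
#'   voxel semantics documented throughout as (z, y, x).
#' @param spacing mm spacing per axis (all > 0).
#' @param subject_id character id.
#' @param label integer class in `{0, 1, 2}` or `NA` when unknown.
#' @param provenance list recording source path / format.
#' @return object of class `volume_sample`.
#' @export
volume_sample <- function(voxels, spacing = c(1, 1, 1), subject_id = "s1",
                          label = NA_integer_, provenance = list()) {
  stopifnot(length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) stop("voxel values must be finite")
  if (any(spacing <= 0)) stop("spacing must be > 0 on each axis")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 subject_id = subject_id,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 provenance = provenance),
            class = "volume_sample")
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf("<volume_sample %s: %s voxels, spacing %s mm, label %s>\n",
              x$subject_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

#' Read a volume from NIfTI or a DICOM slice series
#'
#' @param path a `.nii`/`.nii.gz` file or a directory containing one DICOM
#'   series.
#' @param format `"auto"` (from the path), `"nifti"`, or `"dicom_series"`.
#' @param label optional integer class label to attach.
#' @return a `volume_sample`.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series"),
                        label = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("missing input: ", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else if
      (grepl("\\.nii(\\.gz)?$", path)) "nifti" else
        stop("unsupported format: cannot infer reader for ", path)
  raw <- switch(format,
    nifti = read_nifti(path),
    dicom_series = read_dicom_series(path))
  volume_sample(raw$voxels, spacing = raw$spacing,
                subject_id = basename(path), label = label,
                provenance = list(source = path, format = format))
}

# Trilinear resampling of a 3D array to a target shape, preserving the
# physical field of view (half-voxel aligned, clamped at the borders).
resample_trilinear <- function(vox, target) {
  din <- dim(vox)
  ax <- lapply(1:3, function(a) {
    src <- (seq_len(target[a]) - 0.5) * din[a] / target[a] - 0.5
    src <- pmin(pmax(src, 0), din[a] - 1)
    i0 <- floor(src)
    list(i0 = as.integer(i0) + 1L,
         i1 = as.integer(pmin(i0 + 1, din[a] - 1)) + 1L,
         f = src - i0)
  })
  g <- expand.grid(z = seq_len(target[1]), y = seq_len(target[2]),
                   x = seq_len(target[3]))
  out <- numeric(nrow(g))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    iz <- if (cz == 0) ax[[1]]$i0 else ax[[1]]$i1
    iy <- if (cy == 0) ax[[2]]$i0 else ax[[2]]$i1
    ix <- if (cx == 0) ax[[3]]$i0 else ax[[3]]$i1
    wz <- if (cz == 0) 1 - ax[[1]]$f else ax[[1]]$f
    wy <- if (cy == 0) 1 - ax[[2]]$f else ax[[2]]$f
    wx <- if (cx == 0) 1 - ax[[3]]$f else ax[[3]]$f
    w <- wz[g$z] * wy[g$y] * wx[g$x]
    out <- out + w * vox[cbind(iz[g$z], iy[g$y], ix[g$x])]
  }
  array(out, dim = target)
}

#' Preprocess a volume to the extractor input contract
#'
#' Trilinear-resamples to `target_shape` (default 56^3) and z-scores the
#' intensities over the whole volume (mean 0, sd 1). A constant-intensity
#' volume maps to all zeros instead of dividing by zero. Spacing is rescaled
#' so the physical extent is preserved.
#'
#' @param v a `volume_sample`.
#' @param target_shape voxel triple.
#' @return a preprocessed `volume_sample`.
#' @export
preprocess_volume <- function(v, target_shape = c(56L, 56L, 56L)) {
  stopifnot(inherits(v, "volume_sample"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0L))
    stop("target shape must be a positive voxel triple")
  vox <- v$voxels
  din <- dim(vox)
  if (!all(din == target_shape)) vox <- resample_trilinear(vox, target_shape)
  s <- sd(vox)
  vox <- if (!is.finite(s) || s < 1e-12) array(0, dim = target_shape)
         else (vox - mean(vox)) / s
  volume_sample(vox, spacing = v$spacing * din / target_shape,
                subject_id = v$subject_id, label = v$label,
                provenance = c(v$provenance, list(preprocessed = TRUE)))
}
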