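test_that("NIfTI volumes round-trip bit-exactly through the package writer", {
  set.seed(1)
  vox <- array(rnorm(10 * 12 * 14), dim = c(10, 12, 14))
  v <- volume_sample(vox, spacing = c(1.5, 0.8, 0.8), subject_id = "rt")
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_nifti(v, path)
    back <- read_nifti(path)
    expect_identical(back$voxels, vox)
    expect_equal(back$spacing, c(1.5, 0.8, 0.8), tolerance = 1e-6)
  }
})

test_that("package NIfTI output is readable by nibabel (independent oracle)", {
  set.seed(2)
  vox <- array(round(rnorm(6 * 7 * 8), 3), dim = c(6, 7, 8))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti(vox, path, spacing = c(2, 1, 1))
  script <- paste(
    "import nibabel, sys",
    sprintf("img = nibabel.load('%s')", path),
    "d = img.get_fdata()",
    "print(d.shape[0], d.shape[1], d.shape[2], '%.6f' % float(d.sum()))",
    sep = "; ")
  out <- tryCatch(system2("python", c("-c", shQuote(script)), stdout = TRUE,
                          stderr = TRUE),
                  warning = function(w) character(0),
                  error = function(e) character(0))
  fields <- strsplit(paste(out, collapse = " "), "\\s+")[[1]]
  expect_gte(length(fields), 4)
  expect_equal(as.integer(fields[1:3]), c(6L, 7L, 8L))
  expect_equal(as.numeric(fields[4]), sum(vox), tolerance = 1e-5)
})

test_that("DICOM series round-trip preserves integer voxels and order", {
  set.seed(3)
  vox <- array(sample(-500:500, 5 * 8 * 9, replace = TRUE), dim = c(5, 8, 9))
  dir <- tempfile("dcm")
  write_dicom_series(vox, dir, spacing = c(2.5, 1, 1))
  back <- read_dicom_series(dir)
  expect_equal(dim(back$voxels), c(5L, 8L, 9L)) # depth = slice count
  expect_identical(back$voxels, vox + 0) # numeric but value-exact
  expect_equal(back$spacing, c(2.5, 1, 1))

  v <- read_volume(dir)
  expect_s3_class(v, "volume_sample")
  expect_equal(v$provenance$format, "dicom_series")
})

test_that("inconsistent slice geometry and missing inputs raise errors", {
  dir <- tempfile("mix")
  write_dicom_series(array(1, dim = c(2, 6, 6)), dir)
  write_dicom_series(array(1, dim = c(2, 4, 4)), tempdir0 <- tempfile())
  file.copy(list.files(tempdir0, full.names = TRUE)[1],
            file.path(dir, "odd_slice.dcm"))
  expect_error(read_dicom_series(dir), "inconsistent slice geometry")
  expect_error(read_volume(tempfile("nope")), "missing input")
  bad <- tempfile(fileext = ".xyz")
  writeLines("x", bad)
  expect_error(read_volume(bad), "unsupported format")
})

test_that("preprocess_volume enforces the 56^3 contract and normalization", {
  set.seed(4)
  v <- volume_sample(array(rnorm(20 * 24 * 18), dim = c(20, 24, 18)))
  out <- preprocess_volume(v) # default target
  expect_equal(dim(out$voxels), c(56L, 56L, 56L))
  expect_lt(abs(mean(out$voxels)), 1e-6)
  expect_lt(abs(sd(out$voxels) - 1), 1e-6)

  const <- preprocess_volume(volume_sample(array(7, dim = c(10, 10, 10))),
                             c(8L, 8L, 8L))
  expect_true(all(const$voxels == 0))

  expect_error(preprocess_volume(v, c(0L, 8L, 8L)), "positive")
})

test_that("resampling preserves monotone gradients and is idempotent", {
  ramp <- array(rep(seq(0, 1, length.out = 30), times = 12 * 12),
                dim = c(30, 12, 12))
  v <- preprocess_volume(volume_sample(ramp), c(17L, 9L, 9L))
  profile <- v$voxels[, 5, 5]
  expect_true(all(diff(profile) > 0))

  again <- preprocess_volume(v, c(17L, 9L, 9L))
  expect_equal(again$voxels, v$voxels, tolerance = 1e-12)
})
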