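test_that("NIfTI write/read round-trips values and spacing exactly", {
  p <- generate_phantom(toy_phantom_spec(seed = 4))
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(p$volume, tmp)
  back <- read_volume(tmp)
  expect_identical(back$values, p$volume$values)
  expect_equal(back$spacing, p$volume$spacing, tolerance = 1e-6)

  tmpm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(p$labels, tmpm)
  backm <- read_mask(tmpm)
  expect_identical(backm$labels, p$labels$labels)
})

test_that("constructors reject invalid spacing", {
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(label_mask(array(7L, c(2, 2, 2)), c(1, 1, 1)), "codes")
})

test_that("resampling a constant volume preserves the constant", {
  v <- ct_volume(array(450, c(20, 20, 20)), c(1, 1, 1))
  r <- resample(v, c(0.9, 0.66, 0.66))
  expect_true(all(abs(r$values - 450) < 1e-12))
  expect_equal(r$spacing, c(0.9, 0.66, 0.66))
})

test_that("output shape follows round(extent / target) with ties to even", {
  v <- ct_volume(array(rnorm(40 * 40 * 40), c(40, 40, 40)), c(1, 1, 1))
  r <- resample(v, c(0.9, 0.66, 0.66))
  # independent shape computation from physical extents
  expect_identical(dim(r$values),
                   as.integer(c(round(40 / 0.9), round(40 / 0.66),
                                round(40 / 0.66))))
})

test_that("label resampling is nearest-neighbour and closed over codes", {
  p <- generate_phantom(toy_phantom_spec(seed = 2))
  lab <- p$labels$labels
  lab[1, 1, 1] <- 255L     # ignore label must survive
  m <- label_mask(lab, p$labels$spacing)
  r <- resample(m, c(1.2, 1, 1))
  expect_true(all(unique(as.vector(r$labels)) %in%
                    unique(as.vector(lab))))
  expect_true(is.integer(r$labels))
})

test_that("resampling to own spacing short-circuits to identity", {
  v <- ct_volume(array(rnorm(1000), c(10, 10, 10)), c(0.9, 0.66, 0.66))
  r <- resample(v, c(0.9, 0.66, 0.66))
  expect_identical(r$values, v$values)
  expect_error(resample(ct_volume(array(c(NA, rnorm(7)), c(2, 2, 2)),
                                  c(1, 1, 1)), c(2, 2, 2)), "non-finite")
})

test_that("DICOM series read applies rescale and sorts slices", {
  dir <- withr::local_tempdir()
  # stored value 1474 with slope 1, intercept -1024 must read as 450 HU
  write_test_dicom_series(dir, hu_values = c(450, 60, 200), rows = 6L,
                          cols = 5L, pixel_spacing = c(0.7, 0.5))
  # shuffle file names so sorting must come from slice positions
  files <- list.files(dir, full.names = TRUE)
  shuffled <- file.path(dir, c("z.dcm", "a.dcm", "m.dcm"))
  file.rename(files, shuffled)
  vol <- read_volume(dir)
  expect_identical(dim(vol$values), c(3L, 6L, 5L))
  expect_equal(vol$spacing, c(0.9, 0.7, 0.5), tolerance = 1e-9)
  expect_true(all(vol$values[1, , ] == 450))
  expect_true(all(vol$values[2, , ] == 60))
  expect_true(all(vol$values[3, , ] == 200))
})

test_that("inconsistent or underspecified DICOM series are rejected", {
  dir <- withr::local_tempdir()
  write_test_dicom_series(dir, hu_values = c(100, 100))
  write_test_dicom(file.path(dir, "bad.dcm"),
                   matrix(0, 8, 8), 8L, 8L,
                   pixel_spacing = c(1.5, 1.5),
                   position = c(0, 0, 1.8))
  expect_error(read_volume(dir), "PixelSpacing differs")

  dir2 <- withr::local_tempdir()
  write_test_dicom(file.path(dir2, "nospacing.dcm"),
                   matrix(0, 4, 4), 4L, 4L, drop_pixel_spacing = TRUE)
  expect_error(read_volume(dir2), "refusing to assume")

  dir3 <- withr::local_tempdir()
  write_test_dicom_series(dir3, hu_values = c(0, 0, 0))
  # non-uniform slice gap: move the last slice
  write_test_dicom(file.path(dir3, "slice03.dcm"), matrix(1024, 8, 8),
                   8L, 8L, position = c(0, 0, 5))
  expect_error(read_volume(dir3), "non-uniform")
})
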