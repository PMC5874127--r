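test_that("DICOM series round-trips pixels, spacing and thickness", {
  set.seed(11)
  slices <- lapply(1:3, function(i) {
    matrix(round(rnorm(32 * 32, mean = 40, sd = 10)), 32, 32)
  })
  dir <- withr::local_tempdir()
  write_test_dicom_series(dir, slices)
  st <- read_image_stack(dir, "dicom_series")
  expect_equal(n_scans(st), 3)
  for (i in 1:3) expect_equal(scan_image(st, i), slices[[i]])
  expect_equal(st$pixel_spacing_mm, c(0.703125, 0.703125))
  expect_equal(st$slice_thickness_mm, 0.625)
})

test_that("implicit-VR DICOM reads identically to explicit", {
  px <- matrix(round(rnorm(16 * 16, 0, 20)), 16, 16)
  f1 <- withr::local_tempfile(fileext = ".dcm")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(f1, px, implicit = FALSE)
  write_test_dicom(f2, px, implicit = TRUE)
  expect_equal(read_dicom_slice(f1)$pixels, px)
  expect_equal(read_dicom_slice(f2)$pixels, px)
})

test_that("mixed matrix sizes across a series is a format error", {
  dir <- withr::local_tempdir()
  write_test_dicom(file.path(dir, "a.dcm"), matrix(0, 16, 16))
  write_test_dicom(file.path(dir, "b.dcm"), matrix(0, 32, 32))
  expect_error(read_image_stack(dir, "dicom_series"), "mixed matrix sizes")
})

test_that("missing spacing falls back to configuration or errors", {
  dir <- withr::local_tempdir()
  write_test_dicom_series(dir, list(matrix(0, 16, 16)), omit_spacing = TRUE)
  expect_error(read_image_stack(dir, "dicom_series"), "PixelSpacing")
  st <- read_image_stack(dir, "dicom_series", pixel_spacing_mm = 360 / 512)
  expect_equal(st$pixel_spacing_mm, c(0.703125, 0.703125))
})

test_that("array stack text format round-trips at full precision", {
  set.seed(3)
  st <- image_stack(array(rnorm(8 * 8 * 10), dim = c(8, 8, 10)),
                    360 / 512, 0.625, labels = list(condition = "x"))
  f <- withr::local_tempfile(fileext = ".stk")
  write_array_stack(st, f)
  back <- read_array_stack(f)
  expect_identical(back$pixels, st$pixels)
  expect_identical(back$pixel_spacing_mm, st$pixel_spacing_mm)
  expect_identical(back$slice_thickness_mm, st$slice_thickness_mm)
})

test_that("multi-page TIFF stacks are read in page order", {
  pages <- list(matrix(seq(0, 1, length.out = 64), 8, 8),
                matrix(seq(1, 0, length.out = 64), 8, 8))
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 32L)
  st <- read_image_stack(f, "tiff_stack", pixel_spacing_mm = 0.5)
  expect_equal(n_scans(st), 2)
  expect_equal(scan_image(st, 1), pages[[1]], tolerance = 1e-6)
  expect_equal(scan_image(st, 2), pages[[2]], tolerance = 1e-6)
  expect_error(read_image_stack(f, "tiff_stack"), "pixel_spacing_mm")
})

test_that("reformat averages consecutive thin slices and scales thickness", {
  one <- matrix(rnorm(16 * 16), 16, 16)
  st <- image_stack(array(rep(one, 4), dim = c(16, 16, 4)), 0.7, 0.625)
  thick <- reformat_stack(st, 4)
  expect_equal(n_scans(thick), 1)
  expect_equal(scan_image(thick, 1), one)
  expect_equal(thick$slice_thickness_mm, 2.5)
  expect_identical(reformat_stack(st, 1), st)
  expect_error(reformat_stack(st, 3), "remainder 1")
})

test_that("reformat commutes with scaling and reduces noise variance", {
  set.seed(21)
  st <- image_stack(array(rnorm(24 * 24 * 8, sd = 10), dim = c(24, 24, 8)),
                    0.7, 0.625)
  scaled <- image_stack(st$pixels * 3.7, 0.7, 0.625)
  expect_equal(reformat_stack(scaled, 4)$pixels,
               reformat_stack(st, 4)$pixels * 3.7)
  # variance of the mean of group_size independent slices is sigma^2 / 4
  big <- image_stack(array(rnorm(32 * 32 * 400, sd = 10),
                           dim = c(32, 32, 400)), 0.7, 0.625)
  thick <- reformat_stack(big, 4)
  expect_equal(var(as.vector(thick$pixels)), 25, tolerance = 0.05)
})

test_that("curve CSV writes a header plus one row per record and round-trips", {
  tab <- data.frame(condition = "fbp", ring_radius_px = 50,
                    axis = "horizontal",
                    frequency_per_mm = c(0, 1 / (16 * 0.703125)),
                    nps_hu2mm2 = c(49.4384765625, pi))
  f <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(tab, f)
  expect_length(readLines(f), nrow(tab) + 1)
  expect_equal(read_curves_csv(f), tab)
  expect_error(write_curves_csv(tab[0, ], f), "nonempty")
})

test_that("2D NPS exports to float TIFF with sidecar and reads back", {
  set.seed(5)
  nps <- nps2d_from_patches(replicate(20, matrix(rnorm(256, 0, 10), 16, 16),
                                      simplify = FALSE), 0.703125)
  f <- withr::local_tempfile(fileext = ".tif")
  write_nps2d_tiff(nps, f)
  expect_true(file.exists(paste0(f, ".axes.txt")))
  back <- read_nps2d_tiff(f)
  expect_equal(back$power, nps$power, tolerance = 1e-6)
  expect_equal(back$fx, nps$fx)
  expect_equal(back$fy, nps$fy)
})
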