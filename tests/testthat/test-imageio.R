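test_that("NIfTI round-trip preserves values, geometry and units", {
  set.seed(42)
  img <- image3d(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                 spacing_mm = c(1.2, 1.2, 3), origin_mm = c(-10, 4.5, 22),
                 units = "SUV")
  path <- tempfile(fileext = ".nii.gz")
  write_image(img, path)
  back <- read_image(path)
  expect_lt(max(abs(back$values - img$values)), 1e-5)
  expect_equal(back$spacing_mm, img$spacing_mm, tolerance = 1e-6)
  expect_equal(back$origin_mm, img$origin_mm, tolerance = 1e-6)
  expect_equal(back$units, "SUV")
})

test_that("masks are written as unsigned 8-bit, images as float", {
  mask <- image3d(array(c(0, 1), c(4, 4, 4)), spacing_mm = c(4, 4, 4))
  pm <- tempfile(fileext = ".nii.gz")
  write_image(mask, pm)
  expect_equal(RNifti::niftiHeader(pm)$datatype, 2L)  # NIfTI uint8
  img <- image3d(array(rnorm(64), c(4, 4, 4)), units = "HU")
  pf <- tempfile(fileext = ".nii.gz")
  write_image(img, pf)
  expect_equal(RNifti::niftiHeader(pf)$datatype, 16L)  # NIfTI float32
  expect_lt(max(abs(read_image(pm)$values - mask$values)), 1e-7)
})

test_that("I/O contracts are enforced", {
  img <- image3d(array(0, c(4, 4, 4)))
  path <- tempfile(fileext = ".nii.gz")
  write_image(img, path)
  expect_error(write_image(img, path), "overwrite")
  expect_silent(write_image(img, path, overwrite = TRUE))
  expect_error(read_image(tempfile(fileext = ".nii.gz")), "exist")
  # 4-D payloads are rejected
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), p4)
  expect_error(read_image(p4), "3-D")
  # empty / non-3-D arrays cannot become images
  expect_error(image3d(array(0, c(4, 4))), "3-D")
  expect_error(image3d(numeric(0)), "3-D")
})

test_that("body-weight SUV conversion matches hand arithmetic", {
  conc <- image3d(array(5000, c(4, 4, 4)), units = "Bq_per_mL")
  suv0 <- activity_to_suv(conc, weight_kg = 70, injected_mbq = 210,
                          minutes_post_injection = 0)
  expect_equal(suv0$values[1], 5000 * 70000 / 210e6, tolerance = 1e-12)
  expect_equal(suv0$units, "SUV")
  # one half-life of decay doubles the SUV
  suv1 <- activity_to_suv(conc, 70, 210, minutes_post_injection = 109.77,
                          half_life_min = 109.77)
  expect_equal(suv1$values[1], 2 * suv0$values[1], tolerance = 1e-9)
  # zero concentration maps to zero
  zero <- activity_to_suv(image3d(array(0, c(4, 4, 4)),
                                  units = "Bq_per_mL"), 70, 210)
  expect_true(all(zero$values == 0))
  expect_error(activity_to_suv(conc, -70, 210), "positive")
  expect_error(activity_to_suv(suv0, 70, 210), "Bq_per_mL")
})
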