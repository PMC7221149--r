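test_that("rigid transform algebra is exact", {
  t1 <- rigid_transform(c(3, -2, 5), c(5, 3, -4), c(10, -20, 5))
  # matrix round-trip
  back <- petoverlap:::transform_from_matrix(transform_matrix(t1),
                                             c(10, -20, 5))
  expect_equal(back$rotation_deg, t1$rotation_deg, tolerance = 1e-10)
  expect_equal(back$translation_mm, t1$translation_mm, tolerance = 1e-10)
  # composition with the inverse is the identity
  comp <- compose_transforms(t1, invert_transform(t1))
  expect_lt(max(abs(transform_matrix(comp) - diag(4))), 1e-9)
  # identity correction leaves the base unchanged
  id <- rigid_transform()
  same <- compose_transforms(id, t1)
  expect_equal(transform_matrix(same), transform_matrix(t1),
               tolerance = 1e-12)
  # pure translations add
  net <- compose_transforms(rigid_transform(translation_mm = c(1, 0, 0)),
                            rigid_transform(translation_mm = c(2, 0, 0)))
  expect_equal(net$translation_mm, c(3, 0, 0), tolerance = 1e-12)
  expect_equal(net$rotation_deg, c(0, 0, 0), tolerance = 1e-12)
  # rotation determinant is +1
  expect_equal(det(transform_matrix(t1)[1:3, 1:3]), 1, tolerance = 1e-12)
})

test_that("target registration error has its closed forms", {
  grid_img <- image3d(array(0, c(10, 10, 10)), spacing_mm = c(4, 4, 4))
  roi <- array(FALSE, c(10, 10, 10))
  roi[4:6, 4:6, 4:6] <- TRUE
  truth <- rigid_transform(c(1, 2, -1), c(3, -2, 5))
  expect_equal(registration_error(truth, truth, roi, grid_img), 0)
  # a pure 2 mm translation discrepancy gives TRE = 2 mm everywhere
  est <- rigid_transform(c(1, 2, -1), c(3, -2, 5) + c(2, 0, 0))
  expect_equal(registration_error(truth, est, roi, grid_img), 2,
               tolerance = 1e-9)
  # small-angle rotation error grows with distance from the center
  rot_err <- rigid_transform(c(0, 0, 1))
  near <- far <- array(FALSE, c(10, 10, 10))
  near[5:6, 5:6, 5:6] <- TRUE
  far[9:10, 9:10, 5:6] <- TRUE
  centered <- image3d(array(0, c(10, 10, 10)), spacing_mm = c(4, 4, 4),
                      origin_mm = -c(18, 18, 18))
  expect_gt(registration_error(rigid_transform(), rot_err, far, centered),
            registration_error(rigid_transform(), rot_err, near, centered))
  expect_error(registration_error(truth, est, array(FALSE, c(10, 10, 10)),
                                  grid_img), "empty")
})

test_that("transform JSON files round-trip and import 4x4 matrices", {
  t1 <- rigid_transform(c(-2, 0.5, 3), c(1.5, -7, 2), c(0, 10, -5))
  path <- tempfile(fileext = ".json")
  write_transform(t1, path)
  back <- read_transform(path)
  expect_equal(back$rotation_deg, t1$rotation_deg, tolerance = 1e-9)
  expect_equal(back$translation_mm, t1$translation_mm, tolerance = 1e-9)
  expect_equal(back$center_mm, t1$center_mm)
  # matrix-only import
  jsonlite::write_json(list(matrix = transform_matrix(t1)),
                       path, digits = NA)
  m <- read_transform(path)
  expect_equal(transform_matrix(m), transform_matrix(t1),
               tolerance = 1e-8)
  jsonlite::write_json(list(foo = 1), path, auto_unbox = TRUE)
  expect_error(read_transform(path), "transform")
})
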