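test_that("resampling through transforms honours its contracts", {
  set.seed(7)
  img <- image3d(array(rnorm(16^3, 100, 10), c(16, 16, 16)),
                 spacing_mm = c(2, 2, 2), units = "HU")
  # identity transform on the same grid leaves values unchanged
  out <- apply_transform(img, rigid_transform(), petoverlap:::grid_of(img))
  expect_lt(max(abs(out$values - img$values)), 1e-9)
  # masks must use nearest-neighbour
  mask <- image3d(array(c(0, 1), c(16, 16, 16)), spacing_mm = c(2, 2, 2))
  expect_error(apply_transform(mask, rigid_transform(),
                               petoverlap:::grid_of(mask), "linear"),
               "nearest")
  # a shifted binary mask conserves voxel count within 2%
  blob <- array(FALSE, c(16, 16, 16))
  blob[6:11, 6:11, 6:11] <- TRUE
  bimg <- image3d(blob + 0, spacing_mm = c(2, 2, 2))
  shifted <- apply_transform(bimg, rigid_transform(translation_mm =
                                                     c(5, 0, 0)),
                             petoverlap:::grid_of(bimg), "nearest")
  expect_lt(abs(sum(shifted$values) - sum(blob)) / sum(blob), 0.02)
  # out-of-field voxels take the configured default
  far <- apply_transform(img, rigid_transform(translation_mm =
                                                c(100, 0, 0)),
                         petoverlap:::grid_of(img))
  expect_true(any(far$values == -1000))
})

test_that("center-of-mass initialization recovers pure shifts", {
  set.seed(11)
  arr <- array(0, c(24, 24, 24))
  arr[8:14, 10:16, 9:15] <- 500
  img <- image3d(arr, spacing_mm = c(2, 2, 2), units = "HU")
  # identical images give a near-zero translation
  t0 <- center_of_mass_transform(img, img)
  expect_lt(max(abs(t0$translation_mm)), 1e-6)
  # image vs itself shifted by 6 mm along x
  moved <- apply_transform(img, rigid_transform(translation_mm =
                                                  c(-6, 0, 0)),
                           petoverlap:::grid_of(img))
  t1 <- center_of_mass_transform(img, moved)
  expect_equal(t1$translation_mm[1], 6, tolerance = 0.5)
  expect_lt(max(abs(t1$translation_mm[2:3])), 0.5)
  expect_error(center_of_mass_transform(
    image3d(array(0, c(8, 8, 8)), units = "SUV"), img), "mass")
})

test_that("rigid MI registration recovers phantom misalignments", {
  p <- coarse_ct_params(misalign_translation_mm = c(5, 3, -4),
                        misalign_rotation_deg = c(3, 0, 2))
  case <- generate_case(p, seed = 31)
  init <- center_of_mass_transform(case$baseline$ct, case$recurrence$ct)
  reg <- register_rigid_mi(case$baseline$ct, case$recurrence$ct, init)
  expect_true(reg$converged)
  tre <- registration_error(case$truth$true_transform, reg$transform,
                            case$truth$vt_mask, case$baseline$pet)
  expect_lt(tre, 2)
  expect_lt(max(abs(reg$transform$translation_mm -
                      case$truth$true_transform$translation_mm)), 1.5)
  # the metric value never decreases across accepted steps in a level
  for (tr in reg$trace) expect_true(all(diff(tr) >= -1e-12))
  # moving = fixed with identity init stays at the identity
  reg0 <- register_rigid_mi(case$baseline$ct, case$baseline$ct,
                            rigid_transform(center_mm =
                                              init$center_mm))
  expect_lte(max(abs(reg0$transform$translation_mm)), 0.5 + 1e-6)
  expect_lte(max(abs(reg0$transform$rotation_deg)), 0.5 + 1e-6)
  # determinism: repeated runs give the same transform
  reg2 <- register_rigid_mi(case$baseline$ct, case$recurrence$ct, init)
  expect_identical(reg$transform, reg2$transform)
})
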