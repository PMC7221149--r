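test_that("phantom parameter invariants are validated", {
  expect_error(phantom_params(suv_background = 6, suv_tumor_low = 5),
               "ordered")
  expect_error(phantom_params(v1_fraction = 1.2), "v1_fraction")
  expect_error(phantom_params(overlap_target_x = 1.5), "0, 1")
  expect_error(phantom_params(vt_target_cc = -1), "positive")
  expect_error(phantom_params(grid_shape = c(8, 96, 96)), "16")
})

test_that("anatomy is deterministic with disjoint labels and a fillable bladder", {
  p <- coarse_ct_params()
  a1 <- build_anatomy(p, seed = 3)
  a2 <- build_anatomy(p, seed = 3)
  expect_identical(a1$labels$values, a2$labels$values)
  lab <- a1$labels$values
  for (l in 1:5) expect_gt(sum(lab == l), 0)  # every structure present
  # bladder filling: recurrence volume scaled by 1 + delta within 5%
  p5 <- coarse_ct_params(bladder_fill_delta = 0.5)
  nb_base <- sum(build_anatomy(p5, seed = 3)$labels$values == 3)
  nb_rec <- sum(build_anatomy(p5, seed = 3,
                              timepoint = "recurrence")$labels$values == 3)
  expect_lt(abs(nb_rec / nb_base - 1.5), 0.075)
})

test_that("ground truth hits its volume and overlap targets", {
  case <- generate_case(phantom_params(), seed = 5, materialize = "truth")
  tr <- case$truth
  expect_lt(abs(tr$vt_cc - 41.9) / 41.9, 0.2)
  expect_lt(abs(tr$v1_cc - 0.43 * tr$vt_cc) / (0.43 * tr$vt_cc), 0.2)
  expect_true(all(tr$vt_mask[tr$v1_mask]))          # V1 inside VT
  expect_false(any(tr$vt_mask & tr$bladder_exclusion))
  expect_true(abs(tr$achieved_x - 0.70) <= 0.02)
  expect_true(abs(tr$achieved_y - 0.77) <= 0.02)
  # identical seeds give identical cases
  again <- generate_case(phantom_params(), seed = 5, materialize = "truth")
  expect_identical(tr$v2_mask, again$truth$v2_mask)
})

test_that("recurrence planting covers the containment and disjoint corners", {
  base <- phantom_params()
  cal <- petoverlap:::case_geometry(base, 9)
  v1 <- petoverlap:::carve_v1(cal$vt_mask, petoverlap:::pet_grid(base),
                              base$v1_fraction, cal$shapes)
  truth0 <- list(vt_mask = cal$vt_mask, v1_mask = v1, shapes = cal$shapes,
                 bladder_exclusion = cal$bladder_exclusion)
  # X = 1 with Y = |V1|/|V2| forces V2 to contain V1 entirely
  n1 <- sum(v1)
  pc <- base
  pc$overlap_target_x <- 1
  pc$overlap_target_y <- n1 / round(1.3 * n1)
  contain <- plant_recurrence(truth0, pc)
  expect_true(all(contain$v2_mask[v1]))
  # X = 0, Y = 0 gives disjoint masks of the target volume
  pd <- base
  pd$overlap_target_x <- 0
  pd$overlap_target_y <- 0
  disj <- plant_recurrence(truth0, pd)
  expect_equal(sum(disj$v2_mask & v1), 0)
  expect_lt(abs(sum(disj$v2_mask) * 0.064 - base$v2_target_cc), 0.5)
  # one-sided zero targets are infeasible
  pi_ <- base
  pi_$overlap_target_x <- 0.5
  pi_$overlap_target_y <- 0
  expect_error(plant_recurrence(truth0, pi_), "infeasible")
})

test_that("noise-free blur-free synthesis reproduces the ideal uptake map", {
  p <- phantom_params(class_sd = 0, psf_fwhm_mm = 0)
  cal <- petoverlap:::case_geometry(p, 4)
  v1 <- petoverlap:::carve_v1(cal$vt_mask, petoverlap:::pet_grid(p),
                              p$v1_fraction, cal$shapes)
  masks <- c(petoverlap:::pet_masks(p, cal$shapes, "baseline"),
             list(vt = cal$vt_mask, v1 = v1))
  pet <- synthesize_pet(masks, p, seed = 1, "baseline")
  expect_true(all(pet$values[v1] == p$suv_tumor_high))
  expect_true(all(pet$values[cal$vt_mask & !v1] == p$suv_tumor_low))
  expect_true(all(pet$values[masks$bladder] == p$suv_bladder))
  bg <- masks$body & !cal$vt_mask & !masks$bladder
  expect_true(all(pet$values[bg] == p$suv_background))
  # seeded noise is bit-reproducible
  pn <- phantom_params()
  i1 <- synthesize_pet(masks, pn, seed = 8, "baseline")
  i2 <- synthesize_pet(masks, pn, seed = 8, "baseline")
  expect_identical(i1$values, i2$values)
  expect_error(synthesize_pet(masks, phantom_params(psf_fwhm_mm = -2),
                              seed = 1), ">= 0")
})

test_that("misalignment moves the tumor by the prescribed offset", {
  p <- phantom_params(class_sd = 0)
  cal <- petoverlap:::case_geometry(p, 4)
  masks <- c(petoverlap:::pet_masks(p, cal$shapes, "baseline"),
             list(vt = cal$vt_mask,
                  v1 = petoverlap:::carve_v1(cal$vt_mask,
                                             petoverlap:::pet_grid(p),
                                             p$v1_fraction, cal$shapes)))
  pet <- synthesize_pet(masks, p, seed = 1, "baseline")
  # identity transform: unchanged up to interpolation
  same <- misalign(pet, rigid_transform())
  expect_lt(max(abs(same$values - pet$values)), 1e-6)
  # 5 mm translation moves the uptake centroid by about 5 mm
  tt <- rigid_transform(translation_mm = c(5, 0, 0))
  moved <- misalign(pet, tt)
  centroid <- function(img) {
    w <- pmax(img$values - 3, 0)  # tumor-weighted
    idx <- which(w > 0, arr.ind = TRUE)
    colSums(idx * w[w > 0]) / sum(w[w > 0])
  }
  shift_vox <- as.numeric(centroid(moved) - centroid(pet))
  expect_equal(shift_vox[1] * 4, -5, tolerance = 1)  # acquired frame
  expect_lt(max(abs(shift_vox[2:3] * 4)), 1)
})

test_that("cohorts reproduce the configured composition and distributions", {
  flags <- generate_cohort(21, list(v2_gt_v1_fraction = 1 / 3), seed = 2,
                           materialize = "truth")
  expect_equal(sum(flags$manifest$v2_gt_v1), 7)
  expect_equal(nrow(flags$manifest), 21)
  # the flag matches the drawn target composition case by case
  expect_equal(flags$manifest$v2_gt_v1, flags$manifest$v2_gt_v1_target)
  # single-case cohorts are reproducible
  c1 <- generate_cohort(1, seed = 9, materialize = "truth")
  c2 <- generate_cohort(1, seed = 9, materialize = "truth")
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$cases[[1]]$truth$v2_mask, c2$cases[[1]]$truth$v2_mask)
  expect_error(generate_cohort(0), "positive")
})
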