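test_that("the four overlap indices match their formulas on counted masks", {
  # counts chosen so X and Y are exact decimals
  mk <- masks_from_xy(0.70, 0.77)
  ov <- overlap_metrics(mk$v1, mk$v2, c(4, 4, 4))
  expect_equal(round(ov$dice, 2), 0.73)
  expect_equal(round(ov$of, 2), 0.77)
  expect_equal(ov$x, 0.70, tolerance = 1e-12)
  expect_equal(ov$y, 0.77, tolerance = 1e-12)
  expect_false(ov$v2_gt_v1)
  # identical masks: everything is 1
  a <- array(c(TRUE, FALSE), c(6, 6, 6))
  same <- overlap_metrics(a, a, c(1, 1, 1))
  expect_equal(c(same$dice, same$of, same$x, same$y), rep(1, 4))
  # disjoint masks: everything is 0
  b <- !a
  disj <- overlap_metrics(a, b, c(1, 1, 1))
  expect_equal(c(disj$dice, disj$of, disj$x, disj$y), rep(0, 4))
  expect_error(overlap_metrics(a, array(FALSE, c(6, 6, 6)), c(1, 1, 1)),
               "empty")
  expect_error(overlap_metrics(a, a[1:3, , ], c(1, 1, 1)), "grids")
})

test_that("index identities and the brute-force oracle hold on random masks", {
  set.seed(99)
  for (i in 1:60) {
    mk <- random_mask_pair()
    ov <- overlap_metrics(mk$a, mk$b, c(2, 2, 2))
    bf <- brute_force_overlap(mk$a, mk$b, c(2, 2, 2))
    for (f in names(bf))
      expect_equal(ov[[f]], bf[[f]], tolerance = 1e-12)
    # OF = max(X, Y); Dice = harmonic mean of X and Y; Dice <= OF
    expect_equal(ov$of, max(ov$x, ov$y), tolerance = 1e-12)
    if (ov$x > 0)
      expect_equal(ov$dice, 2 / (1 / ov$x + 1 / ov$y), tolerance = 1e-12)
    expect_lte(ov$dice, ov$of + 1e-12)
    expect_true(all(c(ov$dice, ov$of, ov$x, ov$y) >= 0 &
                      c(ov$dice, ov$of, ov$x, ov$y) <= 1))
    # symmetry: Dice symmetric, X and Y swap with the masks
    rev <- overlap_metrics(mk$b, mk$a, c(2, 2, 2))
    expect_equal(ov$dice, rev$dice, tolerance = 1e-12)
    expect_equal(ov$x, rev$y, tolerance = 1e-12)
  }
})

test_that("concordance bands follow the rounded banding rule", {
  expect_equal(classify_concordance(0.72), "good")
  expect_equal(classify_concordance(0.205), "very low")  # rounds to 0.20
  expect_equal(classify_concordance(0.21), "low")
  expect_equal(classify_concordance(0.55), "moderate")
  expect_equal(classify_concordance(1.0), "very good")
  expect_equal(classify_concordance(0), "very low")
  expect_error(classify_concordance(1.2), "\\[0, 1\\]")
})

test_that("SUV statistics match direct enumeration", {
  # uniform SUV 5 over 10 cc
  vox_cc <- 0.064
  n <- round(10 / vox_cc)
  arr <- array(0, c(20, 20, 20))
  mask <- array(FALSE, c(20, 20, 20))
  mask[seq_len(n)] <- TRUE
  arr[mask] <- 5
  img <- image3d(arr, spacing_mm = c(4, 4, 4), units = "SUV")
  st <- suv_stats(img, mask)
  expect_equal(st$suv_max, 5)
  expect_equal(st$suv_mean, 5)
  expect_equal(st$tlg_g, 5 * n * vox_cc, tolerance = 1e-9)
  # two-voxel mask {4, 8} at 0.064 cc/voxel
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1:2] <- TRUE
  a2 <- array(0, c(4, 4, 4))
  a2[1:2] <- c(4, 8)
  st2 <- suv_stats(image3d(a2, spacing_mm = c(4, 4, 4), units = "SUV"), m2)
  expect_equal(st2$suv_max, 8)
  expect_equal(st2$suv_mean, 6)
  expect_equal(st2$tlg_g, 0.768, tolerance = 1e-9)
  # random image against brute force
  set.seed(5)
  r <- array(runif(4^3, 0, 20), c(4, 4, 4))
  rm <- array(runif(4^3) < 0.5, c(4, 4, 4))
  rs <- suv_stats(image3d(r, spacing_mm = c(2, 2, 2), units = "SUV"), rm)
  expect_equal(rs$suv_max, max(r[rm]))
  expect_equal(rs$suv_mean, mean(r[rm]))
  expect_error(suv_stats(img, array(FALSE, c(20, 20, 20))), "empty")
})

test_that("cohort summaries handle subgroups, exclusion and ordering", {
  fake <- function(d, of, x, y, flag) {
    structure(list(dice = d, of = of, x = x, y = y, v2_gt_v1 = flag,
                   vol_v1_cc = 10, vol_v2_cc = if (flag) 12 else 8,
                   vol_intersection_cc = 5,
                   band = vapply(c(dice = d, of = of, x = x, y = y),
                                 classify_concordance, "")),
              class = "overlap_result")
  }
  one <- summarize_cohort(list(fake(0.7, 0.8, 0.7, 0.75, FALSE)))
  d_row <- one[one$metric == "dice" & one$subgroup == "all", ]
  expect_equal(c(d_row$median, d_row$min, d_row$max), rep(0.7, 3))
  results <- list(fake(0.6, 0.7, 0.6, 0.7, FALSE),
                  fake(0.7, 0.8, 0.65, 0.8, FALSE),
                  fake(0.8, 0.9, 0.9, 0.6, TRUE))
  sm <- summarize_cohort(results)
  all_dice <- sm[sm$metric == "dice" & sm$subgroup == "all", ]
  expect_equal(all_dice$median, 0.7)
  expect_equal(c(all_dice$min, all_dice$max), c(0.6, 0.8))
  expect_equal(sm[sm$subgroup == "v2_gt_v1" & sm$metric == "dice", "n"], 1)
  # exclusion drops the flagged case from the "all" view
  ex <- summarize_cohort(results, exclude_v2_gt_v1 = TRUE)
  expect_equal(ex[ex$subgroup == "all" & ex$metric == "dice", "n"], 2)
  # order invariance
  sm_rev <- summarize_cohort(rev(results))
  expect_equal(sm[order(sm$subgroup, sm$metric), -1],
               sm_rev[order(sm_rev$subgroup, sm_rev$metric), -1],
               tolerance = 1e-12)
  expect_error(summarize_cohort(list()), "no overlap results")
  expect_error(summarize_cohort(list(fake(0.8, 0.9, 0.9, 0.6, TRUE)),
                                exclude_v2_gt_v1 = TRUE), "remain")
  # per-case table carries the documented columns
  tab <- overlap_table(results)
  expect_true(all(c("case_id", "dice", "of", "x", "y", "vol_v1_cc",
                    "vol_v2_cc", "v2_gt_v1", "band_dice") %in%
                    names(tab)))
  expect_equal(nrow(tab), 3)
})
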