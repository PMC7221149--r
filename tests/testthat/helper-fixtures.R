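# Shared fixtures: all built in code at test time.

# Coarse CT grid (same field of view as the default study conditions but
# 2x coarser) keeps registration unit tests fast; the acceptance tests
# use the full default grids.
coarse_ct_params <- function(...) {
  phantom_params(ct_spacing_mm = c(2.4, 2.4, 6),
                 ct_grid_shape = c(144, 112, 40), ...)
}

# Deterministic pseudo-random mask pair on a small grid.
random_mask_pair <- function(dims = c(8, 7, 6), p1 = 0.4, p2 = 0.4) {
  a <- array(runif(prod(dims)) < p1, dims)
  b <- array(runif(prod(dims)) < p2, dims)
  if (!any(a)) a[1] <- TRUE
  if (!any(b)) b[length(b)] <- TRUE
  list(a = a, b = b)
}

# Independent brute-force oracle for the overlap indices: explicit voxel
# enumeration, no set arithmetic shared with the implementation.
brute_force_overlap <- function(a, b, spacing) {
  n1 <- 0L; n2 <- 0L; ni <- 0L
  for (v in seq_along(a)) {
    in1 <- isTRUE(a[[v]])
    in2 <- isTRUE(b[[v]])
    if (in1) n1 <- n1 + 1L
    if (in2) n2 <- n2 + 1L
    if (in1 && in2) ni <- ni + 1L
  }
  vox <- prod(spacing) / 1000
  list(vol_v1_cc = n1 * vox, vol_v2_cc = n2 * vox,
       dice = 2 * ni / (n1 + n2), of = ni / min(n1, n2),
       x = ni / n1, y = ni / n2)
}

# A blocky two-level SUV image: background bg with an embedded box at hi.
two_level_image <- function(dims = c(20, 20, 20), bg = 2, hi = 8,
                            lo_corner = c(8, 8, 8), hi_corner = c(13, 13, 13),
                            spacing = c(4, 4, 4)) {
  arr <- array(bg, dims)
  arr[lo_corner[1]:hi_corner[1], lo_corner[2]:hi_corner[2],
      lo_corner[3]:hi_corner[3]] <- hi
  image3d(arr, spacing_mm = spacing, units = "SUV")
}

dice_between <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
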