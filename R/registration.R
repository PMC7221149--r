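# Rigid recurrence->baseline registration: center-of-mass initialization,
# multi-resolution mutual-information refinement, and resampling.

# Evaluate expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Intensity mass weights: HU shifted so air contributes nothing.
mass_weights <- function(img) {
  if (img$units == "HU") pmax(img$values + 1000, 0) else pmax(img$values, 0)
}

#' Center-of-mass initial transform
#'
#' Pure translation aligning the intensity centroid of the moving image
#' with that of the fixed image; the conventional initialization of
#' rigid mutual-information registration.
#'
#' @param fixed,moving [image3d]s (typically the baseline and recurrence CT).
#' @return a translation-only [rigid_transform] (moving -> fixed), centered
#'   at the fixed-image center.
#' @export
center_of_mass_transform <- function(fixed, moving) {
  cf <- intensity_centroid(fixed)
  cm <- intensity_centroid(moving)
  rigid_transform(c(0, 0, 0), cf - cm, center_mm = image_center_mm(fixed))
}

intensity_centroid <- function(img) {
  w <- mass_weights(img)
  tot <- sum(w)
  if (tot <= 0) stopf("image has zero intensity mass")
  d <- dim(w)
  mi_ <- rowSums(w)                  # i marginal (sum over j, k)
  mj_ <- rowSums(colSums(w))         # j marginal
  mk_ <- colSums(w, dims = 2)        # k marginal
  ci <- sum((seq_len(d[1]) - 1) * mi_) / tot
  cj <- sum((seq_len(d[2]) - 1) * mj_) / tot
  ck <- sum((seq_len(d[3]) - 1) * mk_) / tot
  A <- grid_affine(img)
  as.numeric(A %*% c(ci, cj, ck, 1))[1:3]
}

image_center_mm <- function(img) {
  A <- grid_affine(img)
  as.numeric(A %*% c((dim(img$values) - 1) / 2, 1))[1:3]
}

#' Resample an image through a rigid transform
#'
#' Pull-resampling: the output voxel at fixed-grid position \eqn{x} takes
#' the value of `img` at \eqn{T^{-1}(x)}, where `t` maps the image's own
#' (moving) space into the reference (fixed) space.
#'
#' @param img [image3d] to resample (moving image).
#' @param t [rigid_transform] mapping `img` space -> reference space.
#' @param reference_grid an [image3d] or grid list supplying the target
#'   geometry.
#' @param interpolation `"linear"`, `"nearest"` or `"cubic"`
#'   (Catmull-Rom, the least smoothing choice for PET intensities);
#'   masks (images whose values are all 0/1) must use `"nearest"`.
#' @param fill value for voxels mapping outside `img` (default -1000 for
#'   HU, 0 otherwise).
#' @return [image3d] on the reference grid, same units as `img`.
#' @export
apply_transform <- function(img, t, reference_grid,
                            interpolation = c("linear", "nearest",
                                              "cubic"),
                            fill = NULL) {
  stopifnot(inherits(img, "image3d"), inherits(t, "rigid_transform"))
  interpolation <- match.arg(interpolation)
  is_mask <- all(img$values %in% c(0, 1))
  if (is_mask && interpolation != "nearest")
    stopf("masks must be resampled with nearest-neighbour interpolation")
  grid <- if (inherits(reference_grid, "image3d")) grid_of(reference_grid)
          else reference_grid
  if (is.null(fill)) fill <- if (img$units == "HU") -1000 else 0
  # output index -> world -> T^{-1} -> moving world -> moving index
  M <- solve(grid_affine(img)) %*% transform_matrix(invert_transform(t)) %*%
    grid_affine_of(grid)
  interp_code <- c(linear = 0L, nearest = 1L, cubic = 2L)[[interpolation]]
  vals <- cpp_resample_affine(as.numeric(img$values), dim(img$values),
                              as.integer(grid$dim), M, fill, interp_code)
  image3d(array(vals, grid$dim), grid$spacing_mm, grid$origin_mm,
          grid$direction, img$units)
}

# Smoothed copy of an image (sigma in mm, isotropic).
smooth_image <- function(img, sigma_mm) {
  if (sigma_mm <= 0) return(img)
  sig_vox <- sigma_mm / img$spacing_mm
  with_values(img, array(cpp_gaussian_smooth(as.numeric(img$values),
                                             dim(img$values), sig_vox),
                         dim(img$values)))
}

# Mutual information between fixed sample intensities and the moving image
# sampled at the transformed point positions. Moving intensities are
# soft-binned (linear Parzen window) so the metric varies smoothly with
# sub-voxel displacements; fixed intensities use hard bins. Returns -Inf
# when too few samples land inside the moving image.
mi_metric <- function(fixed_vals, fixed_bin, moving_vals, moving_range,
                      bins) {
  ok <- moving_vals > moving_range[1] & moving_vals < moving_range[2]
  if (sum(ok) < 0.25 * length(moving_vals)) return(-Inf)
  fb <- fixed_bin[ok]
  pos <- (moving_vals[ok] - moving_range[1]) / diff(moving_range) * bins
  j0 <- pmin(pmax(floor(pos + 0.5), 1), bins)       # lower of the two bins
  frac <- pmin(pmax(pos + 0.5 - j0, 0), 1)
  j1 <- pmin(j0 + 1, bins)
  g <- c(fb + bins * (j0 - 1), fb + bins * (j1 - 1))
  w <- c(1 - frac, frac)
  acc <- rowsum(w, g)
  joint <- numeric(bins * bins)
  joint[as.integer(rownames(acc))] <- acc
  n <- sum(joint)
  p <- joint / n
  pf <- tabulate(fb, nbins = bins) / n
  pm <- .colSums(matrix(p, bins, bins), bins, bins)
  nz <- p > 0
  pp <- as.numeric(outer(pf, pm))
  sum(p[nz] * log(p[nz] / pp[nz]))
}

#' Rigid mutual-information registration
#'
#' 6-DOF rigid registration of a moving CT onto a fixed CT by maximizing
#' the mutual information between their intensity distributions
#' (fixed-bin joint histogram), evaluated on a seeded random sample of
#' body voxels, over a coarse-to-fine schedule of Gaussian-smoothed
#' levels. Each level runs a greedy step-halving local search that only
#' accepts metric-improving steps, so the accepted-metric trace is
#' non-decreasing within a level and the procedure is deterministic.
#'
#' @param fixed_ct,moving_ct [image3d]s in HU.
#' @param init initial [rigid_transform] (moving -> fixed); default
#'   [center_of_mass_transform()].
#' @param opts list of options: `bins` (histogram bins, 50), `levels`
#'   (data.frame with `sigma_mm`, `n_samples`, `step_mm`, `min_step_mm`,
#'   `max_iter`), `seed` (sample-selection seed, 1234),
#'   `body_threshold_hu` (sampling restricted to fixed voxels above this,
#'   -500).
#' @return list with `transform` (the refined [rigid_transform]),
#'   `converged`, `metric_initial`, `metric_final`, `iterations` per
#'   level, and `trace` (per-level vectors of accepted metric values,
#'   non-decreasing within each level by construction).
#' @export
register_rigid_mi <- function(fixed_ct, moving_ct, init = NULL,
                              opts = list()) {
  stopifnot(inherits(fixed_ct, "image3d"), inherits(moving_ct, "image3d"))
  bins <- opts$bins %||% 50L
  seed <- opts$seed %||% 1234L
  thr <- opts$body_threshold_hu %||% -500
  levels <- opts$levels %||% data.frame(
    sigma_mm   = c(4, 2, 0),
    n_samples  = c(6000, 12000, 24000),
    step_mm    = c(4, 2, 1),
    min_step_mm = c(0.5, 0.25, 0.05),
    max_iter   = c(60, 60, 80))
  if (is.null(init)) init <- center_of_mass_transform(fixed_ct, moving_ct)

  body_idx <- which(fixed_ct$values > thr)
  if (length(body_idx) < 100L)
    stopf("fixed image has too few voxels above the sampling threshold")
  center <- init$center_mm
  p <- c(init$rotation_deg, init$translation_mm)
  deg_per_mm <- 0.5  # step scaling between rotational and translational axes

  A_fix <- grid_affine(fixed_ct)
  A_mov_inv <- solve(grid_affine(moving_ct))
  trace <- list()
  iters <- integer(0)
  metric_initial <- NA_real_

  eval_metric <- function(par, fvals, fbin, pts_world, mov_smooth, mrange) {
    tr <- rigid_transform(par[1:3], par[4:6], center)
    M <- A_mov_inv %*% transform_matrix(invert_transform(tr))
    pts_idx <- cbind(pts_world, 1) %*% base::t(M)
    mv <- cpp_sample_trilinear(mov_smooth, dim(moving_ct$values),
                               pts_idx[, 1:3, drop = FALSE],
                               fill = mrange[1] - 1)
    mi_metric(fvals, fbin, mv, mrange, bins)
  }

  for (lv in seq_len(nrow(levels))) {
    sig <- levels$sigma_mm[lv]
    fx_s <- smooth_image(fixed_ct, sig)
    mv_s <- smooth_image(moving_ct, sig)
    mov_smooth <- as.numeric(mv_s$values)
    mrange <- range(mov_smooth)
    mrange <- mrange + c(-1, 1) * 1e-6 * max(1, diff(mrange))
    n_s <- min(levels$n_samples[lv], length(body_idx))
    sel <- with_seed(sub_seed(seed, lv), sample(body_idx, n_s))
    idx <- arrayInd(sel, dim(fixed_ct$values))
    pts_world <- (cbind(idx - 1, 1) %*% base::t(A_fix))[, 1:3, drop = FALSE]
    fvals <- as.numeric(fx_s$values)[sel]
    frange <- range(fvals) + c(-1, 1) * 1e-6
    fbin <- pmin(pmax(1L + as.integer((fvals - frange[1]) /
                                        diff(frange) * bins), 1L), bins)

    step <- levels$step_mm[lv]
    cur <- eval_metric(p, fvals, fbin, pts_world, mov_smooth, mrange)
    if (lv == 1L) metric_initial <- cur
    level_start <- cur
    lv_trace <- cur
    it <- 0L
    while (step >= levels$min_step_mm[lv] && it < levels$max_iter[lv]) {
      it <- it + 1L
      best_val <- cur
      best_p <- NULL
      for (ax in 1:6) {
        delta <- if (ax <= 3) step * deg_per_mm else step
        for (sgn in c(-1, 1)) {
          cand <- p
          cand[ax] <- cand[ax] + sgn * delta
          v <- eval_metric(cand, fvals, fbin, pts_world, mov_smooth, mrange)
          if (v > best_val) {
            best_val <- v
            best_p <- cand
          }
        }
      }
      if (is.null(best_p)) {
        step <- step / 2
      } else {
        p <- best_p
        cur <- best_val
        lv_trace <- c(lv_trace, cur)
      }
    }
    trace[[lv]] <- lv_trace
    iters <- c(iters, it)
    if (cur < level_start - 1e-12) {
      return(list(transform = init, converged = FALSE,
                  metric_initial = metric_initial, metric_final = cur,
                  iterations = iters, trace = trace))
    }
  }
  list(transform = rigid_transform(p[1:3], p[4:6], center),
       converged = TRUE, metric_initial = metric_initial,
       metric_final = cur, iterations = iters, trace = trace)
}
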