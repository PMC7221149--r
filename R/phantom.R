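# Seeded generator of paired baseline/recurrence PET/CT pelvic studies with
# full ground truth: a cervix-region anatomy with variable bladder/rectum
# filling, a heterogeneous tumor carrying a high-uptake core (V1) inside the
# whole tumor (VT), a planted recurrence volume (V2) with controllable true
# overlap against V1, and a known rigid misalignment between time points.

# Label codes of the anatomy volume.
LAB_EXTERIOR <- 0L
LAB_SOFT <- 1L
LAB_BONE <- 2L
LAB_BLADDER <- 3L
LAB_RECTUM <- 4L
LAB_TUMOR <- 5L

HU_OF_LABEL <- c("0" = -1000, "1" = 40, "2" = 700, "3" = 10, "4" = -900,
                 "5" = 45)

#' Phantom generation parameters
#'
#' Defaults emulate the acquisition and cohort statistics of a pelvic
#' FDG-PET/CT study of locally advanced cervical cancer: 4 mm isotropic
#' PET voxels on a 96^3 grid, 1.2 x 1.2 x 3 mm CT voxels, a whole-tumor
#' target volume of 41.9 cm^3 with a high-uptake core occupying 43% of
#' it, a 15.1 cm^3 recurrence volume, 6 mm PSF blur and
#' intensity-dependent Gaussian noise.
#'
#' @param pet_spacing_mm,ct_spacing_mm per-axis voxel sizes (mm).
#' @param grid_shape PET voxel counts per axis.
#' @param ct_grid_shape CT voxel counts per axis.
#' @param suv_background,suv_tumor_low,suv_tumor_high SUV class levels,
#'   strictly increasing.
#' @param suv_recurrence uptake level of the recurrence volume on the
#'   follow-up PET; defaults to `suv_tumor_high`. Set lower (e.g. 7) to
#'   emulate a low-contrast post-treatment residual uptake.
#' @param suv_bladder SUV of urine (hot bladder).
#' @param class_sd noise SD (SUV) at background uptake; scaled at each
#'   voxel by the square root of local uptake relative to background.
#' @param psf_fwhm_mm isotropic Gaussian PSF full width at half maximum.
#' @param vt_target_cc whole-tumor target volume (cm^3).
#' @param v1_fraction fraction of VT occupied by the high-uptake core.
#' @param v2_target_cc recurrence target volume (cm^3); when both overlap
#'   targets are positive the implied volume `x * |V1| / y` takes
#'   precedence.
#' @param overlap_target_x,overlap_target_y desired true
#'   (V1 n V2)/V1 and (V1 n V2)/V2, each in `[0, 1]`.
#' @param misalign_translation_mm,misalign_rotation_deg rigid misalignment
#'   applied to the recurrence study.
#' @param bladder_fill_delta relative bladder volume change between time
#'   points (0.5 = recurrence bladder 50% larger).
#' @param seed default RNG seed for this case.
#' @return classed parameter list (`phantom_params`).
#' @export
phantom_params <- function(pet_spacing_mm = c(4, 4, 4),
                           ct_spacing_mm = c(1.2, 1.2, 3),
                           grid_shape = c(96, 96, 96),
                           ct_grid_shape = c(288, 224, 80),
                           suv_background = 1.8,
                           suv_tumor_low = 5,
                           suv_tumor_high = 14,
                           suv_recurrence = NULL,
                           suv_bladder = 30,
                           class_sd = 0.4,
                           psf_fwhm_mm = 6,
                           vt_target_cc = 41.9,
                           v1_fraction = 0.43,
                           v2_target_cc = 15.1,
                           overlap_target_x = 0.70,
                           overlap_target_y = 0.77,
                           misalign_translation_mm = c(5, 3, -4),
                           misalign_rotation_deg = c(3, 0, 2),
                           bladder_fill_delta = 0.3,
                           seed = 1L) {
  p <- as.list(environment())
  if (is.null(p$suv_recurrence)) p$suv_recurrence <- suv_tumor_high
  if (!(suv_background < suv_tumor_low && suv_tumor_low < suv_tumor_high))
    stopf("SUV levels must be strictly ordered background < low < high")
  if (p$suv_recurrence <= suv_background)
    stopf("suv_recurrence must exceed suv_background")
  if (!(v1_fraction > 0 && v1_fraction < 1))
    stopf("v1_fraction must be in (0, 1)")
  for (nm in c("overlap_target_x", "overlap_target_y")) {
    v <- p[[nm]]
    if (!is.na(v) && (v < 0 || v > 1)) stopf("%s must be in [0, 1]", nm)
  }
  if (any(pet_spacing_mm <= 0) || any(ct_spacing_mm <= 0))
    stopf("spacings must be strictly positive")
  if (vt_target_cc <= 0 || v2_target_cc <= 0)
    stopf("target volumes must be strictly positive")
  if (class_sd < 0) stopf("class_sd must be non-negative")
  if (any(grid_shape < 16) || any(ct_grid_shape < 16))
    stopf("degenerate grid: every axis needs at least 16 voxels")
  structure(p, class = "phantom_params")
}

# Centered axis-aligned grids (world origin at the grid center).
centered_grid <- function(shape, spacing) {
  list(dim = as.integer(shape), spacing_mm = spacing,
       origin_mm = -(shape - 1) / 2 * spacing, direction = diag(3))
}

pet_grid <- function(params) centered_grid(params$grid_shape,
                                           params$pet_spacing_mm)
ct_grid <- function(params) centered_grid(params$ct_grid_shape,
                                          params$ct_spacing_mm)

# World coordinates of grid axes (identity direction assumed for phantoms).
grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin_mm[a] + (seq_len(grid$dim[a]) - 1) * grid$spacing_mm[a])
}

# An ellipsoid in world space: center (mm), semi-axes (mm), rotation R.
ellipsoid <- function(center, radii, R = diag(3)) {
  list(center = center, radii = radii, R = R)
}

# Rasterize a union of ellipsoids onto a grid (logical array), evaluating
# each ellipsoid only inside its world bounding box.
rasterize_union <- function(shapes, grid) {
  ax <- grid_axes(grid)
  mask <- array(FALSE, grid$dim)
  for (sh in shapes) {
    r <- max(sh$radii) * 1.001
    rng <- lapply(1:3, function(a)
      which(ax[[a]] >= sh$center[a] - r & ax[[a]] <= sh$center[a] + r))
    if (any(lengths(rng) == 0L)) next
    xs <- ax[[1]][rng[[1]]] - sh$center[1]
    ys <- ax[[2]][rng[[2]]] - sh$center[2]
    zs <- ax[[3]][rng[[3]]] - sh$center[3]
    n <- c(length(xs), length(ys), length(zs))
    pts <- cbind(rep(xs, times = n[2] * n[3]),
                 rep(rep(ys, each = n[1]), times = n[3]),
                 rep(zs, each = n[1] * n[2]))
    q <- pts %*% sh$R            # body-frame coordinates
    inside <- (q[, 1] / sh$radii[1])^2 + (q[, 2] / sh$radii[2])^2 +
      (q[, 3] / sh$radii[3])^2 <= 1
    mask[rng[[1]], rng[[2]], rng[[3]]] <-
      mask[rng[[1]], rng[[2]], rng[[3]]] | array(inside, n)
  }
  mask
}

random_rotation <- function() {
  # QR-based random rotation; adequate for shape jitter.
  M <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Fixed anatomy layout (world mm): body ellipse-cylinder, two femoral bone
# columns, a posterior sacral block, bladder anterior, rectum posterior,
# tumor in the cervix region between them. The bladder sits far enough
# anterior-inferior that even at maximal fill its keep-out zone cannot
# reach the (jittered) tumor center.
anatomy_layout <- function() {
  list(body_semi = c(160, 105), body_z = c(-118, 118),
       bone_x = c(-95, 95), bone_r = 18, bone_z = c(-118, 118),
       sacrum = ellipsoid(c(0, 78, 10), c(32, 22, 55)),
       bladder_center = c(0, -62, -15), bladder_base_cc = 150,
       rectum_center_xy = c(0, 46), rectum_r = 13, rectum_z = c(-60, 30),
       tumor_center = c(0, 6, -12))
}

bladder_shape <- function(params, timepoint, jitter = c(0, 0, 0)) {
  lay <- anatomy_layout()
  vol_cc <- lay$bladder_base_cc
  if (timepoint == "recurrence") vol_cc <- vol_cc * (1 + params$bladder_fill_delta)
  if (vol_cc <= 1) stopf("bladder_fill_delta leaves no bladder volume")
  r0 <- (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)
  ellipsoid(lay$bladder_center + jitter, r0 * c(1.15, 1.0, 0.87))
}

# Keep-out zone around the bladder at its larger fill, padded by 10 mm,
# so tumor, core and recurrence masks are disjoint from the hot urine by
# construction at both time points (and stay clear of the data-derived
# bladder exclusion used at segmentation time).
bladder_exclusion_mask <- function(params, grid, shapes, margin_mm = 10) {
  tp <- if (params$bladder_fill_delta > 0) "recurrence" else "baseline"
  bl <- bladder_shape(params, tp, shapes$bladder_jitter)
  bl$radii <- bl$radii + margin_mm
  rasterize_union(list(bl), grid)
}

#' Build the labeled CT anatomy of one time point
#'
#' Deterministic per seed. Returns the label volume and the HU image on
#' the CT grid: body soft tissue 40 HU, bone 700, urine 10, rectal air
#' -900, exterior -1000, tumor 45.
#'
#' @param params [phantom_params()].
#' @param seed integer seed (drives bladder jitter and tumor shape).
#' @param timepoint `"baseline"` or `"recurrence"`; the recurrence bladder
#'   volume is scaled by `1 + bladder_fill_delta`.
#' @return list with `labels` and `hu` ([image3d]s on the CT grid).
#' @export
build_anatomy <- function(params, seed = params$seed,
                          timepoint = c("baseline", "recurrence")) {
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(params, "phantom_params"))
  grid <- ct_grid(params)
  lay <- anatomy_layout()
  ax <- grid_axes(grid)
  lab <- array(LAB_EXTERIOR, grid$dim)

  in_body_xy <- outer((ax[[1]] / lay$body_semi[1])^2,
                      (ax[[2]] / lay$body_semi[2])^2, "+") <= 1
  in_body_z <- ax[[3]] >= lay$body_z[1] & ax[[3]] <= lay$body_z[2]
  body <- array(FALSE, grid$dim)
  body[, , in_body_z] <- in_body_xy
  lab[body] <- LAB_SOFT

  bone_xy <- outer((ax[[1]] - lay$bone_x[1])^2, ax[[2]]^2, "+") <=
    lay$bone_r^2
  bone_xy <- bone_xy | (outer((ax[[1]] - lay$bone_x[2])^2, ax[[2]]^2, "+") <=
                          lay$bone_r^2)
  bone <- array(FALSE, grid$dim)
  bone[, , in_body_z] <- bone_xy
  bone <- bone | rasterize_union(list(lay$sacrum), grid)
  lab[bone & body] <- LAB_BONE

  shapes <- case_geometry(params, seed)$shapes
  bl <- bladder_shape(params, timepoint, shapes$bladder_jitter)
  lab[rasterize_union(list(bl), grid) & body] <- LAB_BLADDER

  rect_xy <- outer((ax[[1]] - lay$rectum_center_xy[1])^2,
                   (ax[[2]] - lay$rectum_center_xy[2])^2, "+") <=
    lay$rectum_r^2
  rect <- array(FALSE, grid$dim)
  rect_z <- ax[[3]] >= lay$rectum_z[1] & ax[[3]] <= lay$rectum_z[2]
  rect[, , rect_z] <- rect_xy
  lab[rect & body] <- LAB_RECTUM

  tum <- rasterize_union(shapes$vt_shapes, grid) &
    !bladder_exclusion_mask(params, grid, shapes)
  lab[tum & body] <- LAB_TUMOR

  hu <- array(HU_OF_LABEL[as.character(lab)], grid$dim)
  list(labels = image3d(lab + 0, grid$spacing_mm, grid$origin_mm,
                        grid$direction, "none"),
       hu = image3d(hu, grid$spacing_mm, grid$origin_mm, grid$direction,
                    "HU"))
}

# Seeded world-space case geometry: tumor ellipsoid union calibrated to the
# VT volume target, V1 anchor direction, bladder jitter. Must be called
# inside with_seed().
case_shapes <- function(params) {
  lay <- anatomy_layout()
  bladder_jitter <- runif(3, -4, 4)
  center <- lay$tumor_center + runif(3, -5, 5)
  r0 <- (3 * params$vt_target_cc * 1000 / (4 * pi))^(1 / 3)
  jit <- exp(runif(3, log(0.8), log(1.25)))
  jit <- jit / prod(jit)^(1 / 3)
  shapes <- list(ellipsoid(center, r0 * jit, random_rotation()))
  n_extra <- sample(1:3, 1)
  for (i in seq_len(n_extra)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    off <- u * r0 * runif(1, 0.5, 0.8)
    jit2 <- exp(runif(3, log(0.75), log(1.3)))
    jit2 <- jit2 / prod(jit2)^(1 / 3)
    shapes <- c(shapes, list(ellipsoid(center + off, 0.55 * r0 * jit2,
                                       random_rotation())))
  }
  list(vt_shapes = shapes, center = center,
       v1_dir = { u <- rnorm(3); u / sqrt(sum(u^2)) },
       v1_metric = exp(runif(3, log(0.8), log(1.25))),
       v2_dir = { u <- rnorm(3); u / sqrt(sum(u^2)) },
       bladder_jitter = bladder_jitter)
}

# Seeded shape draw followed by VT volume calibration on the PET grid;
# shared by build_anatomy() and generate_case() so CT and PET agree.
case_geometry <- function(params, seed) {
  shapes <- with_seed(sub_seed(seed, 11L), case_shapes(params))
  grid <- pet_grid(params)
  excl <- bladder_exclusion_mask(params, grid, shapes)
  out <- calibrate_vt(shapes, grid, params$vt_target_cc, exclude = excl)
  out$bladder_exclusion <- excl
  out
}

# Rescale VT shapes so the rasterized voxel volume matches the target.
calibrate_vt <- function(shapes, grid, target_cc, exclude = NULL) {
  vox_cc <- prod(grid$spacing_mm) / 1000
  for (it in 1:2) {
    mask <- rasterize_union(shapes$vt_shapes, grid)
    if (!is.null(exclude)) mask <- mask & !exclude
    got <- sum(mask) * vox_cc
    if (got <= 0) stopf("tumor rasterized to an empty mask")
    s <- (target_cc / got)^(1 / 3)
    shapes$vt_shapes <- lapply(shapes$vt_shapes, function(sh) {
      sh$radii <- sh$radii * s
      sh$center <- shapes$center + (sh$center - shapes$center) * s
      sh
    })
  }
  mask <- rasterize_union(shapes$vt_shapes, grid)
  if (!is.null(exclude)) mask <- mask & !exclude
  mask <- largest_component(mask)
  got <- sum(mask) * vox_cc
  if (abs(got - target_cc) > 0.25 * target_cc)
    stopf("tumor volume calibration failed: %.1f cc against a %.1f cc target",
          got, target_cc)
  list(shapes = shapes, vt_mask = mask)
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- cpp_connected_components(mask, dim(mask))
  sizes <- tabulate(lab, nbins = attr(lab, "ncomp"))
  array(lab == which.max(sizes), dim(mask))
}

# Deterministic connected greedy growth: starting from the allowed voxel
# nearest the anchor (or from the frontier of `attach_to`), repeatedly
# add the frontier voxel (6-neighbour of the region, inside `allowed`)
# closest to the anchor, until n voxels. Guarantees a connected region
# with an exact voxel count.
grow_region <- function(allowed, grid, anchor, n, metric = c(1, 1, 1),
                        attach_to = NULL) {
  if (n < 1L) return(array(FALSE, dim(allowed)))
  if (sum(allowed) < n)
    stopf("region of %d voxels does not fit (only %d allowed)",
          n, sum(allowed))
  d <- dim(allowed)
  ax <- grid_axes(grid)
  dist_of <- function(p) {
    p0 <- p - 1L
    i <- p0 %% d[1] + 1L
    j <- (p0 %/% d[1]) %% d[2] + 1L
    k <- p0 %/% (d[1] * d[2]) + 1L
    ((ax[[1]][i] - anchor[1]) / metric[1])^2 +
      ((ax[[2]][j] - anchor[2]) / metric[2])^2 +
      ((ax[[3]][k] - anchor[3]) / metric[3])^2
  }
  neighbours <- function(p) {
    p0 <- p - 1L
    i <- p0 %% d[1] + 1L
    j <- (p0 %/% d[1]) %% d[2] + 1L
    k <- p0 %/% (d[1] * d[2]) + 1L
    nb <- c(if (i > 1L) p - 1L, if (i < d[1]) p + 1L,
            if (j > 1L) p - d[1], if (j < d[2]) p + d[1],
            if (k > 1L) p - d[1] * d[2], if (k < d[3]) p + d[1] * d[2])
    nb
  }
  region <- logical(length(allowed))
  inq <- logical(length(allowed))
  if (is.null(attach_to)) {
    cand <- which(allowed)
    fidx <- cand[which.min(dist_of(cand))]
  } else {
    seed_nb <- unique(unlist(lapply(which(attach_to), neighbours)))
    fidx <- seed_nb[allowed[seed_nb]]
    if (length(fidx) == 0L) {
      cand <- which(allowed)
      fidx <- cand[which.min(dist_of(cand))]
    }
  }
  fdist <- dist_of(fidx)
  inq[fidx] <- TRUE
  taken <- 0L
  while (taken < n) {
    if (length(fidx) == 0L)
      stopf("connected region of %d voxels does not fit here", n)
    j <- which.min(fdist)
    p <- fidx[j]
    fidx <- fidx[-j]
    fdist <- fdist[-j]
    region[p] <- TRUE
    taken <- taken + 1L
    nb <- neighbours(p)
    nb <- nb[allowed[nb] & !inq[nb]]
    if (length(nb)) {
      inq[nb] <- TRUE
      fidx <- c(fidx, nb)
      fdist <- c(fdist, dist_of(nb))
    }
  }
  array(region, d)
}

# The high-uptake core: a connected region of round(f*|VT|) VT voxels
# grown (in a jittered anisotropic metric) around an interior anchor;
# exact fraction, always a connected subset of VT.
carve_v1 <- function(vt_mask, grid, fraction, shapes) {
  idx <- mask_indices(vt_mask)
  ax <- grid_axes(grid)
  pts <- cbind(ax[[1]][idx[, 1]], ax[[2]][idx[, 2]], ax[[3]][idx[, 3]])
  ctr <- colMeans(pts)
  r_eff <- (3 * nrow(pts) * prod(grid$spacing_mm) / (4 * pi))^(1 / 3)
  anchor <- ctr + shapes$v1_dir * 0.25 * r_eff
  n1 <- max(1L, round(fraction * nrow(pts)))
  grow_region(vt_mask, grid, anchor, n1, metric = shapes$v1_metric)
}

#' Plant the recurrence volume with a controlled true overlap
#'
#' Constructs the ground-truth V2 mask so that the achieved
#' X = |V1 n V2|/|V1| and Y = |V1 n V2|/|V2| match the requested targets
#' to rounding precision (always within 0.02). The mask is grown
#' deterministically from an anchor near V1: the required number of
#' intersection voxels is taken from V1 (nearest to the anchor), the rest
#' from outside V1. When both targets are positive the implied volume
#' `x |V1| / y` defines |V2|; with both zero, `v2_target_cc` does and V2
#' is placed disjoint from V1.
#'
#' @param truth partial truth list carrying `vt_mask`, `v1_mask` and the
#'   case `shapes` (as produced inside [generate_case()]).
#' @param params [phantom_params()].
#' @param seed unused (construction is deterministic given the shapes);
#'   kept for interface symmetry.
#' @return `truth` with `v2_mask` and achieved overlap indices filled in.
#' @export
plant_recurrence <- function(truth, params, seed = params$seed) {
  x_t <- params$overlap_target_x
  y_t <- params$overlap_target_y
  if (is.na(x_t) || is.na(y_t))
    stopf("overlap targets must be set (use 0 for a disjoint recurrence)")
  if ((x_t > 0 && y_t == 0) || (x_t == 0 && y_t > 0))
    stopf(paste("infeasible overlap targets X=%.2f, Y=%.2f:",
                "both must be zero (disjoint) or both positive"),
          x_t, y_t)
  grid <- pet_grid(params)
  vox_cc <- prod(grid$spacing_mm) / 1000
  v1 <- truth$v1_mask
  n1 <- sum(v1)
  if (n1 == 0L) stopf("v1_mask is empty")
  if (x_t == 0 && y_t == 0) {
    n_int <- 0L
    n2 <- max(1L, round(params$v2_target_cc / vox_cc))
  } else {
    n_int <- round(x_t * n1)
    n2 <- max(1L, round(n_int / y_t))
    if (n_int > n2)
      stopf("infeasible overlap targets: X*|V1| (%d voxels) exceeds |V2| (%d)",
            n_int, n2)
  }
  ax <- grid_axes(grid)
  idx1 <- mask_indices(v1)
  pts1 <- cbind(ax[[1]][idx1[, 1]], ax[[2]][idx1[, 2]], ax[[3]][idx1[, 3]])
  ctr <- colMeans(pts1)
  r_eff <- (3 * n1 * prod(grid$spacing_mm) / (4 * pi))^(1 / 3)
  u <- truth$shapes$v2_dir
  v2 <- array(FALSE, dim(v1))
  if (n_int > 0L) {
    anchor <- ctr + u * r_eff * 1.15 * (1.05 - x_t)
    v2 <- grow_region(v1, grid, anchor, n_int)
    grow_anchor <- anchor
  } else {
    grow_anchor <- ctr + u * r_eff * 3.0
  }
  n_out <- n2 - n_int
  if (n_out > 0L) {
    allowed <- !v1
    if (!is.null(truth$bladder_exclusion))
      allowed <- allowed & !truth$bladder_exclusion
    if (n_int > 0L) {
      # grow the outside part attached to the intersection region so V2
      # stays connected
      out_part <- grow_region(allowed, grid, grow_anchor, n_out,
                              attach_to = v2)
      v2 <- v2 | out_part
    } else {
      v2 <- grow_region(allowed, grid, grow_anchor, n_out)
    }
  }
  n_int_got <- sum(v2 & v1)
  truth$v2_mask <- v2
  truth$achieved_x <- n_int_got / n1
  truth$achieved_y <- n_int_got / sum(v2)
  truth$achieved_dice <- 2 * n_int_got / (n1 + sum(v2))
  truth$achieved_of <- if (n_int_got == 0) 0 else
    n_int_got / min(n1, sum(v2))
  if (abs(truth$achieved_x - x_t) > 0.02 ||
      abs(truth$achieved_y - y_t) > 0.02)
    stopf("achieved overlap (X=%.3f, Y=%.3f) misses targets (X=%.2f, Y=%.2f)",
          truth$achieved_x, truth$achieved_y, x_t, y_t)
  truth
}

#' Synthesize a PET image from ground-truth masks
#'
#' A piecewise-constant ideal uptake map (air / body background /
#' tumor-low / tumor-high / hot bladder) is convolved with an isotropic
#' Gaussian PSF and corrupted with zero-mean Gaussian noise whose SD at
#' each voxel is `class_sd` scaled by the square root of the local
#' (blurred) uptake relative to background; the result is clipped at 0.
#'
#' @param masks list with logical PET-grid arrays `body`, `bladder`, and
#'   either `vt`/`v1` (baseline) or `v2` (recurrence).
#' @param params [phantom_params()].
#' @param seed noise seed.
#' @param timepoint `"baseline"` or `"recurrence"`.
#' @return [image3d] in SUV on the PET grid.
#' @export
synthesize_pet <- function(masks, params, seed = params$seed,
                           timepoint = c("baseline", "recurrence")) {
  timepoint <- match.arg(timepoint)
  blurred <- blurred_uptake(masks, params, timepoint)
  add_pet_noise(blurred, params, seed)
}

# Piecewise-constant ideal uptake convolved with the PSF (no noise).
blurred_uptake <- function(masks, params,
                           timepoint = c("baseline", "recurrence")) {
  timepoint <- match.arg(timepoint)
  if (params$psf_fwhm_mm < 0) stopf("psf_fwhm_mm must be >= 0")
  grid <- pet_grid(params)
  ideal <- array(0.05, grid$dim)
  ideal[masks$body] <- params$suv_background
  if (timepoint == "baseline") {
    ideal[masks$vt] <- params$suv_tumor_low
    ideal[masks$v1] <- params$suv_tumor_high
  } else {
    ideal[masks$v2] <- params$suv_recurrence %||% params$suv_tumor_high
  }
  ideal[masks$bladder] <- params$suv_bladder
  img <- ideal
  if (params$psf_fwhm_mm > 0) {
    sig_vox <- params$psf_fwhm_mm / 2.3548 / grid$spacing_mm
    img <- array(cpp_gaussian_smooth(as.numeric(img), grid$dim, sig_vox),
                 grid$dim)
  }
  image3d(img, grid$spacing_mm, grid$origin_mm, grid$direction, "SUV")
}

# Intensity-dependent Gaussian noise on a blurred uptake map, clipped at 0.
add_pet_noise <- function(blurred, params, seed) {
  img <- blurred$values
  if (params$class_sd > 0) {
    sd_map <- params$class_sd *
      sqrt(pmax(img, 0.01) / params$suv_background)
    img <- img + with_seed(seed, rnorm(length(img))) * sd_map
  }
  with_values(blurred, array(pmax(img, 0), dim(img)))
}

# PET-grid anatomy masks shared by both time points.
pet_masks <- function(params, shapes, timepoint) {
  grid <- pet_grid(params)
  lay <- anatomy_layout()
  ax <- grid_axes(grid)
  body <- array(FALSE, grid$dim)
  in_xy <- outer((ax[[1]] / lay$body_semi[1])^2,
                 (ax[[2]] / lay$body_semi[2])^2, "+") <= 1
  in_z <- ax[[3]] >= lay$body_z[1] & ax[[3]] <= lay$body_z[2]
  body[, , in_z] <- in_xy
  bl <- bladder_shape(params, timepoint, shapes$bladder_jitter)
  list(body = body, bladder = rasterize_union(list(bl), grid) & body)
}

#' Apply the ground-truth misalignment to a recurrence image
#'
#' The recurrence study is synthesized in the baseline frame; this
#' resamples it through the true transform so that registering
#' recurrence back to baseline should recover `true_transform`.
#'
#' @param img [image3d] (recurrence PET or CT in the baseline frame).
#' @param true_transform [rigid_transform] mapping recurrence space to
#'   baseline space.
#' @return misaligned [image3d] on the same grid.
#' @export
misalign <- function(img, true_transform) {
  apply_transform(img, invert_transform(true_transform), grid_of(img),
                  interpolation = "linear")
}

#' Generate one paired baseline/recurrence phantom case
#'
#' Orchestrates anatomy construction, tumor/core/recurrence ground truth,
#' PET synthesis, and the rigid misalignment of the recurrence study.
#' Deterministic per `(params, seed)`.
#'
#' @param params [phantom_params()].
#' @param seed integer case seed.
#' @param materialize `"full"` (images + truth) or `"truth"` (ground-truth
#'   masks and indices only; no CT/PET synthesis).
#' @param output_dir optional directory; when given, images and masks are
#'   written as NIfTI with a JSON truth sidecar.
#' @return list with `baseline` (`pet`, `ct`), `recurrence` (`pet`, `ct`,
#'   both misaligned), and `truth` (masks on the baseline PET grid, true
#'   transform, true class means/SDs, achieved overlap indices, bladder
#'   bounding box for ROI exclusion).
#' @export
generate_case <- function(params = phantom_params(), seed = params$seed,
                          materialize = c("full", "truth"),
                          output_dir = NULL) {
  materialize <- match.arg(materialize)
  stopifnot(inherits(params, "phantom_params"))
  grid <- pet_grid(params)
  cal <- case_geometry(params, seed)
  shapes <- cal$shapes
  vt <- cal$vt_mask
  if (!any(vt)) stopf("empty VT ground truth")
  v1 <- carve_v1(vt, grid, params$v1_fraction, shapes)
  truth <- list(vt_mask = vt, v1_mask = v1, shapes = shapes,
                bladder_exclusion = cal$bladder_exclusion)
  truth <- plant_recurrence(truth, params, seed)
  truth$true_transform <- rigid_transform(params$misalign_rotation_deg,
                                          params$misalign_translation_mm,
                                          center_mm = c(0, 0, 0))
  lv <- c(params$suv_background, params$suv_tumor_low, params$suv_tumor_high)
  truth$true_class_means <- lv
  truth$true_class_sds <- params$class_sd * sqrt(lv / params$suv_background)
  vox_cc <- prod(grid$spacing_mm) / 1000
  truth$vt_cc <- sum(vt) * vox_cc
  truth$v1_cc <- sum(v1) * vox_cc
  truth$v2_cc <- sum(truth$v2_mask) * vox_cc
  truth$v2_gt_v1 <- sum(truth$v2_mask) > sum(v1)

  pm_base <- pet_masks(params, shapes, "baseline")
  bb <- bladder_box(pm_base$bladder)
  truth$bladder_box <- bb
  case <- list(truth = truth, params = params, seed = seed)
  if (materialize == "full") {
    pm_rec <- pet_masks(params, shapes, "recurrence")
    pet1 <- synthesize_pet(c(pm_base, list(vt = vt, v1 = v1)), params,
                           seed = sub_seed(seed, 21L), "baseline")
    # The acquired recurrence PET: an isotropic PSF commutes with rigid
    # motion, so the blurred aligned uptake field is sampled on the
    # misaligned acquisition grid (smooth field, cubic interpolation is
    # near-exact) and the acquisition noise is then drawn in that frame.
    blurred_rec <- blurred_uptake(c(pm_rec, list(v2 = truth$v2_mask)),
                                  params, "recurrence")
    blurred_acq <- apply_transform(blurred_rec,
                                   invert_transform(truth$true_transform),
                                   grid, interpolation = "cubic",
                                   fill = 0.05)
    blurred_acq$values <- pmax(blurred_acq$values, 0)
    pet2 <- add_pet_noise(blurred_acq, params, sub_seed(seed, 22L))
    ct1 <- build_anatomy(params, seed, "baseline")$hu
    ct2_aligned <- build_anatomy(params, seed, "recurrence")$hu
    case$baseline <- list(pet = pet1, ct = ct1)
    case$recurrence <- list(pet = pet2,
                            ct = misalign(ct2_aligned,
                                          truth$true_transform))
  }
  if (!is.null(output_dir)) write_case(case, output_dir)
  case
}

# Padded bounding box (1-based index ranges) of the bladder on the PET grid.
bladder_box <- function(bladder_mask, pad = 2L) {
  idx <- mask_indices(bladder_mask)
  if (nrow(idx) == 0L) return(NULL)
  d <- dim(bladder_mask)
  list(lo = pmax(apply(idx, 2, min) - pad, 1L),
       hi = pmin(apply(idx, 2, max) + pad, d))
}

write_case <- function(case, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- case$truth
  grid <- pet_grid(case$params)
  msk <- function(m) image3d(m + 0, grid$spacing_mm, grid$origin_mm,
                             grid$direction, "none")
  write_image(msk(tr$vt_mask), file.path(output_dir, "truth_vt.nii.gz"),
              overwrite = TRUE)
  write_image(msk(tr$v1_mask), file.path(output_dir, "truth_v1.nii.gz"),
              overwrite = TRUE)
  write_image(msk(tr$v2_mask), file.path(output_dir, "truth_v2.nii.gz"),
              overwrite = TRUE)
  if (!is.null(case$baseline)) {
    write_image(case$baseline$pet, file.path(output_dir, "pet1.nii.gz"),
                overwrite = TRUE)
    write_image(case$baseline$ct, file.path(output_dir, "ct1.nii.gz"),
                overwrite = TRUE)
    write_image(case$recurrence$pet, file.path(output_dir, "pet2.nii.gz"),
                overwrite = TRUE)
    write_image(case$recurrence$ct, file.path(output_dir, "ct2.nii.gz"),
                overwrite = TRUE)
  }
  write_transform(tr$true_transform,
                  file.path(output_dir, "true_transform.json"))
  jsonlite::write_json(
    list(seed = case$seed, vt_cc = tr$vt_cc, v1_cc = tr$v1_cc,
         v2_cc = tr$v2_cc, v2_gt_v1 = tr$v2_gt_v1,
         achieved_x = tr$achieved_x, achieved_y = tr$achieved_y,
         achieved_dice = tr$achieved_dice, achieved_of = tr$achieved_of,
         true_class_means = tr$true_class_means,
         true_class_sds = tr$true_class_sds),
    file.path(output_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Generate a synthetic cohort
#'
#' Per-case parameters are drawn from distributions matched to the cohort
#' statistics being emulated: log-normal whole-tumor volumes (mean 41.9,
#' SD 31.6 cm^3), a uniform high-uptake fraction around 0.43, and uniform
#' overlap targets in subgroup-specific bands. The V2>V1 subgroup is a
#' configured composition: exactly `round(n * v2_gt_v1_fraction)` cases
#' draw targets with Y < X (hence |V2| > |V1|), shuffled over case order.
#'
#' @param n number of cases (>= 1).
#' @param cohort_params list of overrides: `v2_gt_v1_fraction` (default
#'   1/3), `vt_mean_cc`/`vt_sd_cc`, `v1_fraction_range`, `base_params`
#'   (a [phantom_params()] template).
#' @param seed cohort seed.
#' @param materialize `"truth"` (default; ground truth only) or `"full"`
#'   (also synthesize all images).
#' @param output_dir optional directory for per-case NIfTI output and a
#'   cohort `manifest.json`.
#' @return list with `cases` (each a [generate_case()] result) and
#'   `manifest` (one row per case: seed, drawn parameters, ground-truth
#'   volumes, overlap indices and the V2>V1 flag).
#' @export
generate_cohort <- function(n, cohort_params = list(), seed = 1L,
                            materialize = c("truth", "full"),
                            output_dir = NULL) {
  materialize <- match.arg(materialize)
  if (!is_scalar_num(n) || n < 1) stopf("n must be a positive integer")
  n <- as.integer(n)
  cp <- cohort_params
  frac <- cp$v2_gt_v1_fraction %||% (1 / 3)
  vt_mean <- cp$vt_mean_cc %||% 41.9
  vt_sd <- cp$vt_sd_cc %||% 31.6
  v1f_range <- cp$v1_fraction_range %||% c(0.35, 0.52)
  base <- cp$base_params %||% phantom_params()

  sdlog <- sqrt(log(1 + (vt_sd / vt_mean)^2))
  meanlog <- log(vt_mean) - sdlog^2 / 2
  n_gt <- round(n * frac)
  draws <- with_seed(sub_seed(seed, 1L), {
    gt_flag <- rep(FALSE, n)
    gt_flag[sample.int(n, n_gt)] <- TRUE
    data.frame(
      case = seq_len(n),
      vt_cc = pmin(pmax(rlnorm(n, meanlog, sdlog), 10), 160),
      v1_fraction = runif(n, v1f_range[1], v1f_range[2]),
      v2_gt_v1_target = gt_flag,
      x_target = ifelse(gt_flag, runif(n, 0.75, 0.95),
                        runif(n, 0.51, 0.71)),
      y_target = ifelse(gt_flag, runif(n, 0.50, 0.70),
                        runif(n, 0.72, 0.95)),
      tx = runif(n, -8, 8), ty = runif(n, -8, 8), tz = runif(n, -8, 8),
      rx = runif(n, -5, 5), ry = runif(n, -5, 5), rz = runif(n, -5, 5),
      bladder_fill_delta = runif(n, -0.3, 0.5))
  })
  draws$seed <- vapply(seq_len(n), function(i) sub_seed(seed, 100L + i), 1L)

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    pi_ <- base
    pi_$vt_target_cc <- draws$vt_cc[i]
    pi_$v1_fraction <- draws$v1_fraction[i]
    pi_$overlap_target_x <- draws$x_target[i]
    pi_$overlap_target_y <- draws$y_target[i]
    pi_$misalign_translation_mm <- c(draws$tx[i], draws$ty[i], draws$tz[i])
    pi_$misalign_rotation_deg <- c(draws$rx[i], draws$ry[i], draws$rz[i])
    pi_$bladder_fill_delta <- draws$bladder_fill_delta[i]
    pi_$seed <- draws$seed[i]
    od <- if (is.null(output_dir)) NULL else
      file.path(output_dir, sprintf("case_%03d", i))
    cases[[i]] <- generate_case(pi_, seed = draws$seed[i],
                                materialize = materialize, output_dir = od)
  }
  draws$vt_truth_cc <- vapply(cases, function(cs) cs$truth$vt_cc, 0)
  draws$v1_truth_cc <- vapply(cases, function(cs) cs$truth$v1_cc, 0)
  draws$v2_truth_cc <- vapply(cases, function(cs) cs$truth$v2_cc, 0)
  draws$v2_gt_v1 <- vapply(cases, function(cs) cs$truth$v2_gt_v1, TRUE)
  draws$achieved_x <- vapply(cases, function(cs) cs$truth$achieved_x, 0)
  draws$achieved_y <- vapply(cases, function(cs) cs$truth$achieved_y, 0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(seed = seed, n = n, manifest = draws),
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cases = cases, manifest = draws)
}
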