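# FLAB-style segmentation: a finite Gaussian mixture over hard tissue
# classes augmented with discrete fuzzy transition levels between adjacent
# classes, fitted by a deterministic EM-like scheme under a spatially
# adaptive (locally averaged) prior field. Three classes on baseline PET
# jointly delineate the whole tumor (VT) and its high-uptake core (V1);
# two classes on recurrence PET delineate V2.

# Normalize an exclusion specification (roi_box or logical array) to a
# logical full-grid array.
as_exclusion_array <- function(exclude, dims) {
  if (is.null(exclude)) return(NULL)
  if (inherits(exclude, "roi_box")) {
    ex <- array(FALSE, dims)
    ex[exclude$lo[1]:exclude$hi[1], exclude$lo[2]:exclude$hi[2],
       exclude$lo[3]:exclude$hi[3]] <- TRUE
    return(ex)
  }
  if (is.array(exclude) && identical(dim(exclude), as.integer(dims)))
    return(exclude != 0)
  stopf("exclusion must be a roi_box or a logical array on the image grid")
}

#' Data-derived bladder exclusion mask
#'
#' Urine is by far the hottest structure in the pelvis on FDG-PET, so
#' the bladder can be masked out directly from the image: voxels above
#' `threshold_suv` (default 20, well above tumor uptake), dilated by
#' `dilate_mm` to cover partial-volume spill. Returns NULL when nothing
#' exceeds the threshold.
#'
#' @param img [image3d] in SUV.
#' @param threshold_suv urine detection threshold.
#' @param dilate_mm isotropic dilation of the detected region.
#' @return logical full-grid array, or NULL.
#' @export
bladder_exclusion_from_pet <- function(img, threshold_suv = 20,
                                       dilate_mm = 8) {
  stopifnot(inherits(img, "image3d"))
  hot <- img$values > threshold_suv
  if (!any(hot)) return(NULL)
  r <- pmax(1L, as.integer(ceiling(dilate_mm / img$spacing_mm)))
  idx <- which(hot, arr.ind = TRUE)
  out <- array(FALSE, dim(img$values))
  sp <- img$spacing_mm
  # Euclidean-ball dilation via shifted assignment
  for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
    if ((dx * sp[1])^2 + (dy * sp[2])^2 + (dz * sp[3])^2 > dilate_mm^2)
      next
    ii <- idx[, 1] + dx; jj <- idx[, 2] + dy; kk <- idx[, 3] + dz
    ok <- ii >= 1 & jj >= 1 & kk >= 1 & ii <= dim(out)[1] &
      jj <= dim(out)[2] & kk <= dim(out)[3]
    out[cbind(ii[ok], jj[ok], kk[ok])] <- TRUE
  }
  out
}

#' Rectangular region of interest
#'
#' 1-based inclusive voxel index bounds of a box ROI.
#'
#' @param lo,hi integer length-3 lower/upper corners (1-based, inclusive).
#' @return object of class `roi_box`.
#' @export
roi_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(hi < lo))
    stopf("roi_box needs lo <= hi on all three axes")
  if (any(hi - lo + 1L < 3L))
    stopf("ROI must span at least 3 voxels per axis")
  structure(list(lo = lo, hi = hi), class = "roi_box")
}

roi_dims <- function(roi) roi$hi - roi$lo + 1L

roi_values <- function(arr, roi) {
  arr[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2], roi$lo[3]:roi$hi[3]]
}

#' Select a tumor-bearing box ROI on a PET image
#'
#' `mode = "auto"`: bounding box of the largest connected component of
#' voxels above `threshold_suv` (default 2.5 SUV), dilated by `dilate`
#' voxels, after zeroing an optional bladder-exclusion box.
#' `mode = "box"`: validate and return a user-supplied [roi_box()].
#'
#' @param img [image3d] in SUV.
#' @param mode `"auto"` or `"box"`.
#' @param box user [roi_box()] (mode `"box"`).
#' @param threshold_suv uptake threshold for the auto mode.
#' @param exclude_box optional [roi_box()] or logical full-grid array
#'   (e.g. around the bladder) whose voxels are ignored by the auto mode.
#' @param dilate dilation of the auto bounding box, in voxels.
#' @return a [roi_box()].
#' @export
select_roi <- function(img, mode = c("auto", "box"), box = NULL,
                       threshold_suv = 2.5, exclude_box = NULL,
                       dilate = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "image3d"))
  if (img$units != "SUV") stopf("ROI selection expects an SUV image")
  if (mode == "box") {
    if (is.null(box)) stopf("mode 'box' needs a roi_box")
    stopifnot(inherits(box, "roi_box"))
    if (any(box$hi > dim(img$values))) stopf("ROI exceeds the image grid")
    return(box)
  }
  hot <- img$values > threshold_suv
  ex <- as_exclusion_array(exclude_box, dim(img$values))
  if (!is.null(ex)) hot[ex] <- FALSE
  if (!any(hot)) stopf("no uptake above threshold %.2f SUV", threshold_suv)
  lab <- cpp_connected_components(hot, dim(img$values))
  ncomp <- attr(lab, "ncomp")
  sizes <- tabulate(lab, nbins = ncomp)
  comp <- which.max(sizes)
  idx <- which(array(lab, dim(img$values)) == comp, arr.ind = TRUE)
  roi_box(pmax(apply(idx, 2, min) - dilate, 1L),
          pmin(apply(idx, 2, max) + dilate, dim(img$values)))
}

#' Deterministic quantile initialization of class parameters
#'
#' Means at the 25/75% (K = 2) or 25/60/95% (K = 3) intensity quantiles;
#' SDs at the ROI standard deviation divided by K.
#'
#' @param y numeric intensities in the ROI.
#' @param k number of hard classes (2 or 3).
#' @return list with `means` (ascending) and `sds`.
#' @export
init_params <- function(y, k) {
  if (!k %in% 2:3) stopf("k must be 2 or 3")
  if (length(y) < 10 * k)
    stopf("ROI too small: %d voxels for %d classes (need >= %d)",
          length(y), k, 10 * k)
  if (diff(range(y)) == 0)
    stopf("constant intensities in ROI: segmentation is degenerate")
  probs <- if (k == 2L) c(0.25, 0.75) else c(0.25, 0.60, 0.95)
  means <- as.numeric(quantile(y, probs, names = FALSE))
  rng <- range(y)
  if (any(diff(means) < 1e-3 * diff(rng))) {
    # Quantile anchors coincide when one class dominates the ROI (e.g.
    # a small tumor in a large background box); fall back to anchors
    # spread evenly over the occupied intensity range.
    means <- rng[1] + (seq_len(k) - 0.5) / k * diff(rng)
  }
  list(means = means, sds = rep(sd(y) / k, k))
}

# Label table: k hard classes plus the fuzzy levels between each adjacent
# pair. Columns: id, type, k_lo, k_hi, eps.
flab_label_table <- function(k, fuzzy_levels = c(0.25, 0.5, 0.75)) {
  hard <- data.frame(type = "hard", k_lo = seq_len(k), k_hi = seq_len(k),
                     eps = NA_real_)
  fz <- do.call(rbind, lapply(seq_len(k - 1), function(kk)
    data.frame(type = "fuzzy", k_lo = kk, k_hi = kk + 1,
               eps = fuzzy_levels)))
  tab <- rbind(hard, fz)
  tab$id <- seq_len(nrow(tab))
  tab
}

# Per-label Gaussian moments implied by the class parameters.
label_moments <- function(tab, means, sds) {
  hard <- tab$type == "hard"
  mu <- se <- numeric(nrow(tab))
  mu[hard] <- means[tab$k_lo[hard]]
  se[hard] <- sds[tab$k_lo[hard]]
  e <- tab$eps[!hard]
  lo <- tab$k_lo[!hard]; hi <- tab$k_hi[!hard]
  mu[!hard] <- (1 - e) * means[lo] + e * means[hi]
  se[!hard] <- sqrt((1 - e)^2 * sds[lo]^2 + e^2 * sds[hi]^2)
  list(mu = mu, sd = se)
}

#' Observation density of a FLAB label
#'
#' Hard class k: Normal(mu_k, sigma_k^2). Fuzzy level eps between classes
#' (k, k+1): Normal((1-eps) mu_k + eps mu_{k+1},
#' (1-eps)^2 sigma_k^2 + eps^2 sigma_{k+1}^2).
#'
#' @param y numeric intensities.
#' @param label a one-row label descriptor (list/row with `type`, `k_lo`,
#'   `k_hi`, `eps`).
#' @param model list with `means` and `sds` (class parameters, ascending).
#' @return density values, strictly positive and finite.
#' @export
label_density <- function(y, label, model) {
  if (identical(label$type, "hard")) {
    mu <- model$means[label$k_lo]
    s <- model$sds[label$k_lo]
  } else {
    e <- label$eps
    mu <- (1 - e) * model$means[label$k_lo] + e * model$means[label$k_hi]
    s <- sqrt((1 - e)^2 * model$sds[label$k_lo]^2 +
                e^2 * model$sds[label$k_hi]^2)
  }
  pmax(dnorm(y, mu, s), .Machine$double.xmin)
}

#' Spatially adaptive prior field
#'
#' Per-voxel label prior: `(1 - lambda)` times the mean posterior over
#' the 3x3x3 neighbourhood plus `lambda` times the global label
#' frequencies, renormalized. This local averaging is what adapts the
#' segmentation to the spatial context of each voxel.
#'
#' @param post n x L posterior matrix (rows sum to 1) over an ROI.
#' @param roi_dim length-3 voxel dimensions of the ROI.
#' @param lambda global-blend weight (default 0.1).
#' @return n x L prior matrix, rows summing to 1.
#' @export
estimate_local_priors <- function(post, roi_dim, lambda = 0.1) {
  L <- ncol(post)
  glob <- colMeans(post)
  pr <- matrix(0, nrow(post), L)
  for (l in seq_len(L)) {
    sm <- cpp_boxmean3(post[, l], as.integer(roi_dim))
    pr[, l] <- (1 - lambda) * sm + lambda * glob[l]
  }
  pr / rowSums(pr)
}

#' Fit a FLAB-style mixture segmentation
#'
#' Iterates posterior computation (label density times spatial prior),
#' posterior-weighted re-estimation of class means/SDs (each fuzzy label
#' contributing weight `1 - eps` to its lower class and `eps` to its
#' upper class), and prior re-estimation, until the maximum relative
#' change in class means falls below `tol` or `max_iter` iterations. The
#' final per-voxel label is the maximum-posterior label. Deterministic.
#'
#' @param x [image3d] (SUV) or numeric 3-D array.
#' @param roi [roi_box()]; default is the whole array.
#' @param k number of hard classes: 3 for baseline (background, tumor,
#'   high-uptake core), 2 for recurrence (background, tumor).
#' @param exclude optional [roi_box()] (or logical full-grid array) of
#'   voxels to hold out of the fit, e.g. an operator-drawn box around
#'   the bladder; held-out voxels are fixed to the background class and
#'   never enter the parameter estimates or the output masks.
#' @param fuzzy_levels ordered fuzzy levels in (0, 1) per adjacent pair.
#'   The default ladder of 7 levels is fine enough to absorb the
#'   partial-volume transition between classes; a coarser ladder lets
#'   transition voxels leak into the hard classes, inflating their
#'   fitted SDs and biasing the derived volumes outward.
#' @param lambda spatial-prior global-blend weight.
#' @param tol convergence tolerance on the relative change of the means.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return an object of class `flab` with components `means`, `sds`
#'   (ascending class parameters), `labels` (label table with fitted
#'   moments), `label_map` (integer array of final label ids over the
#'   ROI), `posterior`, `prior`, `convergence`, `roi`, `data`.
#' @seealso [masks_from_segmentation()], [flab_segment()]
#' @examples
#' set.seed(1)
#' arr <- array(rnorm(20^3, 2, 0.3), c(20, 20, 20))
#' arr[8:13, 8:13, 8:13] <- rnorm(6^3, 8, 0.5)
#' fit <- flab(arr, k = 2)
#' coef(fit)
#' @export
flab <- function(x, roi = NULL, k = 3, exclude = NULL,
                 fuzzy_levels = seq(0.125, 0.875, by = 0.125),
                 lambda = 0.1, tol = 1e-3, max_iter = 100L) {
  arr <- if (inherits(x, "image3d")) x$values else x
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stopf("`x` must be an image3d or a 3-D array")
  if (!k %in% 2:3) stopf("k must be 2 or 3")
  if (any(fuzzy_levels <= 0 | fuzzy_levels >= 1))
    stopf("fuzzy levels must lie strictly inside (0, 1)")
  if (is.null(roi)) roi <- roi_box(c(1, 1, 1), dim(arr))
  stopifnot(inherits(roi, "roi_box"))
  if (any(roi$hi > dim(arr))) stopf("ROI exceeds the image grid")
  rd <- roi_dims(roi)
  yarr <- roi_values(arr, roi)
  y <- as.numeric(yarr)
  keep <- rep(TRUE, length(y))
  exarr <- as_exclusion_array(exclude, dim(arr))
  if (!is.null(exarr)) {
    keep <- !as.logical(roi_values(exarr, roi))
    if (!any(keep)) stopf("exclusion removes the whole ROI")
  }

  ini <- init_params(y[keep], k)
  means <- ini$means
  sds <- ini$sds
  sd_floor <- max(1e-3 * diff(range(y)), 1e-12)
  sds <- pmax(sds, sd_floor)
  tab <- flab_label_table(k, fuzzy_levels)
  L <- nrow(tab)
  W <- membership_weights(tab, k)
  prior <- matrix(1 / L, length(y), L)
  post <- prior
  it <- 0L
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    mom <- label_moments(tab, means, sds)
    dens <- vapply(seq_len(L), function(l)
      pmax(dnorm(y, mom$mu[l], mom$sd[l]), .Machine$double.xmin),
      numeric(length(y)))
    post <- prior * dens
    rs <- rowSums(post)
    bad <- rs <= 0 | !is.finite(rs)
    if (any(bad)) {
      post[bad, ] <- 1 / L
      rs[bad] <- 1
    }
    post <- post / rs
    if (!all(keep)) {                     # held-out voxels: fixed background
      post[!keep, ] <- 0
      post[!keep, 1] <- 1
    }
    cw <- post[keep, , drop = FALSE] %*% W   # class weights, fitted voxels
    wsum <- colSums(cw)
    if (any(wsum < 10))
      stopf(paste("class %d collapsed (weight %.1f voxels);",
                  "consider reducing k"),
            which.min(wsum), min(wsum))
    new_means <- as.numeric(crossprod(cw, y[keep]) / wsum)
    ord <- order(new_means)
    new_means <- new_means[ord]
    cw <- cw[, ord, drop = FALSE]
    wsum <- wsum[ord]
    new_sds <- sqrt(vapply(seq_len(k), function(kk)
      sum(cw[, kk] * (y[keep] - new_means[kk])^2) / wsum[kk], 0))
    new_sds <- pmax(new_sds, sd_floor)
    delta <- max(abs(new_means - means) / pmax(abs(means), 1e-9))
    means <- new_means
    sds <- new_sds
    prior <- estimate_local_priors(post, rd, lambda)
    if (delta < tol) break
  }
  converged <- delta < tol
  if (!converged)
    warning(sprintf("FLAB did not converge in %d iterations (delta %.2g)",
                    max_iter, delta), call. = FALSE)
  mom <- label_moments(tab, means, sds)
  tab$mu <- mom$mu
  tab$sd <- mom$sd
  label_map <- array(tab$id[max.col(post, ties.method = "first")], rd)
  structure(list(
    means = means, sds = sds, k = k, labels = tab,
    label_map = label_map, posterior = post, prior = prior,
    convergence = list(iterations = it, delta = delta,
                       converged = converged, tol = tol),
    keep = keep, roi = roi, dim = dim(arr),
    grid = if (inherits(x, "image3d")) grid_of(x) else NULL,
    data = y, call = match.call()),
    class = "flab")
}

#' Derive binary masks from a fitted segmentation
#'
#' Mask membership is decided per voxel from its posterior-mean class
#' membership (each fuzzy level at `eps` carries membership `eps` to its
#' upper class and `1 - eps` to its lower class). 3-class fits: VT is
#' the set with combined class-2 plus class-3 membership of at least
#' 0.5 (equivalently: classes 2 and 3, all fuzzy(2,3) levels, and the
#' background transition at fuzzy membership >= 0.5); V1 is the set with
#' class-3 membership of at least 0.5, so V1 is a subset of VT by
#' construction. 2-class fits: V2 is the set with class-2 membership of
#' at least 0.5. Only the connected component containing the ROI seed
#' (default: the hottest ROI voxel) is retained.
#'
#' For 2-class fits the tumor-class mean is peak-referenced before the
#' membership cut (`plateau_correct`): a small hot structure under the
#' scanner PSF has an attenuated interior, which drags the fitted class
#' mean below the true plateau and pushes the half-membership contour
#' outward; re-evaluating the memberships with the class mean set to a
#' high quantile (0.85) of the class's own voxels removes most of that
#' outward bias. On noise-free or unblurred data the quantile equals the
#' fitted mean and the correction is a no-op.
#'
#' @param fit a [flab()] object.
#' @param seed_point optional 1-based voxel index (length 3, full-grid
#'   coordinates) used to pick the connected component.
#' @param plateau_correct peak-reference the top class before cutting;
#'   default: on for 2-class fits, off for 3-class fits (whose larger
#'   delineated structures showed no such bias on phantoms).
#' @return named list of logical full-grid arrays: `vt`, `v1` (k = 3) or
#'   `v2` (k = 2).
#' @export
masks_from_segmentation <- function(fit, seed_point = NULL,
                                    plateau_correct = NULL) {
  stopifnot(inherits(fit, "flab"))
  tab <- fit$labels
  W <- membership_weights(tab, fit$k)
  member <- fit$posterior %*% W        # n x k posterior-mean membership
  if (plateau_correct %||% (fit$k == 2L)) {
    sel <- member[, fit$k] >= 0.5 & fit$keep
    if (sum(sel) >= 20) {
      m_star <- as.numeric(quantile(fit$data[sel], 0.85))
      if (m_star > fit$means[fit$k]) {
        means2 <- fit$means
        means2[fit$k] <- m_star
        mom <- label_moments(tab, means2, fit$sds)
        dens <- vapply(seq_len(nrow(tab)), function(l)
          pmax(dnorm(fit$data, mom$mu[l], mom$sd[l]),
               .Machine$double.xmin), numeric(length(fit$data)))
        post <- fit$prior * dens
        post <- post / rowSums(post)
        post[!fit$keep, ] <- 0
        post[!fit$keep, 1] <- 1
        member <- post %*% W
      }
    }
  }
  pick <- function(w) {
    m <- array(FALSE, fit$dim)
    m[fit$roi$lo[1]:fit$roi$hi[1], fit$roi$lo[2]:fit$roi$hi[2],
      fit$roi$lo[3]:fit$roi$hi[3]] <- array(w >= 0.5, roi_dims(fit$roi))
    m
  }
  if (is.null(seed_point)) {
    y_seed <- fit$data
    y_seed[!fit$keep] <- -Inf
    roi_idx <- which.max(y_seed)
    loc <- arrayInd(roi_idx, roi_dims(fit$roi))
    seed_point <- as.integer(loc) + fit$roi$lo - 1L
  }
  keep_component <- function(mask) {
    if (!any(mask)) stopf("segmentation produced an empty mask")
    lab <- array(cpp_connected_components(mask, dim(mask)), dim(mask))
    comp <- lab[seed_point[1], seed_point[2], seed_point[3]]
    if (comp == 0L) {
      sizes <- tabulate(lab, nbins = max(lab))
      comp <- which.max(sizes)
    }
    lab == comp
  }
  if (fit$k == 3L) {
    vt <- keep_component(pick(member[, 2] + member[, 3]))
    v1 <- pick(member[, 3]) & vt
    if (!any(v1)) stopf("segmentation produced an empty high-uptake mask")
    v1 <- keep_component(v1)
    list(vt = vt, v1 = v1)
  } else {
    v2 <- keep_component(pick(member[, 2]))
    list(v2 = v2)
  }
}

# Class-membership weight each label carries (L x k): hard labels belong
# wholly to their class, fuzzy labels split eps / 1 - eps between their
# adjacent classes.
membership_weights <- function(tab, k) {
  W <- matrix(0, nrow(tab), k)
  for (l in seq_len(nrow(tab))) {
    if (tab$type[l] == "hard") W[l, tab$k_lo[l]] <- 1
    else {
      W[l, tab$k_lo[l]] <- 1 - tab$eps[l]
      W[l, tab$k_hi[l]] <- tab$eps[l]
    }
  }
  W
}

#' One-call FLAB segmentation of an image
#'
#' Convenience wrapper: fit [flab()] inside `roi` and derive the binary
#' masks; 3-class fits return VT and V1, 2-class fits return V2.
#'
#' @inheritParams flab
#' @param ... further arguments passed to [flab()].
#' @return list with `fit` (the [flab()] object) and `masks`.
#' @export
flab_segment <- function(x, roi = NULL, k = 3, ...) {
  fit <- flab(x, roi = roi, k = k, ...)
  list(fit = fit, masks = masks_from_segmentation(fit))
}

#' Fixed percent-SUVmax threshold segmentation
#'
#' The fixed-threshold comparator: voxels in the ROI at or above
#' `pct / 100` of the ROI SUVmax; the largest connected component is
#' retained. This is the approach whose overlap estimates the
#' FLAB-based pipeline is designed to improve upon.
#'
#' @param img [image3d] in SUV.
#' @param roi [roi_box()].
#' @param pct_of_suvmax threshold percentage in (0, 100).
#' @param exclude optional [roi_box()] or logical full-grid array ignored
#'   by the thresholding (e.g. the bladder).
#' @return logical full-grid mask.
#' @export
threshold_segment <- function(img, roi, pct_of_suvmax, exclude = NULL) {
  stopifnot(inherits(img, "image3d"), inherits(roi, "roi_box"))
  if (!is_scalar_num(pct_of_suvmax) || pct_of_suvmax <= 0 ||
      pct_of_suvmax >= 100)
    stopf("pct_of_suvmax must be in (0, 100)")
  yroi <- roi_values(img$values, roi)
  exarr <- as_exclusion_array(exclude, dim(img$values))
  if (!is.null(exarr)) yroi[as.logical(roi_values(exarr, roi))] <- -Inf
  thr <- pct_of_suvmax / 100 * max(yroi)
  mask <- array(FALSE, dim(img$values))
  mask[roi$lo[1]:roi$hi[1], roi$lo[2]:roi$hi[2], roi$lo[3]:roi$hi[3]] <-
    yroi >= thr
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) stopf("threshold produced an empty mask")
  lab <- array(cpp_connected_components(mask, dim(mask)), dim(mask))
  sizes <- tabulate(lab, nbins = max(lab))
  lab == which.max(sizes)
}
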