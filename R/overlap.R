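# Overlap quantification between the baseline high-uptake sub-volume (V1)
# and the recurrence volume (V2): Dice, overlap fraction, X and Y, with
# concordance bands, SUV statistics and cohort summaries.

#' Overlap indices between two masks
#'
#' Voxel-count set arithmetic on a common grid:
#' \deqn{Dice = 2|V1 \cap V2| / (|V1| + |V2|)}
#' \deqn{OF = |V1 \cap V2| / \min(|V1|, |V2|)}
#' \deqn{X = |V1 \cap V2| / |V1|, \quad Y = |V1 \cap V2| / |V2|}
#' Volumes are voxel counts times the voxel volume in cm^3. The result
#' also carries the concordance band of each index and the V2 > V1 flag
#' (cases where the recurrence volume exceeds the baseline high-uptake
#' sub-volume, for which overlap analysis is considered unreliable and
#' which cohort summaries can exclude).
#'
#' @param v1_mask,v2_mask logical arrays on the same grid, both non-empty.
#' @param spacing_mm per-axis voxel size in mm (or an [image3d] to take
#'   it from).
#' @return object of class `overlap_result`: volumes (`vol_v1_cc`,
#'   `vol_v2_cc`, `vol_intersection_cc`), indices (`dice`, `of`, `x`,
#'   `y`), `band` per index, `v2_gt_v1`.
#' @examples
#' a <- array(FALSE, c(8, 8, 8)); b <- a
#' a[1:4, , ] <- TRUE; b[3:6, , ] <- TRUE
#' overlap_metrics(a, b, spacing_mm = c(4, 4, 4))
#' @export
overlap_metrics <- function(v1_mask, v2_mask, spacing_mm) {
  if (!identical(dim(v1_mask), dim(v2_mask)))
    stopf("masks are on different grids")
  n1 <- sum(v1_mask)
  n2 <- sum(v2_mask)
  if (n1 == 0L || n2 == 0L)
    stopf("overlap indices are undefined for an empty mask")
  if (inherits(spacing_mm, "image3d")) spacing_mm <- spacing_mm$spacing_mm
  vox_cc <- prod(spacing_mm) / 1000
  ni <- sum(v1_mask & v2_mask)
  res <- list(
    vol_v1_cc = n1 * vox_cc,
    vol_v2_cc = n2 * vox_cc,
    vol_intersection_cc = ni * vox_cc,
    dice = 2 * ni / (n1 + n2),
    of = ni / min(n1, n2),
    x = ni / n1,
    y = ni / n2,
    v2_gt_v1 = n2 > n1)
  res$band <- vapply(res[c("dice", "of", "x", "y")],
                     classify_concordance, "")
  structure(res, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("V1 %.2f cc, V2 %.2f cc, intersection %.2f cc%s\n",
              x$vol_v1_cc, x$vol_v2_cc, x$vol_intersection_cc,
              if (x$v2_gt_v1) "  [V2 > V1]" else ""))
  for (m in c("dice", "of", "x", "y"))
    cat(sprintf("  %-4s %.2f (%s)\n", toupper(m), round(x[[m]], 2),
                x$band[[m]]))
  invisible(x)
}

#' Concordance band of an overlap index
#'
#' The value is rounded to 2 decimals and banded: 0-0.20 very low,
#' 0.21-0.40 low, 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00 very
#' good. Rounding first closes the gaps between the printed band edges.
#'
#' @param value overlap index in `[0, 1]`.
#' @return band label (character).
#' @export
classify_concordance <- function(value) {
  if (!is_scalar_num(value) || value < 0 || value > 1)
    stopf("concordance is defined for values in [0, 1]")
  v <- round(value, 2)
  if (v <= 0.20) "very low"
  else if (v <= 0.40) "low"
  else if (v <= 0.60) "moderate"
  else if (v <= 0.80) "good"
  else "very good"
}

#' SUV statistics over a mask
#'
#' SUVmax, SUVmean and total lesion glycolysis
#' (TLG = SUVmean x volume in cm^3, reported in grams).
#'
#' @param img [image3d] in SUV.
#' @param mask non-empty logical array on the same grid.
#' @return list with `suv_max`, `suv_mean`, `volume_cc`, `tlg_g`.
#' @export
suv_stats <- function(img, mask) {
  stopifnot(inherits(img, "image3d"))
  if (!identical(dim(img$values), dim(mask)))
    stopf("mask is not on the image grid")
  if (!any(mask)) stopf("SUV statistics are undefined for an empty mask")
  vals <- img$values[mask]
  vol <- sum(mask) * voxel_volume_cc(img)
  list(suv_max = max(vals), suv_mean = mean(vals), volume_cc = vol,
       tlg_g = mean(vals) * vol)
}

#' Cohort summary of overlap results
#'
#' Median, range, mean and SD of each overlap index over three subgroup
#' views: all cases, cases with V2 <= V1, and cases with V2 > V1. The
#' V2 > V1 cases are the ones for which the overlap analysis is
#' considered unreliable; `exclude_v2_gt_v1` additionally drops them from
#' the `all` view.
#'
#' @param results list of [overlap_metrics()] results.
#' @param exclude_v2_gt_v1 drop flagged cases from the `all` view.
#' @return data.frame with one row per metric x subgroup: `subgroup`,
#'   `metric`, `n`, `median`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_cohort <- function(results, exclude_v2_gt_v1 = FALSE) {
  if (length(results) < 1L) stopf("no overlap results to summarize")
  flags <- vapply(results, function(r) isTRUE(r$v2_gt_v1), TRUE)
  views <- list(all = if (exclude_v2_gt_v1) which(!flags) else
                  seq_along(results),
                v2_le_v1 = which(!flags),
                v2_gt_v1 = which(flags))
  rows <- list()
  for (vn in names(views)) {
    sel <- views[[vn]]
    if (length(sel) == 0L) {
      if (vn == "all") stopf("no cases remain after exclusion")
      next
    }
    for (m in c("dice", "of", "x", "y")) {
      v <- vapply(results[sel], function(r) r[[m]], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = vn, metric = m, n = length(v), median = median(v),
        min = min(v), max = max(v), mean = mean(v),
        sd = if (length(v) > 1) sd(v) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Write per-case overlap results as CSV
#'
#' One row per case with volumes, the four indices, the V2>V1 flag and
#' the concordance band of each index.
#'
#' @param results list of [overlap_metrics()] results.
#' @param path output CSV path (optional).
#' @return the table, invisibly when written.
#' @export
overlap_table <- function(results, path = NULL) {
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(case_id = i, dice = r$dice, of = r$of, x = r$x, y = r$y,
               vol_v1_cc = r$vol_v1_cc, vol_v2_cc = r$vol_v2_cc,
               vol_intersection_cc = r$vol_intersection_cc,
               v2_gt_v1 = r$v2_gt_v1,
               band_dice = r$band[["dice"]], band_of = r$band[["of"]],
               band_x = r$band[["x"]], band_y = r$band[["y"]])
  }))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
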