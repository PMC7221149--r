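#' 6-parameter rigid transform
#'
#' Rigid map from recurrence (moving) space to baseline (fixed) space:
#' \deqn{T(x) = R (x - c) + c + t} with \eqn{R} built from three Euler
#' angles (intrinsic Z-Y-X order, degrees), translation \eqn{t} in mm and
#' rotation center \eqn{c} in mm.
#'
#' @param rotation_deg length-3 Euler angles (deg), intrinsic Z-Y-X.
#' @param translation_mm length-3 translation (mm).
#' @param center_mm length-3 rotation center (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  rotation_deg <- as.numeric(rotation_deg)
  translation_mm <- as.numeric(translation_mm)
  center_mm <- as.numeric(center_mm)
  if (length(rotation_deg) != 3L || any(!is.finite(rotation_deg)))
    stopf("rotation_deg must be 3 finite angles")
  if (length(translation_mm) != 3L || any(!is.finite(translation_mm)))
    stopf("translation_mm must be 3 finite numbers")
  if (length(center_mm) != 3L || any(!is.finite(center_mm)))
    stopf("center_mm must be 3 finite numbers")
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 center_mm = center_mm,
                 convention = "intrinsic-ZYX-deg"),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (%s) deg [%s], trans (%s) mm, center (%s) mm\n",
    paste(format(x$rotation_deg, digits = 4), collapse = ", "),
    x$convention,
    paste(format(x$translation_mm, digits = 4), collapse = ", "),
    paste(format(x$center_mm, digits = 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix_zyx <- function(deg) {
  r <- deg * pi / 180
  cz <- cos(r[3]); sz <- sin(r[3])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[1]); sx <- sin(r[1])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler Z-Y-X angles (deg) from a rotation matrix; assumes |pitch| < 90 deg,
# which holds for the small rotations of patient repositioning.
euler_zyx_from_matrix <- function(R) {
  b <- asin(-R[3, 1])
  a <- atan2(R[2, 1], R[1, 1])
  g <- atan2(R[3, 2], R[3, 3])
  c(g, b, a) * 180 / pi
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param t a [rigid_transform].
#' @return 4x4 matrix mapping homogeneous world points (mm).
#' @export
transform_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- rotation_matrix_zyx(t$rotation_deg)
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- t$center_mm - R %*% t$center_mm + t$translation_mm
  A
}

# Rebuild a rigid_transform from a 4x4 matrix, expressed about `center_mm`.
transform_from_matrix <- function(A, center_mm = c(0, 0, 0)) {
  R <- A[1:3, 1:3]
  rot <- euler_zyx_from_matrix(R)
  trans <- A[1:3, 4] - center_mm + R %*% center_mm
  rigid_transform(rot, as.numeric(trans), center_mm)
}

#' Invert a rigid transform
#' @param t a [rigid_transform].
#' @return the inverse transform (same rotation center).
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- rotation_matrix_zyx(t$rotation_deg)
  Rt <- base::t(R)
  rigid_transform(euler_zyx_from_matrix(Rt),
                  as.numeric(-Rt %*% t$translation_mm),
                  t$center_mm)
}

#' Compose two rigid transforms
#'
#' Returns `correction` applied after `base` (`correction o base`),
#' expressed about the rotation center of `base`. Used to apply an
#' operator-supplied manual correction on top of the automatic
#' registration result.
#'
#' @param correction,base [rigid_transform]s with the same convention.
#' @return the composed [rigid_transform].
#' @export
compose_transforms <- function(correction, base) {
  stopifnot(inherits(correction, "rigid_transform"),
            inherits(base, "rigid_transform"))
  if (!identical(correction$convention, base$convention))
    stopf("transform conventions differ")
  transform_from_matrix(transform_matrix(correction) %*%
                          transform_matrix(base),
                        center_mm = base$center_mm)
}

#' Apply a rigid transform to world points
#' @param t a [rigid_transform].
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of mapped points.
#' @export
transform_points <- function(t, pts) {
  A <- transform_matrix(t)
  pts <- cbind(pts, 1) %*% base::t(A)
  pts[, 1:3, drop = FALSE]
}

#' Target registration error between two transforms
#'
#' Mean Euclidean discrepancy, over the world coordinates of the ROI
#' voxel centers, between the mappings of the true and estimated
#' transforms.
#'
#' @param truth,estimate [rigid_transform]s (moving -> fixed).
#' @param roi_mask logical array of ROI voxels on the fixed grid.
#' @param grid_img [image3d] supplying the fixed-grid geometry.
#' @return scalar TRE in mm.
#' @export
registration_error <- function(truth, estimate, roi_mask, grid_img) {
  idx <- mask_indices(roi_mask)
  if (nrow(idx) == 0L) stopf("ROI mask is empty")
  pts <- index_to_world(grid_img, idx)
  d <- transform_points(invert_transform(truth), pts) -
    transform_points(invert_transform(estimate), pts)
  mean(sqrt(rowSums(d^2)))
}

#' Write / read a rigid transform as JSON
#'
#' The file stores the Euler angles, translation, center, convention tag
#' and the equivalent 4x4 homogeneous matrix.
#'
#' @param t a [rigid_transform].
#' @param path JSON file path.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(
    list(rotation_deg = t$rotation_deg, translation_mm = t$translation_mm,
         center_mm = t$center_mm, convention = t$convention,
         matrix = transform_matrix(t)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$rotation_deg))
    return(rigid_transform(x$rotation_deg, x$translation_mm, x$center_mm))
  if (!is.null(x$matrix))
    return(transform_from_matrix(matrix(unlist(x$matrix), 4, 4)))
  stopf("'%s' does not contain a rigid transform", path)
}
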