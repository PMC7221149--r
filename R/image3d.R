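#' 3-D scalar image with voxel grid geometry
#'
#' Container for a 3-D volume (PET, CT, or mask) together with its voxel
#' grid geometry: per-axis spacing in mm, world origin in mm, a 3x3
#' orthonormal direction matrix, and a unit tag. World coordinates of the
#' 0-based voxel index \eqn{(i,j,k)} are
#' \eqn{origin + direction \%*\% (spacing * (i,j,k))}, i.e. the NIfTI affine
#' convention.
#'
#' @param values numeric 3-D array of voxel values.
#' @param spacing_mm positive length-3 numeric, voxel size per axis (mm).
#' @param origin_mm length-3 numeric, world position of voxel (0,0,0) (mm).
#' @param direction 3x3 orthonormal matrix of axis directions.
#' @param units one of `"SUV"`, `"HU"`, `"Bq_per_mL"`, `"none"`.
#' @return An object of class `image3d`.
#' @examples
#' img <- image3d(array(0, c(16, 16, 16)), spacing_mm = c(4, 4, 4))
#' voxel_volume_cc(img)
#' @export
image3d <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                    direction = diag(3),
                    units = c("none", "SUV", "HU", "Bq_per_mL")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("`values` must be a 3-D array, got %d dimension(s)",
          length(dim(values)))
  if (length(values) == 0L) stopf("`values` must be non-empty")
  if (!all(is.finite(values))) stopf("`values` must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stopf("`spacing_mm` must be 3 strictly positive numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stopf("`origin_mm` must be 3 finite numbers")
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stopf("`direction` must be orthonormal within 1e-6")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, direction = direction,
                 units = units),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image3d> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 3), collapse = " x "),
              x$units))
  cat(sprintf("  origin (%s) mm; value range [%.3g, %.3g]\n",
              paste(format(x$origin_mm, digits = 4), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$values)

#' Voxel volume in cubic centimetres
#'
#' @param x an `image3d` or a length-3 spacing vector in mm.
#' @return scalar voxel volume in cm^3.
#' @export
voxel_volume_cc <- function(x) {
  sp <- if (inherits(x, "image3d")) x$spacing_mm else as.numeric(x)
  prod(sp) / 1000
}

# 4x4 homogeneous voxel-index (0-based) -> world (mm) affine of an image.
grid_affine <- function(img) {
  A <- diag(4)
  A[1:3, 1:3] <- img$direction %*% diag(img$spacing_mm)
  A[1:3, 4] <- img$origin_mm
  A
}

# Geometry-only description of a grid, used as a resampling target.
grid_of <- function(img) {
  list(dim = dim(img$values), spacing_mm = img$spacing_mm,
       origin_mm = img$origin_mm, direction = img$direction)
}

grid_affine_of <- function(grid) {
  A <- diag(4)
  A[1:3, 1:3] <- grid$direction %*% diag(grid$spacing_mm)
  A[1:3, 4] <- grid$origin_mm
  A
}

# World coordinates (n x 3, mm) of 1-based voxel index rows (n x 3).
index_to_world <- function(img, idx) {
  A <- grid_affine(img)
  pts <- cbind(idx - 1, 1) %*% t(A)
  pts[, 1:3, drop = FALSE]
}

# Replace voxel values, keeping geometry and optionally retagging units.
with_values <- function(img, values, units = img$units) {
  image3d(values, img$spacing_mm, img$origin_mm, img$direction, units)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}
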