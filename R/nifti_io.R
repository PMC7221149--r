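#' Read a NIfTI-1 image as an `image3d`
#'
#' Geometry (spacing, origin, direction) is taken from the NIfTI affine.
#' The unit tag is read from a JSON sidecar (same path with `.json`
#' replacing the NIfTI extension) when present, otherwise from `units`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units fallback unit tag when no sidecar is found.
#' @return an [image3d].
#' @seealso [write_image()]
#' @export
read_image <- function(path, units = "none") {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("cannot read NIfTI '%s': %s",
                                            path, conditionMessage(e)))
  d <- dim(nii)
  if (length(d) != 3L)
    stopf("expected a 3-D volume, '%s' has %d dimensions", path, length(d))
  aff <- RNifti::xform(nii)
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stopf("degenerate affine in '%s'", path)
  direction <- sweep(M, 2, spacing, "/")
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    units <- meta$units %||% units
  }
  image3d(array(as.numeric(nii), dim = d), spacing_mm = spacing,
          origin_mm = aff[1:3, 4], direction = direction, units = units)
}

#' Write an `image3d` as NIfTI-1
#'
#' The grid geometry is stored in the sform affine. Binary masks (all
#' values in \{0, 1\}) are written as unsigned 8-bit, other images as
#' 32-bit float. A JSON sidecar carrying the unit tag is written next to
#' the image.
#'
#' @param img an [image3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param overwrite logical; refuse to clobber an existing file unless TRUE.
#' @export
write_image <- function(img, path, overwrite = FALSE) {
  stopifnot(inherits(img, "image3d"))
  if (file.exists(path) && !overwrite)
    stopf("'%s' exists; use overwrite = TRUE", path)
  is_mask <- all(img$values %in% c(0, 1))
  nii <- RNifti::asNifti(img$values)
  aff <- grid_affine(img)
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  RNifti::writeNifti(nii, path,
                     datatype = if (is_mask) "uint8" else "float")
  jsonlite::write_json(list(units = img$units), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Convert an activity-concentration image to SUV
#'
#' Body-weight standardized uptake value:
#' \deqn{SUV = C \times w / D(t)} with \eqn{C} the concentration in
#' Bq/mL, \eqn{w} the body weight in grams, and
#' \eqn{D(t) = D_0 2^{-t/T_{1/2}}} the injected activity decay-corrected
#' to scan time.
#'
#' @param img [image3d] in `Bq_per_mL`.
#' @param weight_kg patient weight (kg).
#' @param injected_mbq injected activity (MBq).
#' @param minutes_post_injection uptake time between injection and scan.
#' @param half_life_min tracer half-life (default 109.77 min, F-18).
#' @return [image3d] in SUV.
#' @export
activity_to_suv <- function(img, weight_kg, injected_mbq,
                            minutes_post_injection = 60,
                            half_life_min = 109.77) {
  stopifnot(inherits(img, "image3d"))
  if (img$units != "Bq_per_mL")
    stopf("input image must be in Bq_per_mL, got %s", img$units)
  for (v in c(weight_kg, injected_mbq, half_life_min))
    if (!is_scalar_num(v) || v <= 0)
      stopf("weight, dose and half-life must be positive scalars")
  if (!is_scalar_num(minutes_post_injection) || minutes_post_injection < 0)
    stopf("minutes_post_injection must be a non-negative scalar")
  decayed_bq <- injected_mbq * 1e6 *
    2^(-minutes_post_injection / half_life_min)
  with_values(img, img$values * (weight_kg * 1000) / decayed_bq,
              units = "SUV")
}
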