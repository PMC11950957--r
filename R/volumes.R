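## Core volumetric data model.
##
## Axis convention (fixed project-wide): arrays are indexed
## (slice, row, column) with slice = craniocaudal (increasing superior),
## row increasing posterior, column increasing toward patient left.
## `spacing` and `origin` follow the same order, in millimetres.

#' Volumetric image container
#'
#' An `image_volume` is a 3D scalar grid (CT-like intensities in arbitrary
#' units) with voxel spacing and physical origin in millimetres. Axis order
#' is (slice, row, column), slice being craniocaudal.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin Numeric length-3, physical coordinate of the first voxel
#'   in mm. Defaults to `c(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  vol <- structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "image_volume")
  validate_volume(vol)
  vol
}

#' Binary structure mask
#'
#' A `structure_mask` is a 0/1 grid aligned to a reference volume, naming
#' one of the six plan structures (PTV, rectum, bladder, left/right femoral
#' head, body).
#'
#' @param values 3D array with values in \{0, 1\}.
#' @param roi_name One of `"PTV"`, `"rectum"`, `"bladder"`,
#'   `"femoral_head_L"`, `"femoral_head_R"`, `"body"`.
#' @inheritParams image_volume
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, roi_name, spacing, origin = c(0, 0, 0)) {
  roi_name <- match.arg(roi_name, ROI_NAMES)
  msk <- structure(
    list(values = values, roi_name = roi_name,
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = c("structure_mask", "image_volume"))
  validate_volume(msk)
  if (!all(msk$values %in% c(0, 1)))
    stop("structure mask values must be 0/1", call. = FALSE)
  storage.mode(msk$values) <- "integer"
  msk
}

#' Dose grid
#'
#' A `dose_grid` holds absolute dose in Gy on the shared plan grid, along
#' with the prescription (total dose in Gy) and the fraction count, which
#' radiobiological conversions need.
#'
#' @param values 3D numeric array of dose in Gy, all finite and >= 0.
#' @param prescription Total prescribed dose in Gy (> 0).
#' @param n_fractions Number of fractions (>= 1).
#' @inheritParams image_volume
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, prescription, n_fractions, spacing,
                      origin = c(0, 0, 0)) {
  dg <- structure(
    list(values = values, prescription = as.numeric(prescription),
         n_fractions = as.integer(n_fractions),
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = c("dose_grid", "image_volume"))
  validate_volume(dg)
  if (any(dg$values < 0)) stop("dose values must be >= 0", call. = FALSE)
  if (!isTRUE(dg$prescription > 0))
    stop("prescription must be > 0", call. = FALSE)
  if (!isTRUE(dg$n_fractions >= 1L))
    stop("n_fractions must be >= 1", call. = FALSE)
  dg
}

validate_volume <- function(vol) {
  v <- vol$values
  if (!is.array(v) || length(dim(v)) != 3L)
    stop("expected 3D volume", call. = FALSE)
  if (any(dim(v) == 0L)) stop("grid must be non-empty", call. = FALSE)
  if (!all(is.finite(v))) stop("all voxel values must be finite",
                               call. = FALSE)
  if (length(vol$spacing) != 3L || any(!is.finite(vol$spacing)) ||
      any(vol$spacing <= 0))
    stop("spacing must be three strictly positive values", call. = FALSE)
  if (length(vol$origin) != 3L || any(!is.finite(vol$origin)))
    stop("origin must be three finite values", call. = FALSE)
  invisible(vol)
}

#' One patient-equivalent plan sample
#'
#' Bundles the planning image, the six structure masks and the planned dose
#' on one shared grid. Masks are restricted craniocaudally to the PTV
#' extent plus/minus 1 cm, mirroring clinical contouring practice for this
#' treatment site.
#'
#' @param id Sample identifier (string).
#' @param image An [image_volume()].
#' @param masks Named list containing exactly the six ROIs
#'   (`PTV`, `rectum`, `bladder`, `femoral_head_L`, `femoral_head_R`,
#'   `body`), each a [structure_mask()] on the image grid.
#' @param dose A [dose_grid()] on the image grid.
#' @return An object of class `plan_sample`.
#' @export
plan_sample <- function(id, image, masks, dose) {
  missing_rois <- setdiff(ROI_NAMES, names(masks))
  if (length(missing_rois))
    stop("missing ROI mask(s): ", paste(missing_rois, collapse = ", "),
         call. = FALSE)
  masks <- masks[ROI_NAMES]
  ref_dim <- dim(image$values)
  for (m in masks) {
    if (!identical(dim(m$values), ref_dim) ||
        max(abs(m$spacing - image$spacing)) > 1e-6)
      stop("grid mismatch between image and mask '", m$roi_name, "'",
           call. = FALSE)
  }
  if (!identical(dim(dose$values), ref_dim) ||
      max(abs(dose$spacing - image$spacing)) > 1e-6)
    stop("grid mismatch between image and dose", call. = FALSE)
  for (nm in ROI_NAMES)
    if (sum(masks[[nm]]$values) == 0L)
      stop("ROI '", nm, "' is empty", call. = FALSE)
  structure(list(id = as.character(id), image = image, masks = masks,
                 dose = dose),
            class = "plan_sample")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.plan_sample <- function(x, ...) {
  cat(sprintf("<plan_sample> id=%s grid %s, prescription %.1f Gy / %d fx\n",
              x$id, paste(dim(x$image$values), collapse = "x"),
              x$dose$prescription, x$dose$n_fractions))
  invisible(x)
}
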