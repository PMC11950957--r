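## NIfTI and manifest I/O. Storage format is NIfTI (.nii.gz) plus a JSON
## plan manifest; DICOM-RT is deliberately out of scope. Masks are stored
## as integers, images and doses as floating point. The array axis order
## (slice, row, column) maps directly onto NIfTI dims 1..3.

#' Read a volume from a NIfTI file
#'
#' @param path Path to a 3D NIfTI file.
#' @return An [image_volume()] with values, spacing and origin taken from
#'   the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L)
    stop("expected 3D volume, got ", length(dim(im)), "D: ", path,
         call. = FALSE)
  vals <- array(as.numeric(im), dim = dim(im))
  if (!all(is.finite(vals)))
    stop("non-finite voxels in ", path, call. = FALSE)
  sp <- RNifti::pixdim(im)
  orig <- as.numeric(RNifti::xform(im)[1:3, 4])
  image_volume(vals, spacing = sp, origin = orig)
}

#' Write a volume to a NIfTI file
#'
#' Masks are written as integer data, images and doses as floating point;
#' the affine is diagonal in the voxel spacing with the origin as offset.
#'
#' @param vol An [image_volume()], [structure_mask()] or [dose_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  validate_volume(vol)
  vals <- vol$values
  datatype <- if (inherits(vol, "structure_mask")) "int16" else "double"
  im <- RNifti::asNifti(array(as.numeric(vals), dim = dim(vals)))
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  RNifti::qform(im) <- aff
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' Load a plan sample from a JSON manifest
#'
#' The manifest schema is
#' `{id, image, dose, prescription_gy, n_fractions, masks: {roi: path}}`
#' with file paths resolved relative to the manifest location. Grid
#' alignment of all members is validated; a missing ROI or a shape mismatch
#' is rejected.
#'
#' @param manifest Path to a manifest JSON file.
#' @return A [plan_sample()].
#' @export
load_plan_sample <- function(manifest) {
  if (!file.exists(manifest))
    stop("manifest not found: ", manifest, call. = FALSE)
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  for (field in c("id", "image", "dose", "prescription_gy", "n_fractions",
                  "masks"))
    if (is.null(mf[[field]]))
      stop("manifest missing field '", field, "'", call. = FALSE)
  base <- dirname(normalizePath(manifest))
  resolve <- function(p)
    if (file.exists(p)) p else file.path(base, p)
  image <- read_volume(resolve(mf$image))
  dose_vol <- read_volume(resolve(mf$dose))
  dose <- dose_grid(dose_vol$values, prescription = mf$prescription_gy,
                    n_fractions = mf$n_fractions,
                    spacing = dose_vol$spacing, origin = dose_vol$origin)
  mask_paths <- mf$masks
  missing_rois <- setdiff(ROI_NAMES, names(mask_paths))
  if (length(missing_rois))
    stop("manifest missing ROI(s): ", paste(missing_rois, collapse = ", "),
         call. = FALSE)
  masks <- lapply(ROI_NAMES, function(nm) {
    v <- read_volume(resolve(mask_paths[[nm]]))
    structure_mask(round(v$values), roi_name = nm, spacing = v$spacing,
                   origin = v$origin)
  })
  names(masks) <- ROI_NAMES
  plan_sample(mf$id, image, masks, dose)
}

#' Write a plan sample and its manifest to a directory
#'
#' Writes `<id>_image.nii.gz`, `<id>_dose.nii.gz`, one mask file per ROI
#' and `<id>.json` into `dir`.
#'
#' @param sample A [plan_sample()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_plan_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sample$id
  img_file <- paste0(id, "_image.nii.gz")
  dose_file <- paste0(id, "_dose.nii.gz")
  write_volume(sample$image, file.path(dir, img_file))
  write_volume(sample$dose, file.path(dir, dose_file))
  mask_files <- setNames(paste0(id, "_mask_", ROI_NAMES, ".nii.gz"),
                         ROI_NAMES)
  for (nm in ROI_NAMES)
    write_volume(sample$masks[[nm]], file.path(dir, mask_files[[nm]]))
  mf <- list(id = id, image = img_file, dose = dose_file,
             prescription_gy = sample$dose$prescription,
             n_fractions = sample$dose$n_fractions,
             masks = as.list(mask_files))
  manifest <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(mf, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
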