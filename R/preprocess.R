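## Preprocessing chain from raw plan samples to model-ready channel
## stacks: in-plane crop + resize, craniocaudal slice selection, coverage
## rescaling of dose, cohort-level dose normalization, channel assembly.

#' Preprocessing configuration
#'
#' @param crop_size In-plane crop window in pixels (square), centred on
#'   the body-mask centroid; `NULL` keeps the full in-plane grid. At
#'   clinical resolution the convention is a 400-pixel crop of the 512
#'   matrix.
#' @param target_size In-plane size after resampling (square); the model
#'   input resolution. Must not exceed the crop size.
#' @param max_slices Cap on the number of consecutive slices (default 80).
#' @param margin_mm Craniocaudal margin around the PTV for slice
#'   selection, mm (default 10).
#' @param coverage_fraction Fraction of the prescription used by the
#'   coverage rule (default 0.95).
#' @param coverage_volume PTV volume fraction (percent/100) that must
#'   receive it (default 0.95).
#' @param ct_window CT display window `c(low, high)` in image intensity
#'   units; intensities are scaled linearly to \[0, 1\] over this window
#'   (default soft-tissue window `c(-160, 240)`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_size = NULL, target_size = 128,
                              max_slices = 80, margin_mm = 10,
                              coverage_fraction = 0.95,
                              coverage_volume = 0.95,
                              ct_window = c(-160, 240)) {
  stopifnot(is.null(crop_size) || crop_size >= target_size,
            target_size >= 4, max_slices >= 1, margin_mm >= 0,
            coverage_fraction > 0, coverage_fraction <= 1,
            coverage_volume > 0, coverage_volume <= 1,
            length(ct_window) == 2L, ct_window[1] < ct_window[2])
  structure(as.list(environment()), class = "preprocess_config")
}

resize_slice <- function(mat, target, nearest = FALSE) {
  EBImage::resize(mat, w = target, h = target,
                  filter = if (nearest) "none" else "bilinear")
}

#' Crop and resample a plan sample in-plane
#'
#' Crops each axial plane to a square window centred on the body-mask
#' centroid and resamples to the target size: bilinear interpolation for
#' image and dose, nearest-neighbour for masks. Voxel spacing is updated
#' by the crop/target ratio (e.g. 0.98 mm at a 400 to 128 reduction
#' becomes 3.06 mm).
#'
#' @param sample A [plan_sample()].
#' @param cfg A [preprocess_config()].
#' @return A resampled [plan_sample()].
#' @export
crop_and_resize <- function(sample, cfg = preprocess_config()) {
  dm <- dim(sample$image$values)
  crop <- if (is.null(cfg$crop_size)) min(dm[2], dm[3]) else cfg$crop_size
  if (crop > dm[2] || crop > dm[3])
    stop("crop window exceeds grid bounds", call. = FALSE)
  bidx <- which(sample$masks$body$values > 0, arr.ind = TRUE)
  ctr <- c(mean(bidx[, 2]), mean(bidx[, 3]))
  r0 <- min(max(1, round(ctr[1] - crop / 2)), dm[2] - crop + 1)
  c0 <- min(max(1, round(ctr[2] - crop / 2)), dm[3] - crop + 1)
  rows <- r0:(r0 + crop - 1)
  cols <- c0:(c0 + crop - 1)

  tgt <- cfg$target_size
  scale <- crop / tgt
  new_spacing <- sample$image$spacing * c(1, scale, scale)
  new_origin <- sample$image$origin +
    c(0, (r0 - 1) * sample$image$spacing[2],
      (c0 - 1) * sample$image$spacing[3])

  resample <- function(arr, nearest) {
    out <- array(0, dim = c(dm[1], tgt, tgt))
    for (k in seq_len(dm[1]))
      out[k, , ] <- resize_slice(arr[k, rows, cols], tgt, nearest)
    out
  }
  image <- image_volume(resample(sample$image$values, FALSE),
                        spacing = new_spacing, origin = new_origin)
  dose_vals <- resample(sample$dose$values, FALSE)
  dose_vals[dose_vals < 0] <- 0
  dose <- dose_grid(dose_vals, prescription = sample$dose$prescription,
                    n_fractions = sample$dose$n_fractions,
                    spacing = new_spacing, origin = new_origin)
  masks <- lapply(sample$masks, function(m)
    structure_mask(resample(m$values, TRUE), m$roi_name,
                   spacing = new_spacing, origin = new_origin))
  plan_sample(sample$id, image, masks, dose)
}

#' Select the consecutive slice range covering the PTV
#'
#' Returns the indices of consecutive slices covering the PTV extent plus
#' the craniocaudal margin, truncated symmetrically about the PTV centroid
#' slice when the covered extent exceeds `max_slices`.
#'
#' @param sample A [plan_sample()].
#' @param cfg A [preprocess_config()].
#' @return Integer vector of slice indices (consecutive).
#' @export
select_slices <- function(sample, cfg = preprocess_config()) {
  ptv_any <- apply(sample$masks$PTV$values > 0, 1, any)
  if (!any(ptv_any)) stop("empty PTV", call. = FALSE)
  n_margin <- floor(cfg$margin_mm / sample$image$spacing[1])
  lo <- max(1L, min(which(ptv_any)) - n_margin)
  hi <- min(dim(sample$image$values)[1], max(which(ptv_any)) + n_margin)
  idx <- lo:hi
  if (length(idx) > cfg$max_slices) {
    ctr <- round(mean(which(ptv_any)))
    half <- cfg$max_slices %/% 2
    lo <- max(1L, ctr - half)
    hi <- lo + cfg$max_slices - 1L
    if (hi > dim(sample$image$values)[1]) {
      hi <- dim(sample$image$values)[1]
      lo <- hi - cfg$max_slices + 1L
    }
    idx <- lo:hi
  }
  idx
}

#' Rescale a dose to the PTV coverage rule
#'
#' Multiplies the dose by the factor that makes the PTV
#' `D[coverage_volume]%` equal `coverage_fraction` times the prescription
#' (default: 95% of the PTV receives 95% of the prescription, i.e.
#' D95% = 71.06 Gy at 74.8 Gy). The quantile is the exact voxel quantile
#' (largest dose with covered volume at least the target), which makes the
#' operation exactly idempotent; the binned-DVH D95% agrees within one
#' interpolation bin.
#'
#' @param dose A [dose_grid()].
#' @param ptv PTV [structure_mask()].
#' @param cfg A [preprocess_config()].
#' @return The rescaled [dose_grid()], with the factor as attribute
#'   `"scale_factor"`.
#' @export
rescale_to_coverage <- function(dose, ptv, cfg = preprocess_config()) {
  d95 <- dose_at_volume_exact(dose$values, ptv$values,
                              100 * cfg$coverage_volume)
  if (!isTRUE(d95 > 0))
    stop("PTV dose is zero: coverage rescaling undefined", call. = FALSE)
  f <- cfg$coverage_fraction * dose$prescription / d95
  out <- dose
  out$values <- dose$values * f
  attr(out, "scale_factor") <- f
  out
}

#' Normalize a cohort of doses by the global maximum
#'
#' Divides every dose by the single maximum over the whole training
#' cohort, mapping all values into \[0, 1\]; the constant is returned so
#' test-time predictions can be denormalized by the training constant.
#'
#' @param doses List of [dose_grid()]s (the training cohort).
#' @return List with `normalized` (list of 3D arrays in \[0, 1\]) and
#'   `constant` (the global maximum dose in Gy).
#' @export
normalize_global <- function(doses) {
  if (!length(doses)) stop("empty cohort", call. = FALSE)
  gmax <- max(vapply(doses, function(d) max(d$values), numeric(1)))
  if (!isTRUE(gmax > 0)) stop("all-zero dose cohort", call. = FALSE)
  list(normalized = lapply(doses, function(d) d$values / gmax),
       constant = gmax)
}

#' Assemble the 7-channel model input stack
#'
#' Builds the fixed-order channel stack (CT, rectum, bladder, left femoral
#' head, right femoral head, PTV, body) for the selected slices. CT
#' intensities are scaled linearly to \[0, 1\] over the configured window;
#' mask channels are binary.
#'
#' @param sample A preprocessed [plan_sample()].
#' @param cfg A [preprocess_config()].
#' @param slices Slice indices (default [select_slices()]).
#' @return An object of class `channel_stack`: list with `data` (array
#'   `[slice, row, col, channel]`), `slices` (source indices), `channels`
#'   (names), and the sample `id`.
#' @export
assemble_channels <- function(sample, cfg = preprocess_config(),
                              slices = select_slices(sample, cfg)) {
  dm <- dim(sample$image$values)
  ct <- (sample$image$values - cfg$ct_window[1]) /
    diff(cfg$ct_window)
  ct <- pmin(pmax(ct, 0), 1)
  arr <- array(0, dim = c(length(slices), dm[2], dm[3],
                          length(CHANNEL_ORDER)))
  arr[, , , 1] <- ct[slices, , , drop = FALSE]
  mask_order <- c("rectum", "bladder", "femoral_head_L", "femoral_head_R",
                  "PTV", "body")
  for (j in seq_along(mask_order))
    arr[, , , j + 1] <-
      sample$masks[[mask_order[j]]]$values[slices, , , drop = FALSE]
  structure(list(data = arr, slices = slices, channels = CHANNEL_ORDER,
                 id = sample$id),
            class = "channel_stack")
}

#' Preprocess a cohort for training or prediction
#'
#' Applies the full chain to every sample: in-plane crop/resize, coverage
#' rescaling of the planned dose, slice selection and channel assembly;
#' then normalizes all rescaled doses by the cohort global maximum (or a
#' supplied constant for a test cohort).
#'
#' @param samples List of [plan_sample()]s.
#' @param cfg A [preprocess_config()].
#' @param norm_constant Optional fixed normalization constant in Gy (the
#'   training constant, when preprocessing a test cohort); `NULL` computes
#'   it from this cohort.
#' @return List with `stacks` (list of `channel_stack`), `doses` (list of
#'   normalized dose arrays restricted to the selected slices),
#'   `samples` (the resampled plan samples with rescaled doses) and
#'   `norm_constant`.
#' @export
preprocess_cohort <- function(samples, cfg = preprocess_config(),
                              norm_constant = NULL) {
  pre <- lapply(samples, function(s) {
    s2 <- crop_and_resize(s, cfg)
    s2$dose <- rescale_to_coverage(s2$dose, s2$masks$PTV, cfg)
    s2
  })
  if (is.null(norm_constant)) {
    norm_constant <- max(vapply(pre, function(s) max(s$dose$values),
                                numeric(1)))
    if (!isTRUE(norm_constant > 0))
      stop("all-zero dose cohort", call. = FALSE)
  }
  stacks <- lapply(pre, assemble_channels, cfg = cfg)
  doses <- lapply(seq_along(pre), function(i)
    pre[[i]]$dose$values[stacks[[i]]$slices, , , drop = FALSE] /
      norm_constant)
  list(stacks = stacks, doses = doses, samples = pre,
       norm_constant = norm_constant)
}
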