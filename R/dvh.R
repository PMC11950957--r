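## Cumulative dose-volume histograms and derived plan metrics.

#' Compute a cumulative DVH
#'
#' Builds the differential histogram of in-structure voxel doses on a
#' uniform grid of `bin_width` Gy and accumulates it into the cumulative
#' curve: the percentage of the structure receiving at least each bin-edge
#' dose.
#'
#' @param dose A [dose_grid()] (or 3D array of doses in Gy).
#' @param mask A [structure_mask()] (or 0/1 array) on the same grid.
#' @param bin_width Histogram bin width in Gy (default 0.1).
#' @return An object of class `dvh_curve`: list with `edges` (Gy),
#'   `cum_volume` (percent, non-increasing, 100 at 0 Gy), `n_voxels`,
#'   `voxel_volume_mm3` and `bin_width`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  vals <- if (inherits(dose, "image_volume")) dose$values else dose
  mvals <- if (inherits(mask, "image_volume")) mask$values else mask
  if (!identical(dim(vals), dim(mvals)))
    stop("dose and mask grids differ", call. = FALSE)
  d <- vals[mvals > 0]
  if (length(d) == 0L)
    stop("empty structure mask: DVH undefined", call. = FALSE)
  stopifnot(bin_width > 0)
  n_bins <- max(1L, ceiling(max(d) / bin_width) + 1L)
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  ## right-open bins [lo, hi): a dose exactly on an edge counts as >= it
  counts <- tabulate(pmin(findInterval(d, edges), n_bins),
                     nbins = n_bins)
  ## cum_volume[i]: fraction of voxels with dose >= edges[i]
  cum <- rev(cumsum(rev(counts))) / length(d) * 100
  vox_vol <- if (inherits(mask, "image_volume")) prod(mask$spacing)
             else NA_real_
  structure(list(edges = edges[seq_len(n_bins + 1L)],
                 cum_volume = c(cum, 0),
                 n_voxels = length(d),
                 voxel_volume_mm3 = vox_vol,
                 bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d voxels, %d bins of %.3g Gy, max %.2f Gy\n",
              x$n_voxels, length(x$edges) - 1L, x$bin_width,
              max(x$edges)))
  invisible(x)
}

#' V_xGy: relative volume at dose
#'
#' Percentage of the structure receiving at least `x` Gy, linearly
#' interpolated between DVH bin edges.
#'
#' @param curve A `dvh_curve`.
#' @param x Dose threshold in Gy (>= 0); vectorized.
#' @return Percent in \[0, 100\].
#' @export
volume_at_dose <- function(curve, x) {
  stopifnot(all(x >= 0))
  vapply(x, function(xi) {
    if (xi >= max(curve$edges)) return(0)
    stats::approx(curve$edges, curve$cum_volume, xout = xi,
                  rule = 2)$y
  }, numeric(1))
}

#' D_x%: dose at relative volume
#'
#' Minimum dose received by the hottest `x`% of the structure: the largest
#' dose whose covered volume is still at least `x`% (ties on flat curve
#' segments resolve to the largest qualifying dose), with linear
#' interpolation between bin edges elsewhere.
#'
#' @param curve A `dvh_curve`.
#' @param x Volume level in percent, in (0, 100\]; vectorized.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(curve, x) {
  stopifnot(all(x > 0), all(x <= 100))
  e <- curve$edges
  cv <- curve$cum_volume
  vapply(x, function(xi) {
    j <- which(cv >= xi)
    if (!length(j)) return(0)
    j <- max(j) # largest dose with coverage >= xi
    if (cv[j] == xi || j == length(e)) return(e[j])
    ## interpolate toward the next (lower-coverage) edge
    e[j] + (e[j + 1] - e[j]) * (cv[j] - xi) / (cv[j] - cv[j + 1])
  }, numeric(1))
}

## Exact voxel-quantile D_x% (scale-equivariant; used by coverage
## rescaling). Same tie convention as dose_at_volume: the largest dose d
## such that the fraction of voxels with dose >= d is at least x%.
dose_at_volume_exact <- function(dose_values, mask_values, x) {
  d <- dose_values[mask_values > 0]
  if (!length(d)) stop("empty structure mask", call. = FALSE)
  sort(d, decreasing = TRUE)[ceiling(x / 100 * length(d))]
}

#' Homogeneity index of a PTV DVH
#'
#' `HI = 100 * (D2% - D98%) / D50%`, in percent; 0 for a perfectly uniform
#' dose.
#'
#' @param curve A `dvh_curve` of the PTV.
#' @return HI in percent.
#' @export
homogeneity_index <- function(curve) {
  d <- dose_at_volume(curve, c(2, 98, 50))
  if (d[3] == 0) stop("D50% is zero: HI undefined", call. = FALSE)
  100 * (d[1] - d[2]) / d[3]
}

#' R50%: 50%-isodose spill
#'
#' `100 * V(dose >= 50% of prescription) / V(PTV)`, the volume of the
#' half-prescription isodose relative to the PTV volume. The isodose
#' volume is taken over the whole grid intersected with the body mask when
#' one is supplied (air excluded), else over the whole grid.
#'
#' @param dose A [dose_grid()].
#' @param ptv PTV [structure_mask()].
#' @param body Optional body [structure_mask()] restricting the isodose
#'   volume.
#' @return R50% in percent (can exceed 100).
#' @export
r50 <- function(dose, ptv, body = NULL) {
  n_ptv <- sum(ptv$values > 0)
  if (n_ptv == 0L) stop("empty PTV", call. = FALSE)
  iso <- dose$values >= 0.5 * dose$prescription
  if (!is.null(body)) iso <- iso & body$values > 0
  100 * sum(iso) / n_ptv
}

## Metric definitions shared by metric_suite and the cohort report:
## the DVH rows of a plan comparison table.
dvh_metric_spec <- function() {
  rbind(
    data.frame(structure = "PTV",
               metric = c("D98%", "D95%", "D50%", "D2%", "Dmean", "HI",
                          "R50%"),
               unit = c("Gy", "Gy", "Gy", "Gy", "Gy", "%", "%")),
    data.frame(structure = "rectum",
               metric = c("V70Gy", "V60Gy", "V50Gy", "V40Gy", "D2%",
                          "Dmean"),
               unit = c("%", "%", "%", "%", "Gy", "Gy")),
    data.frame(structure = "bladder",
               metric = c("V70Gy", "V60Gy", "V50Gy", "V40Gy", "D2%",
                          "Dmean"),
               unit = c("%", "%", "%", "%", "Gy", "Gy")),
    data.frame(structure = "femoral_head_R",
               metric = c("D2%", "Dmean"), unit = c("Gy", "Gy")),
    data.frame(structure = "femoral_head_L",
               metric = c("D2%", "Dmean"), unit = c("Gy", "Gy")))
}

#' All DVH plan metrics for one dose distribution
#'
#' Computes the full DVH metric panel of a plan-comparison table: PTV
#' D98%/D95%/D50%/D2%/Dmean/HI/R50%; rectum and bladder
#' V70Gy/V60Gy/V50Gy/V40Gy/D2%/Dmean; and femoral-head D2%/Dmean, all on
#' the sample's own grid.
#'
#' @param dose A [dose_grid()] on the sample grid.
#' @param masks Named list of the six [structure_mask()]s.
#' @param bin_width DVH bin width in Gy.
#' @return A data.frame with columns `structure`, `metric`, `unit`,
#'   `value` (23 rows).
#' @export
metric_suite <- function(dose, masks, bin_width = 0.1) {
  spec <- dvh_metric_spec()
  curves <- list()
  for (s in unique(spec$structure))
    curves[[s]] <- compute_dvh(dose, masks[[s]], bin_width)
  value <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    cv <- curves[[spec$structure[i]]]
    m <- spec$metric[i]
    value[i] <-
      if (m == "HI") homogeneity_index(cv)
      else if (m == "R50%") r50(dose, masks$PTV, masks$body)
      else if (m == "Dmean") {
        d <- dose$values[masks[[spec$structure[i]]]$values > 0]
        mean(d)
      } else if (grepl("^D", m))
        dose_at_volume(cv, as.numeric(sub("^D([0-9.]+)%$", "\\1", m)))
      else
        volume_at_dose(cv, as.numeric(sub("^V([0-9.]+)Gy$", "\\1", m)))
  }
  cbind(spec, value = value)
}
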