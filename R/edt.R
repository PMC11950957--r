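#' Euclidean distance transform of a binary mask
#'
#' Exact Euclidean distance (in mm, using the voxel spacing) from every
#' voxel to the nearest voxel of the foreground set, computed with the
#' separable squared-distance-transform algorithm. Foreground voxels have
#' distance 0, so for a solid structure this is the distance to the
#' structure (its surface) from outside.
#'
#' @param mask 3D array of 0/1 (or logical).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return 3D numeric array of distances in mm (`Inf` if the mask is empty).
#' @export
distance_transform <- function(mask, spacing) {
  dm <- dim(mask)
  if (length(dm) != 3L) stop("expected 3D mask", call. = FALSE)
  d <- .edt3d(as.integer(mask != 0), as.integer(dm), as.numeric(spacing))
  array(d, dim = dm)
}
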