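## Synthetic pelvic phantom cohort generator.
##
## Each phantom emulates one prostate VMAT patient-equivalent: a CT-like
## image with soft-tissue/bone/air contrast, six structure masks (PTV,
## rectum, bladder, both femoral heads, body) with inter-patient geometric
## variability, and an analytic PTV-conformal planned dose with a concave
## posterior fall-off sparing the rectum. All geometry is sampled in
## physical millimetres on a configurable grid, so the same anatomy
## statistics hold at any resolution.

#' Phantom cohort configuration
#'
#' Geometry ranges are uniform sampling intervals in mm. The defaults
#' target a 192 x 192 mm in-plane field of view and a 96 mm craniocaudal
#' extent (64 x 64 x 32 voxels at 3 mm), prescription 74.8 Gy in 34
#' fractions, and produce cohorts whose planned-dose grade >= 2
#' late-rectal-bleeding LKB NTCP values concentrate in the 8-17% band.
#'
#' @param shape Grid shape `c(n_slice, n_row, n_col)`.
#' @param spacing Voxel spacing in mm, `c(slice, row, col)`.
#' @param prescription Prescribed total dose in Gy.
#' @param n_fractions Number of fractions.
#' @param cohort_size Default cohort size for [generate_cohort()].
#' @param seed Master seed for cohort generation.
#' @param ptv_radius_si,ptv_radius_ap,ptv_radius_lr PTV semi-axis ranges
#'   (craniocaudal, antero-posterior, lateral), mm.
#' @param rectum_radius Rectum tube radius range, mm.
#' @param rectum_gap PTV-to-rectum minimum surface distance range, mm
#'   (0 = abutting, as in unspaced anatomy).
#' @param rectum_curve_amp Lateral sinusoidal curvature amplitude range of
#'   the rectum centreline, mm.
#' @param bladder_radius_si,bladder_radius_ap,bladder_radius_lr Bladder
#'   semi-axis ranges, mm.
#' @param fem_radius Femoral head radius range, mm.
#' @param fem_offset Lateral distance range of femoral head centres from
#'   the midline, mm.
#' @param body_semi_row,body_semi_col Body ellipse semi-axis ranges, mm.
#' @param cc_margin Craniocaudal contouring margin around the PTV, mm;
#'   all masks are restricted to the PTV extent plus this margin.
#' @param falloff_mm Penumbra midpoint of the logistic dose fall-off
#'   outside the PTV, mm (distance at which the profile reaches half its
#'   plateau).
#' @param penumbra_mm Logistic penumbra steepness scale, mm.
#' @param plateau Plateau level of the fall-off profile as a fraction of
#'   the prescription (the near-field dose just outside the PTV).
#' @param bath Low-dose bath level as a fraction of prescription.
#' @param bath_scale_mm Exponential decay scale of the low-dose bath, mm.
#' @param ptv_boost Fractional dose boost from the PTV surface toward its
#'   centre, making D50% exceed D95% strictly.
#' @param rectum_atten Maximum multiplicative attenuation applied
#'   posterior to the anterior rectal wall (the rectum-sparing concavity).
#' @param atten_width_mm Distance over which the posterior attenuation
#'   ramps up to `rectum_atten`, mm.
#' @param atten_deadzone_mm Depth below the anterior rectal wall at which
#'   the attenuation ramp starts, mm.
#' @param noise_gy Amplitude (SD) of the additive smooth dose noise, Gy.
#' @param noise_sigma_vox Gaussian smoothing sigma of the noise field,
#'   voxels.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(32, 64, 64),
                           spacing = c(3, 3, 3),
                           prescription = 74.8,
                           n_fractions = 34,
                           cohort_size = 60,
                           seed = 20260921,
                           ptv_radius_si = c(14, 20),
                           ptv_radius_ap = c(16, 22),
                           ptv_radius_lr = c(20, 28),
                           rectum_radius = c(9, 13),
                           rectum_gap = c(0, 4),
                           rectum_curve_amp = c(2, 6),
                           bladder_radius_si = c(12, 16),
                           bladder_radius_ap = c(18, 24),
                           bladder_radius_lr = c(20, 26),
                           fem_radius = c(18, 22),
                           fem_offset = c(56, 62),
                           body_semi_row = c(80, 86),
                           body_semi_col = c(90, 94),
                           cc_margin = 10,
                           falloff_mm = 15,
                           penumbra_mm = 3,
                           plateau = 1.03,
                           bath = 0.10,
                           bath_scale_mm = 60,
                           ptv_boost = 0.10,
                           rectum_atten = 0.70,
                           atten_width_mm = 12,
                           atten_deadzone_mm = 2.5,
                           noise_gy = 0.8,
                           noise_sigma_vox = 2) {
  cfg <- as.list(environment())
  rng_fields <- c("ptv_radius_si", "ptv_radius_ap", "ptv_radius_lr",
                  "rectum_radius", "rectum_gap", "rectum_curve_amp",
                  "bladder_radius_si", "bladder_radius_ap",
                  "bladder_radius_lr", "fem_radius", "fem_offset",
                  "body_semi_row", "body_semi_col")
  for (f in rng_fields) {
    r <- cfg[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("invalid range for ", f, call. = FALSE)
  }
  if (any(cfg$rectum_gap < 0))
    stop("rectum_gap range must be non-negative (masks may not overlap)",
         call. = FALSE)
  if (cfg$falloff_mm <= 0) stop("falloff_mm must be > 0", call. = FALSE)
  stopifnot(length(shape) == 3L, all(shape >= 4), length(spacing) == 3L,
            all(spacing > 0), prescription > 0, n_fractions >= 1)
  structure(cfg, class = "phantom_config")
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

## Smooth Gaussian random field: white noise filtered separably by
## shifted-array weighted sums (cheap and fully vectorised).
smooth_noise_field <- function(shape, sigma_vox, sd = 1) {
  x <- array(stats::rnorm(prod(shape)), dim = shape)
  if (sigma_vox > 0) {
    half <- max(1L, ceiling(2 * sigma_vox))
    w <- stats::dnorm(seq(-half, half), sd = sigma_vox)
    w <- w / sum(w)
    for (ax in 1:3) {
      y <- array(0, dim = shape)
      n <- shape[ax]
      for (j in seq_along(w)) {
        off <- j - half - 1L
        src <- pmin(pmax(seq_len(n) + off, 1L), n) # replicate edges
        idx <- switch(ax, list(src, TRUE, TRUE), list(TRUE, src, TRUE),
                      list(TRUE, TRUE, src))
        y <- y + w[j] * do.call(`[`, c(list(x), idx, list(drop = FALSE)))
      }
      x <- y
    }
    x <- x / stats::sd(x)
  }
  x * sd
}

## Voxel-centre physical coordinate grids, mm.
coord_grids <- function(shape, spacing) {
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - 0.5) * spacing[i])
  list(z = ax[[1]], y = ax[[2]], x = ax[[3]])
}

#' Generate one phantom anatomy
#'
#' Samples organ geometry from the configured ranges and voxelizes the six
#' structure masks plus a CT-like intensity image. The PTV (prostate plus
#' margin) sits midline; the rectum is a laterally curved tube directly
#' posterior at the sampled surface gap; the bladder lies antero-superior;
#' the femoral heads are lateral spheres; the body is an elliptical
#' cylinder enclosing everything. All masks are restricted craniocaudally
#' to the PTV extent +/- the contouring margin. Geometry that does not fit
#' inside the grid is rejected with an error. Uses the current R RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `image` ([image_volume()]), `masks` (named
#'   list of [structure_mask()]), and `geom` (the sampled geometry, mm).
#' @export
generate_anatomy <- function(config) {
  shape <- config$shape
  spacing <- config$spacing
  fov <- shape * spacing
  g <- coord_grids(shape, spacing)

  geom <- list(
    ptv_center = c(z = 0.42 * fov[1] + stats::runif(1, -3, 3),
                   y = 0.5 * fov[2] + stats::runif(1, -4, 4),
                   x = 0.5 * fov[3] + stats::runif(1, -3, 3)),
    ptv_r = c(si = runif_range(config$ptv_radius_si),
              ap = runif_range(config$ptv_radius_ap),
              lr = runif_range(config$ptv_radius_lr)),
    rectum_radius = runif_range(config$rectum_radius),
    rectum_gap = runif_range(config$rectum_gap),
    rectum_amp = runif_range(config$rectum_curve_amp),
    bladder_r = c(si = runif_range(config$bladder_radius_si),
                  ap = runif_range(config$bladder_radius_ap),
                  lr = runif_range(config$bladder_radius_lr)),
    fem_radius = runif_range(config$fem_radius),
    fem_offset = runif_range(config$fem_offset),
    body_semi = c(row = runif_range(config$body_semi_row),
                  col = runif_range(config$body_semi_col)))
  pc <- geom$ptv_center
  pr <- geom$ptv_r
  geom$rectum_center_y <- unname(pc["y"] + pr["ap"] + geom$rectum_gap +
                                   geom$rectum_radius)
  geom$bladder_center <- c(
    z = unname(pc["z"] + pr["si"] - 4),
    y = unname(pc["y"] - pr["ap"] - geom$bladder_r["ap"] - 2),
    x = unname(pc["x"]))
  geom$fem_center_z <- unname(pc["z"] + stats::runif(1, -4, 4))
  geom$fem_center_y <- unname(pc["y"] + stats::runif(1, -4, 4))

  ## bounds check: every organ must fit inside the grid
  ok <- pc["z"] - pr["si"] > 0 && pc["z"] + pr["si"] < fov[1] &&
    geom$bladder_center["z"] + geom$bladder_r["si"] < fov[1] &&
    geom$bladder_center["y"] - geom$bladder_r["ap"] > 0 &&
    geom$rectum_center_y + geom$rectum_radius <
      0.5 * fov[2] + geom$body_semi["row"] &&
    geom$fem_offset + geom$fem_radius + abs(pc["x"] - 0.5 * fov[3]) <
      geom$body_semi["col"] &&
    0.5 * fov[2] + geom$body_semi["row"] < fov[2] &&
    0.5 * fov[3] + geom$body_semi["col"] < fov[3]
  if (!ok)
    stop("configured geometry ranges let organs leave the grid",
         call. = FALSE)

  Z <- array(rep(g$z, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(g$y, each = shape[1]), times = shape[3]), dim = shape)
  X <- array(rep(g$x, each = shape[1] * shape[2]), dim = shape)

  ptv <- ((Z - pc["z"]) / pr["si"])^2 + ((Y - pc["y"]) / pr["ap"])^2 +
    ((X - pc["x"]) / pr["lr"])^2 <= 1

  ## rectum: tube with elliptical cross-section whose anterior wall tracks
  ## the posterior PTV surface at the sampled gap (the prostate indents the
  ## anterior rectal wall), with a small lateral sinusoidal curvature; it
  ## bends gently anterior beyond the PTV extent
  r_ap <- geom$rectum_radius
  r_lr <- 1.35 * geom$rectum_radius
  gz <- sqrt(pmax(0, 1 - ((g$z - pc["z"]) / pr["si"])^2))
  y_surf <- pc["y"] + pr["ap"] * pmax(0.6, gz)
  yr <- y_surf + geom$rectum_gap + r_ap
  xr <- pc["x"] + geom$rectum_amp * sin(2 * pi * (g$z - pc["z"]) / 100)
  YR <- array(rep(yr, times = shape[2] * shape[3]), dim = shape)
  XR <- array(rep(xr, times = shape[2] * shape[3]), dim = shape)
  rectum <- ((Y - YR) / r_ap)^2 + ((X - XR) / r_lr)^2 <= 1
  rectum <- rectum & !ptv # tangency can share voxel centres; PTV wins
  geom$rectum_wall_y <- y_surf + geom$rectum_gap # anterior wall, per slice

  bc <- geom$bladder_center
  br <- geom$bladder_r
  bladder <- ((Z - bc["z"]) / br["si"])^2 + ((Y - bc["y"]) / br["ap"])^2 +
    ((X - bc["x"]) / br["lr"])^2 <= 1

  fem_l <- (Z - geom$fem_center_z)^2 + (Y - geom$fem_center_y)^2 +
    (X - (pc["x"] + geom$fem_offset))^2 <= geom$fem_radius^2
  fem_r <- (Z - geom$fem_center_z)^2 + (Y - geom$fem_center_y)^2 +
    (X - (pc["x"] - geom$fem_offset))^2 <= geom$fem_radius^2

  body <- ((Y - 0.5 * fov[2]) / geom$body_semi["row"])^2 +
    ((X - 0.5 * fov[3]) / geom$body_semi["col"])^2 <= 1

  ## CT-like intensities (approximate HU)
  img <- array(-1000, dim = shape)
  tissue <- 35 + smooth_noise_field(shape, config$noise_sigma_vox, sd = 8)
  img[body] <- tissue[body]
  img[bladder] <- 12
  img[rectum] <- -30 # partially gas-filled lumen
  img[ptv] <- 42
  img[fem_l | fem_r] <- 700

  ## craniocaudal contouring restriction: PTV +/- margin
  zmin <- min(Z[ptv]) - config$cc_margin
  zmax <- max(Z[ptv]) + config$cc_margin
  slab <- g$z >= zmin & g$z <= zmax
  crop <- function(m) {
    m[!slab, , ] <- FALSE
    m
  }
  masks <- list(
    PTV = crop(ptv), rectum = crop(rectum), bladder = crop(bladder),
    femoral_head_L = crop(fem_l), femoral_head_R = crop(fem_r),
    body = crop(body))
  masks <- lapply(names(masks), function(nm)
    structure_mask(array(as.integer(masks[[nm]]), dim = shape), nm,
                   spacing = spacing))
  names(masks) <- ROI_NAMES
  list(image = image_volume(img, spacing = spacing), masks = masks,
       geom = geom)
}

#' Analytic planned dose for a phantom anatomy
#'
#' Emulates an optimized VMAT dose: approximately the prescription inside
#' the PTV with a centre-weighted heterogeneity (so D50% > D95%), a
#' monotone lateral fall-off with distance from the PTV surface, a
#' multiplicative attenuation ramp posterior to the PTV that carves the
#' concave rectum-sparing isodose pattern, additive smooth noise, a 110%
#' hot-spot cap, and zero dose outside the body. Uses the current R RNG
#' state (noise field).
#'
#' @param anatomy Result of [generate_anatomy()].
#' @param config The [phantom_config()] used to generate it.
#' @return A [dose_grid()].
#' @export
analytic_dose <- function(anatomy, config) {
  masks <- anatomy$masks
  shape <- config$shape
  spacing <- config$spacing
  rx <- config$prescription
  ptv <- masks$PTV$values > 0

  d_out <- distance_transform(masks$PTV$values, spacing)
  d_in <- distance_transform(1L - masks$PTV$values, spacing)

  ## outside: sigmoid penumbra on a plateau near the target plus an
  ## exponential low-dose bath; inside: continuous at the surface with a
  ## centre-weighted boost
  falloff <- function(d)
    pmax(config$plateau / (1 + exp((d - config$falloff_mm) /
                                     config$penumbra_mm)),
         config$bath * exp(-d / config$bath_scale_mm))
  dose <- falloff(d_out)
  surface <- falloff(0)
  ## voxel-centre depth starts one spacing inside; shift so boundary
  ## voxels sit at the surface dose
  d_in_eff <- pmax(d_in - max(spacing), 0)
  inside <- surface + config$ptv_boost * d_in_eff / (d_in_eff + 6)
  dose[ptv] <- inside[ptv]

  ## posterior attenuation ramps up below the anterior rectal wall
  ## (tracked per slice), carving the concave rectum-sparing pattern
  g <- coord_grids(shape, spacing)
  Y <- array(rep(rep(g$y, each = shape[1]), times = shape[3]), dim = shape)
  WALL <- array(rep(anatomy$geom$rectum_wall_y,
                    times = shape[2] * shape[3]), dim = shape)
  ramp <- pmin(pmax((Y - WALL - config$atten_deadzone_mm) /
                      config$atten_width_mm, 0), 1)
  dose <- dose * (1 - config$rectum_atten * ramp)

  dose <- dose * rx +
    smooth_noise_field(shape, config$noise_sigma_vox, sd = config$noise_gy)
  dose <- pmin(pmax(dose, 0), 1.10 * rx)
  dose[masks$body$values == 0L] <- 0
  dose_grid(dose, prescription = rx, n_fractions = config$n_fractions,
            spacing = spacing)
}

#' Generate a phantom cohort
#'
#' Deterministically generates `n` plan samples from the master seed (one
#' derived seed per sample), optionally writing each to disk as NIfTI
#' volumes plus a JSON manifest.
#'
#' @param config A [phantom_config()].
#' @param n Cohort size; defaults to `config$cohort_size`.
#' @param out_dir Optional output directory; when given, every sample is
#'   written via [write_plan_sample()].
#' @return A list of [plan_sample()] objects; when `out_dir` is used, the
#'   manifest paths are attached as attribute `"manifests"`.
#' @export
generate_cohort <- function(config, n = config$cohort_size,
                            out_dir = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max, n)
  samples <- vector("list", n)
  manifests <- character(0)
  for (i in seq_len(n)) {
    set.seed(sample_seeds[i])
    anatomy <- generate_anatomy(config)
    dose <- analytic_dose(anatomy, config)
    samples[[i]] <- plan_sample(sprintf("phantom_%03d", i),
                                anatomy$image, anatomy$masks, dose)
    if (!is.null(out_dir))
      manifests <- c(manifests, write_plan_sample(samples[[i]], out_dir))
  }
  if (!is.null(out_dir)) attr(samples, "manifests") <- manifests
  samples
}
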