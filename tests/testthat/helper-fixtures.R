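# Shared fixtures. Unit tests use a coarse phantom grid (same 192 mm
# field of view as the default, 6 mm voxels) so every stage runs in
# seconds; the acceptance tests use the default 3 mm grid.

small_phantom_config <- function(...) {
  phantom_config(shape = c(16, 32, 32), spacing = c(6, 6, 6), ...)
}

# One small phantom (anatomy + dose), cached per session.
local({
  cache <- new.env(parent = emptyenv())
  small_phantom <<- function(seed = 11) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cfg <- small_phantom_config()
      set.seed(seed)
      an <- generate_anatomy(cfg)
      dose <- analytic_dose(an, cfg)
      cache[[key]] <- plan_sample(paste0("fix", seed), an$image, an$masks,
                                  dose)
    }
    cache[[key]]
  }
})

# Default-configuration 60-phantom cohort with per-sample geometry,
# generated once per session (used by the cohort-level acceptance checks).
local({
  cache <- new.env(parent = emptyenv())
  default_cohort60 <<- function() {
    if (is.null(cache$cohort)) {
      cfg <- phantom_config()
      set.seed(cfg$seed)
      seeds <- sample.int(.Machine$integer.max, 60)
      cache$cohort <- lapply(1:60, function(i) {
        set.seed(seeds[i])
        an <- generate_anatomy(cfg)
        d <- analytic_dose(an, cfg)
        s <- plan_sample(sprintf("phantom_%03d", i), an$image, an$masks, d)
        attr(s, "geom") <- an$geom
        s
      })
    }
    cache$cohort
  }
})

# Simple synthetic dose/mask pair on a given grid for DVH tests.
toy_dose <- function(values, spacing = c(1, 1, 1), rx = 74.8, nfx = 34) {
  dose_grid(values, prescription = rx, n_fractions = nfx,
            spacing = spacing)
}

toy_mask <- function(values, roi = "rectum", spacing = c(1, 1, 1)) {
  structure_mask(values, roi, spacing = spacing)
}

# Uniform-dose DVH curve helper (structure entirely at one dose).
uniform_curve <- function(dose_gy, n_vox = 64, bin = 0.1) {
  arr <- array(dose_gy, dim = c(4, 4, n_vox / 16))
  msk <- array(1L, dim = dim(arr))
  compute_dvh(toy_dose(arr), toy_mask(msk), bin)
}

# Hand-constructed cumulative curve whose differential bins sit EXACTLY at
# the requested doses (narrow bins centred on each dose), for closed-form
# model checks free of histogram-discretization offsets.
exact_curve <- function(doses, vols, half = 0.01) {
  o <- order(doses)
  doses <- doses[o]; vols <- vols[o] / sum(vols)
  edges <- numeric(0); cum <- numeric(0)
  remaining <- 1
  prev_hi <- -Inf
  for (i in seq_along(doses)) {
    lo <- doses[i] - half; hi <- doses[i] + half
    if (lo > prev_hi) { edges <- c(edges, lo); cum <- c(cum, remaining) }
    remaining <- remaining - vols[i]
    edges <- c(edges, hi); cum <- c(cum, remaining)
    prev_hi <- hi
  }
  structure(list(edges = edges, cum_volume = 100 * cum,
                 n_voxels = 1000L, voxel_volume_mm3 = 1,
                 bin_width = 2 * half),
            class = "dvh_curve")
}
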