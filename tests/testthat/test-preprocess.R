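# Preprocessing chain: crop/resize, slice selection, coverage rescaling,
# normalization, channel assembly.

test_that("resizing a constant image stays constant and updates spacing", {
  vals <- array(3.5, c(4, 40, 40))
  rois <- c("PTV", "rectum", "bladder", "femoral_head_L",
            "femoral_head_R")
  masks <- list()
  for (nm in rois)
    masks[[nm]] <- toy_mask(local({
      a <- array(0L, c(4, 40, 40))
      a[2:3, 9:16, 1 + 6 * match(nm, rois) + 0:4] <- 1L
      a
    }), nm, spacing = c(2.5, 0.98, 0.98))
  body <- array(0L, c(4, 40, 40)); body[, 3:38, 3:38] <- 1L
  masks$body <- toy_mask(body, "body", spacing = c(2.5, 0.98, 0.98))
  s <- plan_sample("const",
                   image_volume(vals, c(2.5, 0.98, 0.98)),
                   masks,
                   toy_dose(array(50, c(4, 40, 40)),
                            spacing = c(2.5, 0.98, 0.98)))
  cfg <- preprocess_config(crop_size = 40, target_size = 10)
  out <- crop_and_resize(s, cfg)
  expect_equal(dim(out$image$values), c(4, 10, 10))
  expect_true(all(abs(out$image$values - 3.5) < 1e-9))
  expect_true(all(abs(out$dose$values - 50) < 1e-9))
  # 0.98 mm at a 40 -> 10 reduction becomes 3.92 mm in-plane
  expect_equal(out$image$spacing, c(2.5, 3.92, 3.92), tolerance = 1e-9)
})

test_that("the clinical 400-to-128 reduction yields 3.06 mm pixels", {
  scale <- 400 / 128
  expect_equal(round(0.98 * scale, 2), 3.06)
})

test_that("nearest-neighbour mask resize preserves area approximately", {
  # 20-pixel-radius disk, downsampled 2x: count scales by ~1/4
  n <- 80
  disk <- outer(1:n, 1:n, function(i, j) (i - 40)^2 + (j - 40)^2 <= 400)
  arr <- array(0L, c(1, n, n)); arr[1, , ] <- disk
  resized <- EBImage::resize(disk * 1, w = 40, h = 40, filter = "none")
  expect_lt(abs(sum(resized) - sum(disk) / 4) / (sum(disk) / 4), 0.15)
})

test_that("mask resampling preserves connected-component topology", {
  s <- small_phantom()
  cfg <- preprocess_config(crop_size = 32, target_size = 16)
  out <- crop_and_resize(s, cfg)
  for (nm in c("PTV", "bladder")) {
    before <- max(EBImage::bwlabel(
      s$masks[[nm]]$values[which.max(apply(s$masks[[nm]]$values, 1, sum)),
                           , ]))
    after <- max(EBImage::bwlabel(
      out$masks[[nm]]$values[which.max(apply(out$masks[[nm]]$values, 1,
                                             sum)), , ]))
    expect_equal(after, before, info = nm)
  }
})

test_that("slice selection covers PTV plus margin with centred capping", {
  dm <- c(30, 8, 8)
  mk <- function(slices) {
    a <- array(0L, dm); a[slices, 3:6, 3:6] <- 1L
    a
  }
  masks <- list(PTV = mk(10:20), rectum = mk(10:20), bladder = mk(10:20),
                femoral_head_L = mk(10:20), femoral_head_R = mk(10:20),
                body = mk(1:30))
  masks <- lapply(names(masks), function(nm)
    toy_mask(masks[[nm]], nm, spacing = c(2.5, 1, 1)))
  names(masks) <- ROI_NAMES
  s <- plan_sample("sl", image_volume(array(0, dm), c(2.5, 1, 1)), masks,
                   toy_dose(array(1, dm), spacing = c(2.5, 1, 1)))
  # 1 cm margin at 2.5 mm slices = 4 slices each side
  expect_equal(select_slices(s, preprocess_config(margin_mm = 10)), 6:24)
  expect_equal(select_slices(s, preprocess_config(margin_mm = 0)), 10:20)
  # cap: full coverage truncated symmetrically about the PTV centroid
  capped <- select_slices(s, preprocess_config(margin_mm = 40,
                                               max_slices = 9))
  expect_length(capped, 9)
  expect_equal(round(mean(capped)), 15)
  expect_equal(diff(range(capped)), 8) # consecutive
})

test_that("coverage rescaling hits the fixed point and is idempotent", {
  s <- small_phantom()
  cfg <- preprocess_config()
  out <- rescale_to_coverage(s$dose, s$masks$PTV, cfg)
  d95 <- dose_at_volume_exact <- rtdosepred:::dose_at_volume_exact(
    out$values, s$masks$PTV$values, 95)
  expect_equal(d95, 0.95 * 74.8, tolerance = 1e-12)
  # binned-DVH D95 agrees within one interpolation bin
  d95_dvh <- dose_at_volume(compute_dvh(out, s$masks$PTV), 95)
  expect_lt(abs(d95_dvh - 71.06), 0.1)
  # second application is the identity to 1e-9
  again <- rescale_to_coverage(out, s$masks$PTV, cfg)
  expect_equal(attr(again, "scale_factor"), 1, tolerance = 1e-9)

  # uniform 70 Gy in the PTV at 74.8 Gy prescription: factor 71.06/70
  u <- s$dose
  u$values <- array(70, dim = dim(u$values))
  ru <- rescale_to_coverage(u, s$masks$PTV, cfg)
  expect_equal(attr(ru, "scale_factor"), 71.06 / 70, tolerance = 1e-9)
  expect_equal(max(ru$values), 71.06, tolerance = 1e-9)

  z <- s$dose; z$values <- array(0, dim = dim(z$values))
  expect_error(rescale_to_coverage(z, s$masks$PTV, cfg), "zero")
})

test_that("global normalization maps the cohort into [0,1] and inverts", {
  doses <- lapply(c(60, 82.3, 74), function(m) {
    s <- small_phantom()
    d <- s$dose
    d$values <- d$values / max(d$values) * m
    d
  })
  nrm <- normalize_global(doses)
  expect_equal(nrm$constant, 82.3)
  expect_true(all(vapply(nrm$normalized, max, numeric(1)) <= 1))
  expect_equal(max(nrm$normalized[[2]]), 1)
  # denormalize . normalize = identity
  back <- nrm$normalized[[1]] * nrm$constant
  expect_equal(back, doses[[1]]$values, tolerance = 1e-6)
  # single-sample cohort: constant is that sample's max
  one <- normalize_global(doses[2])
  expect_equal(one$constant, 82.3)
  expect_error(normalize_global(list()), "empty")
})

test_that("channel stacks have the canonical order and properties", {
  s <- small_phantom()
  cfg <- preprocess_config(target_size = 32)
  stack <- assemble_channels(s, cfg)
  expect_equal(dim(stack$data)[4], 7)
  expect_equal(stack$channels,
               c("CT", "rectum", "bladder", "femoral_head_L",
                 "femoral_head_R", "PTV", "body"))
  expect_true(all(stack$data >= 0 & stack$data <= 1))
  # mask channels are binary after assembly
  for (ch in 2:7)
    expect_true(all(stack$data[, , , ch] %in% c(0, 1)), info = ch)
  # body channel contains every organ channel voxelwise
  body <- stack$data[, , , 7]
  for (ch in 2:6)
    expect_true(all(stack$data[, , , ch] <= body), info = ch)
  # permuting the mask list does not change the channel order
  s2 <- s
  s2$masks <- s$masks[rev(names(s$masks))]
  s2 <- plan_sample(s$id, s$image, s2$masks, s$dose)
  stack2 <- assemble_channels(s2, cfg)
  expect_identical(stack$data, stack2$data)
})

test_that("preprocessing is deterministic given the configuration", {
  s <- small_phantom()
  cfg <- preprocess_config(crop_size = 32, target_size = 16)
  a <- preprocess_cohort(list(s), cfg)
  b <- preprocess_cohort(list(s), cfg)
  expect_identical(a$stacks[[1]]$data, b$stacks[[1]]$data)
  expect_identical(a$doses, b$doses)
  expect_identical(a$norm_constant, b$norm_constant)
})
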