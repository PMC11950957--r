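# U-net model: architecture contracts, gradient correctness, optimizer
# sanity, cross-validation mechanics, ensemble identities.

test_that("the network maps a 7-channel stack to a single dose channel", {
  cfg <- net_config(base_features = 4, depth = 2)
  model <- build_unet(cfg, seed = 5)
  H <- 32
  x <- as.numeric(array(rnorm(H * H * 7), c(H * H, 7, 1)))
  out <- rtdosepred:::.unet_predict(model$params, unclass(cfg), x,
                                    H, H, 7L, 1L)
  expect_equal(dim(out), c(H * H, 1))
  # the clinical-resolution geometry: 128 x 128 in, 128 x 128 out
  x2 <- as.numeric(array(rnorm(128 * 128 * 7), c(128 * 128, 7, 1)))
  out2 <- rtdosepred:::.unet_predict(model$params, unclass(cfg), x2,
                                     128L, 128L, 7L, 1L)
  expect_equal(dim(out2), c(128 * 128, 1))
  # indivisible spatial size is rejected
  x3 <- as.numeric(array(rnorm(30 * 30 * 7), c(30 * 30, 7, 1)))
  expect_error(
    rtdosepred:::.unet_predict(model$params, unclass(cfg), x3,
                               30L, 30L, 7L, 1L),
    "divisible")
})

test_that("inference is deterministic for fixed weights and input", {
  cfg <- net_config(base_features = 4, depth = 2)
  model <- build_unet(cfg, seed = 5)
  x <- as.numeric(array(rnorm(32 * 32 * 7), c(32 * 32, 7, 2)))
  a <- rtdosepred:::.unet_predict(model$params, unclass(cfg), x,
                                  32L, 32L, 7L, 2L)
  b <- rtdosepred:::.unet_predict(model$params, unclass(cfg), x,
                                  32L, 32L, 7L, 2L)
  expect_identical(a, b)
})

test_that("trainable parameter count matches the architecture arithmetic", {
  # hand walk: block(cin, cout) = 9*cin*cout + cout (conv1) +
  #   9*cout^2 + cout (conv2) + 4*cout (two BN scale/offset pairs) +
  #   [cin*cout + cout if cin != cout]
  block_n <- function(cin, cout)
    9 * cin * cout + cout + 9 * cout^2 + cout + 4 * cout +
      if (cin != cout) cin * cout + cout else 0
  for (spec in list(c(4, 2), c(8, 3), c(6, 1))) {
    base <- spec[1]; depth <- spec[2]
    expected <- 0
    for (l in seq_len(depth) - 1) {
      cl <- base * 2^l; cn <- 2 * cl
      cin <- if (l == 0) 7 else cl
      expected <- expected + block_n(cin, cl) + # encoder block
        (4 * cl * cn + cn) +                    # down conv 2x2
        (cn * 4 * cl + cl) +                    # up tconv 2x2
        block_n(2 * cl, cl)                     # decoder block
    }
    cd <- base * 2^depth
    expected <- expected + block_n(cd, cd) + (base * 1 + 1)
    model <- build_unet(net_config(base_features = base, depth = depth))
    expect_equal(count_params(model), expected,
                 info = paste(base, depth))
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- net_config(in_channels = 3, base_features = 2, depth = 1,
                    dropout = 0)
  set.seed(5)
  H <- 8; C <- 3; N <- 2
  model <- build_unet(cfg, seed = 42)
  p <- model$params
  x <- rnorm(H * H * C * N) * 0.3
  y <- matrix(rnorm(H * H * N) * 0.1, H * H, N)
  lg <- rtdosepred:::.unet_loss_grads(p, unclass(cfg), x, y, H, H, C, N)
  # directional derivative per tensor; conv biases feeding batch norm have
  # an exactly zero gradient and only finite-difference noise, so skip
  for (nm in c("enc0.conv1.W", "enc0.bn1.g", "enc0.proj.W", "down0.W",
               "up0.W", "dec0.conv2.W", "bott.conv1.W", "head.W",
               "head.b")) {
    dir <- array(rnorm(length(p[[nm]])), dim = dim(p[[nm]]))
    dir <- dir / sqrt(sum(dir^2))
    eps <- 1e-3
    p1 <- p; p1[[nm]] <- p1[[nm]] + eps * dir
    p2 <- p; p2[[nm]] <- p2[[nm]] - eps * dir
    l1 <- rtdosepred:::.unet_loss_grads(p1, unclass(cfg), x, y, H, H,
                                        C, N)$loss
    l2 <- rtdosepred:::.unet_loss_grads(p2, unclass(cfg), x, y, H, H,
                                        C, N)$loss
    fd <- (l1 - l2) / (2 * eps)
    an <- sum(lg$grads[[nm]] * dir)
    expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 0.15, label = nm)
  }
})

test_that("training memorizes a small slice set and is reproducible", {
  cfg <- net_config(base_features = 8, depth = 2, dropout = 0.1)
  set.seed(3)
  H <- 32; C <- 7; N <- 5
  base_in <- array(0, c(H, H, C))
  base_in[10:20, 10:20, 6] <- 1
  base_in[, , 1] <- matrix(runif(H * H), H, H)
  x <- as.numeric(replicate(N, base_in))
  tgt <- outer(1:H, 1:H,
               function(i, j) 0.9 * exp(-((i - 16)^2 + (j - 16)^2) / 80))
  y <- matrix(rep(as.numeric(tgt), N), H * H, N)
  model <- build_unet(cfg, seed = 7)
  res <- rtdosepred:::.unet_train(model$params, unclass(cfg), x, y,
                                  H, H, C, N, 0:4, integer(0),
                                  600L, 5L, 3e-3, 0.9, 0.999, 11L)
  expect_lt(res$train_loss[600], res$train_loss[1] / 100)
  pred <- rtdosepred:::.unet_predict(res$params, unclass(cfg), x,
                                     H, H, C, N)
  expect_lt(mean((pred - y)^2), 1e-3)

  # same seed, same loss history
  r2 <- rtdosepred:::.unet_train(model$params, unclass(cfg), x, y,
                                 H, H, C, N, 0:4, integer(0),
                                 20L, 5L, 3e-3, 0.9, 0.999, 11L)
  r3 <- rtdosepred:::.unet_train(model$params, unclass(cfg), x, y,
                                 H, H, C, N, 0:4, integer(0),
                                 20L, 5L, 3e-3, 0.9, 0.999, 11L)
  expect_identical(r2$train_loss, r3$train_loss)
})

test_that("fold splits partition the cohort with balanced sizes", {
  f <- fold_split(60, 5, seed = 2)
  expect_length(f, 5)
  expect_true(all(vapply(f, length, integer(1)) == 12))
  expect_equal(sort(unlist(f)), 1:60)
  f2 <- fold_split(13, 5, seed = 2)
  expect_true(all(abs(vapply(f2, length, integer(1)) - 13 / 5) <= 1))
  expect_equal(sort(unlist(f2)), 1:13)
  expect_error(fold_split(4, 5), "n >= folds")
})

test_that("cross-validation trains one model per fold, including
           leave-one-out", {
  cfg <- small_phantom_config()
  set.seed(31)
  cohort <- generate_cohort(cfg, n = 5)
  pp <- preprocess_config(target_size = 16, crop_size = 32)
  pre <- preprocess_cohort(cohort, pp)
  ncfg <- net_config(base_features = 2, depth = 1)
  tcfg <- train_config(epochs = 2, folds = 5, seed = 9, batch_size = 8)
  cv <- cross_validate(pre$stacks, pre$doses, ncfg, tcfg)
  expect_length(cv$models, 5)
  expect_equal(sort(unlist(cv$folds)), 1:5)
  expect_true(all(is.finite(cv$val_mse)))
  expect_error(cross_validate(pre$stacks[1:3], pre$doses[1:3], ncfg,
                              tcfg),
               "smaller than fold count")
})

test_that("ensemble prediction averages members and clamps at zero", {
  s <- small_phantom()
  pp <- preprocess_config(target_size = 16, crop_size = 32)
  pre <- preprocess_cohort(list(s), pp)
  stack <- pre$stacks[[1]]
  cfg <- net_config(base_features = 2, depth = 1)
  m1 <- build_unet(cfg, seed = 1)
  m2 <- build_unet(cfg, seed = 2)
  p1 <- ensemble_predict(list(m1), stack)
  p2 <- ensemble_predict(list(m2), stack)
  p12 <- ensemble_predict(list(m1, m2), stack)
  # mean of one model is that model; two-model ensemble is the voxel mean
  # of members (up to the final non-negativity clamp)
  expect_equal(dim(p1), dim(stack$data)[1:3])
  expect_true(all(p1 >= 0))
  raw <- function(m) {
    dm <- dim(stack$data)
    x <- array(0, c(dm[2] * dm[3], dm[4], dm[1]))
    for (k in seq_len(dm[1]))
      x[, , k] <- matrix(stack$data[k, , , ], dm[2] * dm[3], dm[4])
    rtdosepred:::.unet_predict(m$params, unclass(cfg), as.numeric(x),
                               dm[2], dm[3], dm[4], dm[1])
  }
  manual <- (raw(m1) + raw(m2)) / 2
  manual_arr <- array(0, dim(p12))
  for (k in seq_len(dim(p12)[1]))
    manual_arr[k, , ] <- matrix(manual[, k], dim(p12)[2], dim(p12)[3])
  expect_equal(p12, pmax(manual_arr, 0), tolerance = 1e-6)

  # mismatched configurations are rejected
  m3 <- build_unet(net_config(base_features = 4, depth = 1), seed = 1)
  expect_error(ensemble_predict(list(m1, m3), stack), "mismatch")
})

test_that("models survive a save/load round trip", {
  cfg <- net_config(base_features = 2, depth = 1)
  m <- build_unet(cfg, seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$params, m$params)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$base_features, 2)
})
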