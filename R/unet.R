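## 2D U-net dose prediction: model configuration, 5-fold cross-validation
## training and fold-ensemble prediction. The network itself (residual
## convolution blocks with batch normalization and dropout, skip
## concatenations, strided-convolution downsampling, transposed-convolution
## upsampling, Adam on voxelwise MSE) runs in compiled code; see the
## methods vignette for the architecture.

#' U-net architecture configuration
#'
#' The encoder halves the spatial size `depth` times while doubling the
#' feature count from `base_features`; the decoder mirrors it with skip
#' concatenations. Residual connections and batch normalization are part
#' of every block, with a dropout layer after every second
#' batch-normalization layer.
#'
#' @param in_channels Input channels (the 7-channel anatomy stack).
#' @param base_features Feature maps at the first level.
#' @param depth Number of downsamplings; input size must be divisible by
#'   `2^depth`.
#' @param dropout Dropout rate (default 0.1).
#' @return An object of class `net_config`.
#' @export
net_config <- function(in_channels = 7, base_features = 8, depth = 3,
                       dropout = 0.1) {
  stopifnot(in_channels >= 1, base_features >= 1, depth >= 1,
            dropout >= 0, dropout < 1)
  structure(list(in_channels = as.integer(in_channels),
                 base_features = as.integer(base_features),
                 depth = as.integer(depth), dropout = dropout),
            class = "net_config")
}

#' Training configuration
#'
#' Defaults follow the clinical-scale recipe (Adam, learning rate 1e-3,
#' beta1 0.9, beta2 0.999, no weight decay, mini-batches of 15 slices,
#' 250 epochs, 5 folds); desk-scale runs lower `epochs`.
#'
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Mini-batch size in slices.
#' @param epochs Training epochs per fold.
#' @param folds Cross-validation folds (>= 2 for a real split).
#' @param seed Master seed for fold assignment, initialization, shuffling
#'   and dropout.
#' @return An object of class `train_config`. The loss is always the
#'   voxelwise mean squared error between planned and predicted
#'   normalized doses.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, batch_size = 15, epochs = 250,
                         folds = 5, seed = 1) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0,
            beta2 < 1, batch_size >= 1, epochs >= 1, folds >= 2)
  structure(list(learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build (initialize) a U-net model
#'
#' @param cfg A [net_config()].
#' @param seed Initialization seed (He-normal weights).
#' @return An object of class `unet_model`: the configuration plus the
#'   named parameter list (convolution kernels, batch-norm scales/offsets
#'   and running statistics).
#' @export
build_unet <- function(cfg = net_config(), seed = 1) {
  params <- .unet_init(unclass(cfg), as.integer(seed))
  structure(list(config = cfg, params = params), class = "unet_model")
}

#' Trainable parameter count of a model
#'
#' Counts every convolution weight/bias and batch-norm scale/offset;
#' batch-norm running statistics are state, not parameters.
#'
#' @param model A `unet_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  nm <- names(model$params)
  trainable <- !grepl("\\.(rm|rv)$", nm)
  sum(vapply(model$params[trainable], length, integer(1)))
}

## Flatten channel stacks + normalized dose arrays into the contiguous
## tensors the compiled trainer expects: x of shape (H*W, C, n_slices)
## and y of shape (H*W, n_slices), plus the per-sample slice ownership.
stack_tensors <- function(stacks, doses) {
  stopifnot(length(stacks) == length(doses), length(stacks) >= 1)
  dm <- dim(stacks[[1]]$data) # (slices, H, W, C)
  H <- dm[2]; W <- dm[3]; C <- dm[4]
  n_slices <- vapply(stacks, function(s) dim(s$data)[1], integer(1))
  total <- sum(n_slices)
  x <- array(0, dim = c(H * W, C, total))
  y <- matrix(0, H * W, total)
  owner <- integer(total)
  pos <- 0L
  for (i in seq_along(stacks)) {
    sd <- stacks[[i]]$data
    for (k in seq_len(dim(sd)[1])) {
      pos <- pos + 1L
      x[, , pos] <- matrix(sd[k, , , ], H * W, C)
      y[, pos] <- as.vector(doses[[i]][k, , ])
      owner[pos] <- i
    }
  }
  list(x = x, y = y, owner = owner, H = H, W = W, C = C)
}

#' 5-fold split of sample indices
#'
#' Randomly partitions sample indices into `folds` disjoint validation
#' subsets of equal size (within one).
#'
#' @param n Number of samples.
#' @param folds Number of folds.
#' @param seed RNG seed for the random assignment.
#' @return List of integer vectors (validation indices per fold); their
#'   union is `1:n` and they are pairwise disjoint.
#' @export
fold_split <- function(n, folds = 5, seed = 1) {
  stopifnot(n >= folds, folds >= 2)
  set.seed(seed)
  perm <- sample.int(n)
  assign <- rep(seq_len(folds), length.out = n)
  lapply(seq_len(folds), function(f) sort(perm[assign == f]))
}

#' Train one cross-validation fold
#'
#' Trains a fresh model on all slices of the samples outside the fold's
#' validation subset, recording per-epoch training loss (mean over
#' mini-batches) and eval-mode validation MSE. All randomness derives
#' from `tcfg$seed` and the fold index.
#'
#' @param tensors Result of [stack_tensors()].
#' @param val_samples Integer indices of the validation samples.
#' @param ncfg A [net_config()].
#' @param tcfg A [train_config()].
#' @param fold Fold index (used to decorrelate seeds between folds).
#' @return A `unet_model` with `history` (data.frame of per-epoch train
#'   and validation MSE) attached.
#' @export
train_fold <- function(tensors, val_samples, ncfg = net_config(),
                       tcfg = train_config(), fold = 1L) {
  tr_idx <- which(!(tensors$owner %in% val_samples)) - 1L
  va_idx <- which(tensors$owner %in% val_samples) - 1L
  if (!length(tr_idx)) stop("empty training fold", call. = FALSE)
  seed_f <- (tcfg$seed + 7919L * as.integer(fold)) %% .Machine$integer.max
  model <- build_unet(ncfg, seed = seed_f)
  res <- .unet_train(model$params, unclass(ncfg), as.numeric(tensors$x),
                     tensors$y, tensors$H, tensors$W, tensors$C,
                     dim(tensors$x)[3], tr_idx, va_idx,
                     tcfg$epochs, tcfg$batch_size, tcfg$learning_rate,
                     tcfg$beta1, tcfg$beta2, seed_f)
  model$params <- res$params
  model$history <- data.frame(epoch = seq_len(tcfg$epochs),
                              train_mse = res$train_loss,
                              val_mse = res$val_loss)
  model
}

#' 5-fold cross-validation training
#'
#' Randomly partitions the cohort into validation subsets, trains one
#' model per fold and reports the final validation losses.
#'
#' @param stacks List of `channel_stack`s (training cohort).
#' @param doses List of normalized dose arrays matching `stacks`.
#' @param ncfg A [net_config()].
#' @param tcfg A [train_config()].
#' @return List with `models` (one `unet_model` per fold), `folds` (the
#'   validation partition) and `val_mse` (final-epoch validation MSE per
#'   fold).
#' @export
cross_validate <- function(stacks, doses, ncfg = net_config(),
                           tcfg = train_config()) {
  if (length(stacks) < tcfg$folds)
    stop("cohort smaller than fold count", call. = FALSE)
  tensors <- stack_tensors(stacks, doses)
  folds <- fold_split(length(stacks), tcfg$folds, tcfg$seed)
  models <- vector("list", tcfg$folds)
  val_mse <- numeric(tcfg$folds)
  for (f in seq_len(tcfg$folds)) {
    models[[f]] <- train_fold(tensors, folds[[f]], ncfg, tcfg, fold = f)
    val_mse[f] <- utils::tail(models[[f]]$history$val_mse, 1)
  }
  list(models = models, folds = folds, val_mse = val_mse)
}

#' Fold-ensemble prediction for one channel stack
#'
#' The final model is the average of the fold models: the prediction is
#' the voxelwise arithmetic mean of the member predictions (dropout
#' disabled, batch-norm in inference mode), clamped to be non-negative.
#'
#' @param models List of `unet_model`s sharing one configuration.
#' @param stack A `channel_stack`.
#' @return 3D array `[slice, row, col]` of predicted normalized dose.
#' @export
ensemble_predict <- function(models, stack) {
  stopifnot(length(models) >= 1)
  cfg <- models[[1]]$config
  for (m in models)
    if (!identical(unclass(m$config), unclass(cfg)))
      stop("ensemble members have mismatched configurations",
           call. = FALSE)
  dm <- dim(stack$data) # (slices, H, W, C)
  n <- dm[1]
  x <- array(0, dim = c(dm[2] * dm[3], dm[4], n))
  for (k in seq_len(n))
    x[, , k] <- matrix(stack$data[k, , , ], dm[2] * dm[3], dm[4])
  acc <- matrix(0, dm[2] * dm[3], n)
  for (m in models)
    acc <- acc + .unet_predict(m$params, unclass(cfg), as.numeric(x),
                               dm[2], dm[3], dm[4], n)
  acc <- acc / length(models)
  out <- array(0, dim = dm[1:3])
  for (k in seq_len(n)) out[k, , ] <- matrix(acc[, k], dm[2], dm[3])
  pmax(out, 0)
}

#' Predict a full dose grid for a preprocessed sample
#'
#' Runs the fold ensemble on the sample's channel stack, denormalizes by
#' the training-cohort constant, embeds the selected slices back into the
#' full grid, and applies the coverage rescaling using the predicted PTV
#' D95% (or the planned dose's, when `rescale_by = "planned"`).
#'
#' @param models List of `unet_model`s (the fold ensemble).
#' @param sample The preprocessed [plan_sample()] (for grid geometry and
#'   the PTV mask).
#' @param stack The sample's `channel_stack`.
#' @param norm_constant Training-cohort global maximum dose in Gy.
#' @param cfg A [preprocess_config()].
#' @param rescale_by `"predicted"` (default) or `"planned"`: whose PTV
#'   D95% anchors the coverage rescaling of the prediction.
#' @return A [dose_grid()] of the predicted dose.
#' @export
predict_dose <- function(models, sample, stack, norm_constant,
                         cfg = preprocess_config(),
                         rescale_by = c("predicted", "planned")) {
  rescale_by <- match.arg(rescale_by)
  pred <- ensemble_predict(models, stack) * norm_constant
  full <- array(0, dim = dim(sample$image$values))
  full[stack$slices, , ] <- pred
  out <- dose_grid(full, prescription = sample$dose$prescription,
                   n_fractions = sample$dose$n_fractions,
                   spacing = sample$image$spacing,
                   origin = sample$image$origin)
  if (rescale_by == "predicted") {
    out <- rescale_to_coverage(out, sample$masks$PTV, cfg)
  } else {
    f <- cfg$coverage_fraction * sample$dose$prescription /
      dose_at_volume_exact(sample$dose$values, sample$masks$PTV$values,
                           100 * cfg$coverage_volume)
    out$values <- out$values * f
  }
  out
}

#' Save / load a trained model
#'
#' Persists the parameter list in R's serialization format with a JSON
#' sidecar recording the architecture configuration.
#'
#' @param model A `unet_model`.
#' @param path Output path (`.rds`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}
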