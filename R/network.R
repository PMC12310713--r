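#' Build a FLA-UNet (or plain U-Net baseline) model
#'
#' Assembles the segmentation backbone: five encoder stages (two
#' conv3x3+BN+ReLU blocks each, 2x2 max pooling between stages, channel
#' count doubling per stage) and four decoder stages (bilinear 2x
#' upsampling, skip concatenation, an optional feature-location attention
#' block that halves the concatenated channels, two conv blocks), closed by
#' a 1x1 convolution and a per-pixel softmax over classes. With
#' `use_flab = FALSE` the attention blocks are dropped and the model is the
#' plain bilinear-upsampling U-Net used as the ablation baseline.
#'
#' Weights live in a float32 engine behind an external pointer; use
#' [model_weights()] / [set_model_weights()] or [save_checkpoint()] to move
#' them in and out.
#'
#' @param in_channels input image channels (1 for grayscale OCTA).
#' @param num_classes output classes (2: background, FAZ).
#' @param base_width channel count of the first encoder stage; must be even.
#' @param use_flab embed feature-location attention blocks in the decoders.
#' @param pool_kernel odd pooling window of the attention branches.
#' @param hidden_width hidden width of the attention feature branch.
#' @param share_across_channels share one attention parameter set across all
#'   channels of a block (default) or learn per-channel parameters.
#' @param seed integer seed for Kaiming weight initialization.
#' @return an object of class `fla_unet`.
#' @examples
#' net <- fla_unet(base_width = 4, seed = 1)
#' x <- array(rnorm(1 * 1 * 32 * 32), c(1, 1, 32, 32))
#' out <- fla_unet_forward(net, x)
#' dim(out$probabilities)
#' @export
fla_unet <- function(in_channels = 1L, num_classes = 2L, base_width = 64L,
                     use_flab = TRUE, pool_kernel = 3L, hidden_width = 2L,
                     share_across_channels = TRUE, seed = 1L) {
  config <- list(
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    base_width = as.integer(base_width),
    use_flab = isTRUE(use_flab),
    pool_kernel = as.integer(pool_kernel),
    hidden_width = as.integer(hidden_width),
    share_across_channels = isTRUE(share_across_channels)
  )
  if (config$base_width < 2L || config$base_width %% 2L != 0L)
    stop("base_width must be an even integer >= 2")
  ptr <- .unet_create(config, as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "fla_unet")
}

#' @export
print.fla_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fla_unet> %s, base_width=%d, in=%d, classes=%d, seed=%d\n",
              if (cfg$use_flab) "with attention blocks" else "plain U-Net",
              cfg$base_width, cfg$in_channels, cfg$num_classes, x$seed))
  cat(sprintf("  parameters: %s\n",
              format(param_census(x)$total, big.mark = ",")))
  invisible(x)
}

as_batch4 <- function(x, in_channels = 1L) {
  if (is.matrix(x)) {
    dim(x) <- c(1L, 1L, nrow(x), ncol(x))
  } else if (length(dim(x)) == 3L) {
    d <- dim(x)                    # (N, H, W) single-channel stack
    x <- array(x, c(d[1], 1L, d[2], d[3]))
  } else if (length(dim(x)) != 4L) {
    stop("expected a matrix or a 3-D/4-D array")
  }
  storage.mode(x) <- "double"
  x
}

#' Full forward pass: probabilities and predicted mask
#'
#' @param model a [fla_unet()] model.
#' @param x input images: an (N, C, H, W) array, an (N, H, W) stack, or a
#'   single H x W matrix. H and W must be divisible by 16.
#' @param stages if `TRUE`, also return all encoder/decoder intermediate
#'   feature maps (memory-heavy; meant for inspection and testing).
#' @return a list of class `segmentation_output` with `probabilities`
#'   (N, num_classes, H, W), `predicted_mask` (N, H, W) and `logits`.
#' @export
fla_unet_forward <- function(model, x, stages = FALSE) {
  x <- as_batch4(x, model$config$in_channels)
  out <- .unet_forward(model$ptr, x, isTRUE(stages))
  class(out) <- "segmentation_output"
  out
}

#' Encoder features of the five stages
#'
#' Stage s output has `base_width * 2^(s-1)` channels at 1/2^(s-1) of the
#' input resolution.
#'
#' @inheritParams fla_unet_forward
#' @return list of 5 arrays (N, C_s, H_s, W_s), shallowest first.
#' @export
encoder_forward <- function(model, x) {
  .unet_encoder_forward(model$ptr, as_batch4(x))
}

#' Run the decoder chain on given bottom and skip features
#'
#' @param model a [fla_unet()] model.
#' @param bottom deepest feature map (N, 16*base_width, H/16, W/16).
#' @param skips list of 4 encoder feature maps, deepest first.
#' @return final decoder feature map (N, base_width, H, W).
#' @export
decoder_forward <- function(model, bottom, skips) {
  stopifnot(is.list(skips))
  .unet_decoder_forward(model$ptr, as_batch4(bottom),
                        lapply(skips, as_batch4))
}

#' Apply one conv3x3 + batch-norm + ReLU block of the model
#'
#' @param model a [fla_unet()] model.
#' @param which `"enc"` or `"dec"`.
#' @param stage encoder stage 1..5 or decoder level 1..4.
#' @param block block index within the stage (1 or 2).
#' @param x input feature map, (N, C_in, H, W).
#' @param train use batch statistics (`TRUE`) or running statistics.
#' @return output feature map array.
#' @export
conv_block_apply <- function(model, which, stage, block, x, train = FALSE) {
  .unet_conv_block_apply(model$ptr, which, as.integer(stage),
                         as.integer(block), as_batch4(x), isTRUE(train))
}

#' Apply the attention block of one decoder level
#'
#' @param model a [fla_unet()] model built with `use_flab = TRUE`.
#' @param level decoder level 1 (deepest) to 4.
#' @param x concatenated feature map with the level's channel count.
#' @return list with `out` (channels halved), `gates` and `gated` maps.
#' @export
flab_apply <- function(model, level, x) {
  .unet_flab_apply(model$ptr, as.integer(level), as_batch4(x))
}

#' One optimization step on a batch (Adam, joint loss)
#'
#' @param model a [fla_unet()] model (updated in place).
#' @param x input batch (N, C, H, W).
#' @param y integer mask batch (N, H, W), labels in 0..num_classes-1.
#' @param lr Adam learning rate.
#' @param weights a [loss_weights()] pair (Dice weight, CE weight).
#' @return list with `loss`, `dice_loss`, `ce_loss` for the batch.
#' @export
train_step <- function(model, x, y, lr = 0.01, weights = loss_weights()) {
  y <- as_mask3(y)
  .unet_train_step(model$ptr, as_batch4(x), y, lr, weights$w1, weights$w2)
}

#' Joint loss and parameter gradients without updating the model
#'
#' Runs forward + backward and returns the loss together with the gradient
#' of every parameter tensor, for finite-difference verification.
#'
#' @inheritParams train_step
#' @return list with `loss`, `dice_loss`, `ce_loss` and named `grads`.
#' @export
loss_gradients <- function(model, x, y, weights = loss_weights()) {
  .unet_loss_grads(model$ptr, as_batch4(x), as_mask3(y), weights$w1, weights$w2)
}

as_mask3 <- function(y) {
  if (is.matrix(y)) dim(y) <- c(1L, nrow(y), ncol(y))
  if (length(dim(y)) != 3L) stop("mask must be (N, H, W) or a matrix")
  storage.mode(y) <- "integer"
  y
}

#' @rdname model_weights
#' @export
param_census <- function(model) .unet_census(model$ptr)

#' Get or set all model weights
#'
#' Weights are returned as a named list of double arrays (conv kernels in
#' (C_out, C_in, kh, kw) layout, batch-norm parameters and running
#' statistics as vectors). `param_census()` returns per-tensor element
#' counts and the total trainable parameter count.
#'
#' @param model a [fla_unet()] model.
#' @param weights named list as returned by `model_weights()`.
#' @return `model_weights()`: named list; `set_model_weights()`: the model,
#'   invisibly.
#' @export
model_weights <- function(model) .unet_get_weights(model$ptr)

#' @rdname model_weights
#' @export
set_model_weights <- function(model, weights) {
  .unet_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the network configuration,
#' the seed, and every weight tensor, plus a human-readable JSON sidecar
#' (`<path>.json`) echoing the configuration.
#'
#' @param model a [fla_unet()] model.
#' @param path file path for the checkpoint.
#' @return `save_checkpoint()`: `path`, invisibly; `load_checkpoint()`: a
#'   restored `fla_unet` model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = model$config, seed = model$seed,
              weights = model_weights(model),
              package_version = as.character(packageVersion("fazseg")))
  saveRDS(obj, path)
  jsonlite::write_json(
    list(config = model$config, seed = model$seed,
         package_version = obj$package_version),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- do.call(fla_unet, c(obj$config, list(seed = obj$seed)))
  set_model_weights(model, obj$weights)
  model
}

#' Convert exported attention-block weights to reference parameters
#'
#' Extracts the FLAB weights of one decoder level from a model and reshapes
#' them into a [flab_params()] object, so the float32 network path can be
#' cross-checked against the double-precision reference [flab_forward()].
#'
#' @param model a [fla_unet()] model with attention blocks.
#' @param level decoder level 1..4.
#' @return a `flab_params` object.
#' @export
flab_params_from_model <- function(model, level) {
  stopifnot(model$config$use_flab)
  w <- model_weights(model)
  base <- model$config$base_width
  C <- 3L * base * 2L^(3L - (level - 1L))
  r <- model$config$hidden_width
  pick <- function(nm) {
    key <- paste0("flab", level, "_", nm)
    if (is.null(w[[key]])) stop("missing weight ", key)
    w[[key]]
  }
  share <- model$config$share_across_channels
  one_branch <- function(prefix) {
    g <- function(nm) {
      key <- paste0("flab", level, prefix, "_", nm)
      if (is.null(w[[key]])) stop("missing weight ", key)
      w[[key]]
    }
    lw <- g("loc_w")                       # (1, 2, 7, 7)
    loc_w <- array(0, c(7, 7, 2))
    for (ci in 1:2) loc_w[, , ci] <- lw[1, ci, , ]
    list(f1_w = matrix(g("f1_w"), r, 2), f1_b = as.numeric(g("f1_b")),
         f2_w = as.numeric(g("f2_w")), f2_b = as.numeric(g("f2_b")),
         loc_w = loc_w, loc_b = as.numeric(g("loc_b")))
  }
  branches <- if (share) list(one_branch("")) else
    lapply(seq_len(C), function(i) one_branch(paste0("_ch", i)))
  structure(list(
    channels = C, pool_kernel = model$config$pool_kernel, hidden_width = r,
    share_across_channels = share, branches = branches,
    proj_w = pick("proj_w"), proj_b = as.numeric(pick("proj_b"))
  ), class = "flab_params")
}
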