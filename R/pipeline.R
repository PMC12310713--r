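#' Full training configuration
#'
#' Records every hyperparameter of the training protocol: Adam with
#' learning rate 0.01, 200 epochs, batch size 8, 480 x 480 frames, joint
#' loss weights 0.8/0.2, a 7:3 train/test split, and three independent
#' restarts from which the model with the best test-set Dice is kept.
#' Defaults follow that protocol; scale `epochs`, `crop_size` and
#' `model$base_width` down for desk-size experiments.
#'
#' @param optimizer only `"adam"` is supported.
#' @param lr learning rate (> 0).
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param crop_size square working resolution, divisible by 16.
#' @param loss_weights a [loss_weights()] pair (Dice, CE).
#' @param split_ratio train fraction of the train/test split.
#' @param n_restarts independent seeded trainings; the best test-Dice
#'   model wins.
#' @param seed master seed (restart r uses `seed + 1000 * (r - 1)`).
#' @param model list of [fla_unet()] arguments (network architecture).
#' @param resize_policy `"resize"` (bilinear to `crop_size`) or
#'   `"pad_crop"` (reflection-pad up to a multiple of 16, crop predictions
#'   back).
#' @param eval_every evaluate the test set every this many epochs (0 =
#'   only at the end of each restart).
#' @param augment_flips random horizontal/vertical flips during training
#'   (off by default; the protocol states no augmentation).
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", lr = 0.01, epochs = 200L,
                         batch_size = 8L, crop_size = 480L,
                         loss_weights = fazseg::loss_weights(0.8, 0.2),
                         split_ratio = 0.7, n_restarts = 3L, seed = 1L,
                         model = list(), resize_policy = c("resize", "pad_crop"),
                         eval_every = 0L, augment_flips = FALSE) {
  optimizer <- match.arg(optimizer, "adam")
  resize_policy <- match.arg(resize_policy)
  if (lr <= 0) stop("lr must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (crop_size %% 16 != 0) stop("crop_size must be divisible by 16")
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must be in (0,1)")
  if (!inherits(loss_weights, "loss_weights"))
    loss_weights <- do.call(fazseg::loss_weights, as.list(loss_weights))
  model_defaults <- list(in_channels = 1L, num_classes = 2L, base_width = 64L,
                         use_flab = TRUE, pool_kernel = 3L, hidden_width = 2L,
                         share_across_channels = TRUE)
  model <- utils::modifyList(model_defaults, model)
  for (nm in c("in_channels", "num_classes", "base_width", "pool_kernel",
               "hidden_width"))
    model[[nm]] <- as.integer(model[[nm]])
  model$use_flab <- isTRUE(model$use_flab)
  model$share_across_channels <- isTRUE(model$share_across_channels)
  structure(list(
    optimizer = optimizer, lr = lr, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), crop_size = as.integer(crop_size),
    loss_weights = loss_weights, split_ratio = split_ratio,
    n_restarts = as.integer(n_restarts), seed = as.integer(seed),
    model = model, resize_policy = resize_policy,
    eval_every = as.integer(eval_every), augment_flips = isTRUE(augment_flips)
  ), class = "train_config")
}

#' Read / write a training configuration as JSON
#'
#' The on-disk representation mirrors the [train_config()] fields
#' one-for-one; the round trip is lossless.
#'
#' @param config a `train_config` object.
#' @param path JSON file path.
#' @return `write_train_config()`: `path`, invisibly;
#'   `read_train_config()`: a `train_config`.
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  x <- unclass(config)
  x$loss_weights <- list(w1 = config$loss_weights$w1,
                         w2 = config$loss_weights$w2)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$loss_weights <- loss_weights(x$loss_weights$w1, x$loss_weights$w2)
  x$model <- as.list(x$model)
  do.call(train_config, x)
}

#' @rdname write_train_config
#' @param config a `train_config` (or any serializable list).
#' @return `config_hash()`: 8-hex-digit CRC32 of the canonical JSON
#'   serialization.
#' @export
config_hash <- function(config) {
  x <- config
  if (inherits(x, "train_config")) {
    x <- unclass(x)
    x$loss_weights <- list(w1 = x$loss_weights$w1, w2 = x$loss_weights$w2)
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", as.integer(.crc32_bytes(charToRaw(as.character(js))) %% 2^31))
}

reflect_pad_to <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  ri <- c(seq_len(h), rev(seq_len(h)))[seq_len(H)]
  ci <- c(seq_len(w), rev(seq_len(w)))[seq_len(W)]
  m[ri, ci, drop = FALSE]
}

next_mult16 <- function(n) as.integer(ceiling(n / 16) * 16)

# Bring every pair to a network-compatible square resolution.
prep_pairs <- function(pairs, crop_size = NULL, resize_policy = "resize") {
  lapply(pairs, function(p) {
    h <- nrow(p$image); w <- ncol(p$image)
    if (identical(resize_policy, "pad_crop")) {
      H <- next_mult16(h); W <- next_mult16(w)
      p$orig_dim <- c(h, w)
      p$image <- reflect_pad_to(p$image, H, W)
      mm <- p$mask; storage.mode(mm) <- "integer"
      p$mask <- reflect_pad_to(mm, H, W)
    } else {
      target <- if (is.null(crop_size)) c(next_mult16(h), next_mult16(w))
                else c(crop_size, crop_size)
      if (h != target[1] || w != target[2]) {
        p$image <- .resize_bilinear(p$image, target[1], target[2])
        mm <- p$mask; storage.mode(mm) <- "integer"
        p$mask <- .resize_nearest(mm, target[1], target[2])
      }
    }
    p
  })
}

pairs_to_arrays <- function(pairs) {
  n <- length(pairs)
  H <- nrow(pairs[[1]]$image); W <- ncol(pairs[[1]]$image)
  x <- array(0, c(n, 1L, H, W))
  y <- array(0L, c(n, H, W))
  for (i in seq_len(n)) {
    x[i, 1, , ] <- pairs[[i]]$image
    y[i, , ] <- pairs[[i]]$mask
  }
  storage.mode(y) <- "integer"
  list(x = x, y = y)
}

resolve_dataset <- function(dataset) {
  if (is.character(dataset) && length(dataset) == 1)
    return(load_folder_dataset(file.path(dataset, "images"),
                               file.path(dataset, "masks")))
  dataset
}

#' Train a model under the configured protocol
#'
#' Splits the dataset, runs `n_restarts` independent seeded trainings, and
#' keeps the restart with the best macro test-set Dice - the "train three
#' times, keep the optimum on the test metrics" model-selection rule. Any
#' restart whose loss turns non-finite is aborted and recorded; if all
#' restarts fail, an error is raised.
#'
#' @param config a [train_config()].
#' @param dataset list of sample pairs, or a folder with `images/` and
#'   `masks/` subfolders.
#' @param out_dir optional run directory: best checkpoint
#'   (`checkpoint.rds`) and a JSON run record are written there.
#' @param verbose print per-epoch losses.
#' @return object of class `run_record`: per-restart epoch losses and test
#'   metrics, the selected restart, the best model (`$model`), the config
#'   echo, seed and config hash.
#' @export
train <- function(config, dataset, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  pairs <- resolve_dataset(dataset)
  if (length(pairs) == 0) stop("dataset is empty")
  pairs <- prep_pairs(pairs, config$crop_size, config$resize_policy)
  sp <- split_dataset(pairs, config$split_ratio, config$seed)
  tr <- pairs_to_arrays(sp$train)
  te <- pairs_to_arrays(sp$test)
  ntr <- dim(tr$x)[1]

  restarts <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    rseed <- config$seed + 1000L * (r - 1L)
    model <- do.call(fla_unet, c(config$model, list(seed = rseed)))
    set.seed(rseed)
    losses <- rep(NA_real_, config$epochs)
    ok <- TRUE
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      bl <- c()
      for (b0 in seq(1, ntr, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, ntr)]
        xb <- tr$x[idx, , , , drop = FALSE]
        yb <- tr$y[idx, , , drop = FALSE]
        if (config$augment_flips) {
          for (i in seq_along(idx)) {
            if (runif(1) < 0.5) {
              xb[i, 1, , ] <- xb[i, 1, nrow(xb[i, 1, , ]):1, ]
              yb[i, , ] <- yb[i, dim(yb)[2]:1, ]
            }
            if (runif(1) < 0.5) {
              xb[i, 1, , ] <- xb[i, 1, , ncol(xb[i, 1, , ]):1]
              yb[i, , ] <- yb[i, , dim(yb)[3]:1]
            }
          }
        }
        st <- train_step(model, xb, yb, lr = config$lr,
                         weights = config$loss_weights)
        bl <- c(bl, st$loss)
      }
      losses[ep] <- mean(bl)
      if (!is.finite(losses[ep])) {
        ok <- FALSE
        warning("restart ", r, ": non-finite loss at epoch ", ep,
                "; aborting this restart")
        break
      }
      if (verbose)
        message(sprintf("restart %d epoch %3d/%d  loss %.4f", r, ep,
                        config$epochs, losses[ep]))
    }
    rep_test <- if (ok) eval_arrays(model, te) else NULL
    restarts[[r]] <- list(seed = rseed, epoch_loss = losses, completed = ok,
                          test = if (ok) rep_test$macro else NULL,
                          model = if (ok) model else NULL)
  }
  dices <- vapply(restarts, function(z)
    if (z$completed) unname(z$test["dice"]) else -Inf, numeric(1))
  if (all(!is.finite(dices))) stop("all restarts failed with non-finite loss")
  best <- which.max(dices)

  record <- structure(list(
    restarts = lapply(restarts, function(z) z[c("seed", "epoch_loss",
                                                "completed", "test")]),
    best_restart = best,
    best_test = restarts[[best]]$test,
    model = restarts[[best]]$model,
    config = config,
    config_hash = config_hash(config),
    seed = config$seed,
    n_train = ntr, n_test = dim(te$x)[1],
    package_version = as.character(packageVersion("fazseg")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  ), class = "run_record")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(record$model, ckpt)
    record$checkpoint <- ckpt
    rr <- record
    rr$model <- NULL
    rr$config <- unclass(rr$config)
    rr$config$loss_weights <- list(w1 = config$loss_weights$w1,
                                   w2 = config$loss_weights$w2)
    jsonlite::write_json(rr, file.path(out_dir, "run_record.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  record
}

eval_arrays <- function(model, arr, batch_size = 4L) {
  n <- dim(arr$x)[1]
  preds <- vector("list", n)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    out <- fla_unet_forward(model, arr$x[idx, , , , drop = FALSE])
    for (j in seq_along(idx))
      preds[[idx[j]]] <- matrix(out$predicted_mask[j, , ],
                                dim(arr$y)[2], dim(arr$y)[3])
  }
  truths <- lapply(seq_len(n), function(i)
    matrix(arr$y[i, , ], dim(arr$y)[2], dim(arr$y)[3]))
  metric_report(preds, truths, aggregate = "macro")
}

#' Evaluate a model or checkpoint on a dataset
#'
#' Computes the metric report (macro and micro aggregation, per-image rows)
#' and optionally writes a per-image CSV and boundary-overlay PNGs.
#'
#' @param model a `fla_unet` model, a `run_record`, or a checkpoint path.
#' @param dataset pairs list or dataset folder.
#' @param report_csv optional per-image CSV path.
#' @param overlay_dir optional folder for prediction-boundary overlays.
#' @param crop_size working resolution (defaults: keep native size, padded
#'   or resized to a multiple of 16).
#' @param resize_policy `"resize"` or `"pad_crop"`.
#' @return a [metric_report()].
#' @export
evaluate <- function(model, dataset, report_csv = NULL, overlay_dir = NULL,
                     crop_size = NULL, resize_policy = "resize") {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "run_record")) model <- model$model
  stopifnot(inherits(model, "fla_unet"))
  pairs <- resolve_dataset(dataset)
  pairs <- prep_pairs(pairs, crop_size, resize_policy)
  arr <- pairs_to_arrays(pairs)
  rep <- eval_arrays(model, arr)
  if (!is.null(report_csv)) write_metric_report(rep, csv_path = report_csv)
  if (!is.null(overlay_dir)) {
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(pairs)) {
      out <- fla_unet_forward(model, arr$x[i, , , , drop = FALSE])
      pm <- matrix(out$predicted_mask[1, , ], dim(arr$y)[2], dim(arr$y)[3])
      edge <- boundary_pixels(pm)
      ov <- pairs[[i]]$image
      ov[edge] <- 1
      write_png_gray(ov, file.path(overlay_dir, sprintf("overlay_%03d.png", i)))
    }
  }
  rep
}

boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  up <- rbind(mask[1, , drop = FALSE], mask[-H, , drop = FALSE])
  dn <- rbind(mask[-1, , drop = FALSE], mask[H, , drop = FALSE])
  lf <- cbind(mask[, 1, drop = FALSE], mask[, -W, drop = FALSE])
  rt <- cbind(mask[, -1, drop = FALSE], mask[, W, drop = FALSE])
  mask == 1 & (up == 0 | dn == 0 | lf == 0 | rt == 0)
}

#' Component ablation: U-Net vs U-Net + attention vs full model
#'
#' Trains three variants on identical data, seeds and protocol: the plain
#' U-Net with cross-entropy loss only, the attention-equipped U-Net still
#' with cross-entropy only, and the full model with the joint
#' Dice + cross-entropy loss. Each variant is freshly initialized; nothing
#' is shared. Emits a three-row table of MIoU / ACC / Dice.
#'
#' @param config a [train_config()]; its `use_flab` and `loss_weights`
#'   fields are overridden per variant.
#' @param dataset pairs list or dataset folder.
#' @param out_csv optional CSV path for the comparison table.
#' @return data frame with columns `variant`, `miou`, `acc`, `dice`.
#' @export
ablate <- function(config, dataset, out_csv = NULL) {
  stopifnot(inherits(config, "train_config"))
  variants <- list(
    list(name = "U-Net", use_flab = FALSE, weights = loss_weights(0, 1)),
    list(name = "U-Net+FLABs", use_flab = TRUE, weights = loss_weights(0, 1)),
    list(name = "FLA-UNet", use_flab = TRUE, weights = loss_weights(0.8, 0.2))
  )
  rows <- lapply(variants, function(v) {
    cfg <- config
    cfg$model$use_flab <- v$use_flab
    cfg$loss_weights <- v$weights
    rec <- train(cfg, dataset)
    data.frame(variant = v$name,
               miou = unname(rec$best_test["miou"]),
               acc = unname(rec$best_test["acc"]),
               dice = unname(rec$best_test["dice"]))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  tab
}
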