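# Backbone assembly: encoder ladder, decoder fusion, softmax head,
# baseline equivalence, and checkpointing.

test_that("encoder ladder follows the doubling/halving schedule", {
  net <- fla_unet(base_width = 8, seed = 1)
  x <- array(rnorm(64 * 64), c(1, 1, 64, 64))
  feats <- encoder_forward(net, x)
  expect_length(feats, 5)
  for (s in 1:5) {
    d <- dim(feats[[s]])
    expect_identical(d[2], as.integer(8 * 2^(s - 1)))
    expect_identical(d[3], as.integer(64 / 2^(s - 1)))
    expect_identical(d[4], as.integer(64 / 2^(s - 1)))
    expect_true(all(feats[[s]] >= 0))        # post-ReLU
  }
})

test_that("full forward preserves spatial dims and the softmax simplex", {
  net <- tiny_model(seed = 2)
  for (side in c(64L, 160L)) {
    x <- array(rnorm(side * side), c(1, 1, side, side))
    out <- fla_unet_forward(net, x)
    expect_identical(dim(out$probabilities), c(1L, 2L, side, side))
    expect_identical(dim(out$predicted_mask), c(1L, side, side))
    sums <- out$probabilities[1, 1, , ] + out$probabilities[1, 2, , ]
    expect_true(all(abs(sums - 1) < 1e-5))
    expect_true(all(out$probabilities >= 0 & out$probabilities <= 1))
    expect_true(all(out$predicted_mask %in% c(0L, 1L)))
  }
})

test_that("decoder concatenation and attention halving have the right widths", {
  net <- fla_unet(base_width = 8, seed = 4)
  x <- array(rnorm(64 * 64), c(1, 1, 64, 64))
  out <- fla_unet_forward(net, x, stages = TRUE)
  dec <- out$stages$decoder
  for (l in 1:4) {
    wl <- as.integer(8 * 2^(4 - l))           # nominal decoder width
    expect_identical(dim(dec[[l]]$upsampled)[2], 2L * wl)
    expect_identical(dim(dec[[l]]$concat)[2], 3L * wl)
    expect_identical(dim(dec[[l]]$flab_out)[2], 3L * wl %/% 2L)
    expect_identical(dim(dec[[l]]$out)[2], wl)
  }
  expect_identical(dim(dec[[4]]$out)[3:4], c(64L, 64L))
})

test_that("equal logits give 0.5/0.5 probabilities", {
  net <- tiny_model(seed = 5)
  w <- model_weights(net)
  w$head_w[] <- 0
  w$head_b[] <- c(0.3, 0.3)
  set_model_weights(net, w)
  out <- fla_unet_forward(net, array(rnorm(32 * 32), c(1, 1, 32, 32)))
  expect_true(all(abs(out$probabilities - 0.5) < 1e-6))
})

test_that("conv blocks are nonnegative, shape-preserving, and match an
           eval-mode oracle", {
  net <- tiny_model(seed = 6)
  x <- array(rnorm(16 * 16), c(1, 1, 16, 16))
  out <- conv_block_apply(net, "enc", 1, 1, x)
  expect_identical(dim(out), c(1L, 4L, 16L, 16L))
  expect_true(all(out >= 0))
  w <- model_weights(net)
  for (o in 1:4) {
    wk <- aperm(array(w$enc1_block1_conv_w[o, , , ], c(1, 3, 3)), c(2, 3, 1))
    z <- oracle_conv2d(array(x[1, 1, , ], c(16, 16, 1)), wk,
                       w$enc1_block1_conv_b[o])
    z <- (z - w$enc1_block1_bn_rmean[o]) /
      sqrt(w$enc1_block1_bn_rvar[o] + 1e-5) *
      w$enc1_block1_bn_gamma[o] + w$enc1_block1_bn_beta[o]
    expect_lt(max(abs(out[1, o, , ] - pmax(z, 0))), 1e-5)
  }
})

test_that("decoder_forward consumes encoder features deepest-first", {
  net <- fla_unet(base_width = 4, seed = 7)
  x <- array(rnorm(32 * 32), c(1, 1, 32, 32))
  feats <- encoder_forward(net, x)
  dout <- decoder_forward(net, feats[[5]],
                          list(feats[[4]], feats[[3]], feats[[2]], feats[[1]]))
  expect_identical(dim(dout), c(1L, 4L, 32L, 32L))
  # mismatched skip resolution is refused with both shapes named
  expect_error(
    decoder_forward(net, feats[[5]],
                    list(feats[[3]], feats[[3]], feats[[2]], feats[[1]])),
    "upsampled map is")
})

test_that("input validation: channels and divisibility", {
  net <- tiny_model(seed = 8)
  expect_error(fla_unet_forward(net, array(0, c(1, 3, 32, 32))), "channels")
  expect_error(fla_unet_forward(net, array(0, c(1, 1, 30, 30))),
               "divisible by 16")
  expect_error(fla_unet(base_width = 7), "even")
})

test_that("baseline U-Net matches the analytic parameter census", {
  base <- 8L
  plain <- fla_unet(base_width = base, use_flab = FALSE, seed = 9)
  census <- param_census(plain)
  # independent count: conv blocks (3x3 kernels + bias + BN gamma/beta),
  # 1x1 head. Encoder: in->w, w->w, then doubling; decoder: 3m -> m -> m.
  count_block <- function(ci, co) (ci * 9 + 1 + 2) * co
  expected <- 0
  ci <- 1L
  for (s in 0:4) {
    co <- base * 2^s
    expected <- expected + count_block(ci, co) + count_block(co, co)
    ci <- co
  }
  for (l in 0:3) {
    m <- base * 2^(3 - l)
    expected <- expected + count_block(3 * m, m) + count_block(m, m)
  }
  expected <- expected + (base + 1) * 2          # 1x1 conv head, 2 classes
  expect_identical(census$total, as.numeric(expected))
  # attention variant adds exactly the FLAB parameters
  att <- fla_unet(base_width = base, seed = 9)
  flab_extra <- 0
  for (l in 0:3) {
    cc <- 3 * base * 2^(3 - l)
    branch <- (2 * 2 + 2) + (2 + 1) + (98 + 1)   # f1, f2, loc (r = 2)
    proj <- (cc * 9 + 1) * (cc / 2)
    flab_extra <- flab_extra + branch + proj
    # the first decoder block now sees cc/2 inputs instead of cc
    flab_extra <- flab_extra - count_block(cc, base * 2^(3 - l)) +
      count_block(cc / 2, base * 2^(3 - l))
  }
  expect_identical(param_census(att)$total, as.numeric(expected + flab_extra))
})

test_that("same seed reproduces the model bit-for-bit", {
  a <- tiny_model(seed = 123)
  b <- tiny_model(seed = 123)
  x <- array(rnorm(32 * 32), c(1, 1, 32, 32))
  expect_identical(fla_unet_forward(a, x)$probabilities,
                   fla_unet_forward(b, x)$probabilities)
  expect_identical(model_weights(a), model_weights(b))
})

test_that("checkpoints round-trip through disk", {
  net <- tiny_model(seed = 31)
  x <- array(rnorm(32 * 32), c(1, 1, 32, 32))
  y <- array(sample(0:1, 32 * 32, TRUE), c(1, 32, 32))
  train_step(net, x, y)                      # move away from initialization
  p1 <- fla_unet_forward(net, x)$probabilities
  ck <- file.path(tempdir(), "ck.rds")
  save_checkpoint(net, ck)
  expect_true(file.exists(ck))
  expect_true(file.exists(paste0(ck, ".json")))
  restored <- load_checkpoint(ck)
  expect_identical(fla_unet_forward(restored, x)$probabilities, p1)
  expect_identical(restored$config, net$config)
})

test_that("a tiny network can memorize a single image", {
  net <- tiny_model(base = 8, seed = 42)
  cfg <- synth_config(n_images = 1, size = 64, state = "diabetic", seed = 4)
  pair <- generate_dataset(cfg)[[1]]
  x <- array(pair$image, c(1, 1, 64, 64))
  y <- array(pair$mask, c(1, 64, 64)); storage.mode(y) <- "integer"
  loss <- Inf
  for (s in 1:200) {
    loss <- train_step(net, x, y, lr = 0.01)$loss
    if (loss < 0.05) break
  }
  expect_lt(loss, 0.05)
})
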