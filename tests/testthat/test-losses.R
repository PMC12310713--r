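# Cross-entropy, soft Dice, and their weighted combination.

test_that("ce_loss closed forms", {
  y <- seeded_mask(1, 4)
  # perfect prediction
  expect_lt(ce_loss(matrix(as.numeric(y), 4, 4), y), 1e-6)
  # uniform 0.5 -> log 2 regardless of the mask
  expect_equal(ce_loss(matrix(0.5, 4, 4), y), log(2), tolerance = 1e-6)
})

test_that("ce_loss matches the per-pixel scalar oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(runif(16), 4, 4)
    y <- seeded_mask(seed + 10, 4)
    expect_equal(ce_loss(p, y), oracle_ce(p, y), tolerance = 1e-12)
  }
})

test_that("dice_loss: agreement, disjoint masks, scalar oracle", {
  y <- matrix(0L, 6, 6); y[2:4, 2:4] <- 1L
  expect_lt(dice_loss(matrix(as.numeric(y), 6, 6), y), 1e-6)
  # disjoint hard masks of sizes a and b -> 1 - s / (a + b + s)
  p <- matrix(0, 6, 6); p[5:6, 5:6] <- 1
  a <- sum(p); b <- sum(y)
  expect_equal(dice_loss(p, y), 1 - 1 / (a + b + 1), tolerance = 1e-12)
  # both empty: smoothing keeps it ~0, never NaN
  z <- matrix(0, 4, 4)
  expect_equal(dice_loss(z, matrix(0L, 4, 4)), 0)
  for (seed in 1:10) {
    set.seed(seed)
    ps <- matrix(runif(64), 8, 8)
    ys <- seeded_mask(seed + 30, 8)
    expect_equal(dice_loss(ps, ys), oracle_dice_loss(ps, ys),
                 tolerance = 1e-9)
  }
})

test_that("joint_loss is the exact weighted combination", {
  for (seed in 1:20) {
    set.seed(seed)
    p <- matrix(runif(36), 6, 6)
    y <- seeded_mask(seed + 60, 6)
    expect_equal(joint_loss(p, y),
                 0.8 * dice_loss(p, y) + 0.2 * ce_loss(p, y),
                 tolerance = 1e-9)
  }
  p <- matrix(runif(16), 4, 4); y <- seeded_mask(99, 4)
  expect_equal(joint_loss(p, y, loss_weights(1, 0)), dice_loss(p, y))
  expect_equal(joint_loss(p, y, loss_weights(0, 1)), ce_loss(p, y))
  expect_error(loss_weights(-0.1, 0.5), "nonnegative")
  expect_error(loss_weights(0, 0), "positive")
})

test_that("losses are bounded and finite on the whole simplex", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(runif(25), 5, 5)
    p[1] <- 0; p[2] <- 1                    # boundary values
    y <- seeded_mask(seed, 5)
    dl <- dice_loss(p, y)
    cl <- ce_loss(p, y)
    expect_true(dl >= 0 && dl < 1)
    expect_true(is.finite(cl) && cl >= 0)
  }
})

test_that("moving probability toward the true class lowers both losses", {
  set.seed(5)
  p <- matrix(runif(36, 0.2, 0.8), 6, 6)
  y <- seeded_mask(7, 6)
  step <- 0.05
  p2 <- ifelse(y == 1, pmin(p + step, 1), pmax(p - step, 0))
  expect_lt(ce_loss(p2, y), ce_loss(p, y))
  expect_lt(dice_loss(p2, y), dice_loss(p, y))
  # single-pixel perturbation, both directions
  for (i in c(3, 17, 30)) {
    q <- p
    q[i] <- q[i] + 0.05 * (2 * y[i] - 1)
    expect_lte(ce_loss(q, y), ce_loss(p, y))
    expect_lte(dice_loss(q, y), dice_loss(p, y))
  }
})

test_that("analytic joint-loss gradient matches central differences", {
  set.seed(11)
  p <- matrix(runif(9, 0.15, 0.85), 3, 3)
  y <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), 3, 3)
  g <- joint_loss_grad(p, y)
  eps <- 1e-6
  for (i in 1:9) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd <- (joint_loss(pp, y) - joint_loss(pm, y)) / (2 * eps)
    expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i])), 1e-4)
  }
})

test_that("losses accept full softmax output and batches", {
  set.seed(3)
  probs <- array(0, c(2, 2, 4, 4))
  p1 <- array(runif(2 * 16), c(2, 4, 4))
  probs[, 2, , ] <- p1
  probs[, 1, , ] <- 1 - p1
  y <- array(sample(0:1, 32, TRUE), c(2, 4, 4))
  expect_equal(ce_loss(probs, y), ce_loss(p1, y), tolerance = 1e-12)
  expect_equal(dice_loss(probs, y),
               mean(c(oracle_dice_loss(p1[1, , ], y[1, , ]),
                      oracle_dice_loss(p1[2, , ], y[2, , ]))),
               tolerance = 1e-9)
  expect_error(ce_loss(matrix(0.5, 3, 3), matrix(0L, 4, 4)), "mismatch")
  expect_error(ce_loss(matrix(0.5, 3, 3), matrix(2L, 3, 3)), "labels")
})
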