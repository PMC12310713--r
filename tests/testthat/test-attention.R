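# Feature-location attention block: pooling pair, the two branches,
# gating, and the channel-halving projection (double-precision reference
# path plus cross-checks against the float32 network path).

test_that("pooled_pair handles constant and identity windows", {
  const <- matrix(3.7, 6, 5)
  for (k in c(1L, 3L, 5L)) {
    pp <- pooled_pair(const, k)
    expect_equal(pp$avg, const)
    expect_equal(pp$max, const)
  }
  x <- seeded_matrix(1, 6)
  pp1 <- pooled_pair(x, 1L)
  expect_equal(pp1$avg, x)
  expect_equal(pp1$max, x)
})

test_that("pooled_pair matches the brute-force windowed oracle", {
  x4 <- matrix(0:15, 4, 4, byrow = TRUE)
  ref <- oracle_pool(x4, 3)
  got <- pooled_pair(x4, 3)
  expect_equal(got$avg, ref$avg, tolerance = 1e-12)
  expect_equal(got$max, ref$max)
  for (seed in 1:20) {
    x <- seeded_matrix(seed, sample(3:8, 1), sample(3:8, 1))
    for (k in c(3L, 5L)) {
      ref <- oracle_pool(x, k)
      got <- pooled_pair(x, k)
      expect_equal(got$avg, ref$avg, tolerance = 1e-10)
      expect_equal(got$max, ref$max)
      expect_true(all(got$avg <= got$max + 1e-12))
    }
  }
})

test_that("pooled_pair rejects invalid kernels", {
  x <- seeded_matrix(2, 5)
  expect_error(pooled_pair(x, 2), "odd")
  expect_error(pooled_pair(x, 0), "odd")
  expect_error(pooled_pair(x, -3), "odd")
  expect_error(pooled_pair(matrix(c(1, NA), 1, 2), 1), "finite")
})

test_that("feature_weight: zero params, pass-through construction, oracle", {
  par <- flab_params(4, seed = 3)
  sl <- seeded_matrix(4, 5)
  # all-zero branch -> output identically zero
  z <- par
  z$branches[[1]]$f1_w[] <- 0; z$branches[[1]]$f2_w[] <- 0
  expect_true(all(feature_weight(sl, z) == 0))
  # identity-like: first hidden unit passes avg with weight 1
  id <- par
  id$branches[[1]]$f1_w <- matrix(c(1, 0, 0, 0), 2, 2)
  id$branches[[1]]$f1_b <- c(0, 0)
  id$branches[[1]]$f2_w <- c(1, 0)
  id$branches[[1]]$f2_b <- 0
  pos <- abs(seeded_matrix(5, 6))      # nonnegative slice -> ReLU inactive
  expect_equal(feature_weight(pos, id), pooled_pair(pos, 3)$avg)
  # random params vs per-pixel scalar oracle
  for (seed in 1:5) {
    p2 <- flab_params(4, seed = seed)
    x <- seeded_matrix(seed + 100, 5)
    expect_equal(feature_weight(x, p2),
                 oracle_feature_weight(x, p2$branches[[1]], p2$pool_kernel),
                 tolerance = 1e-9)
  }
})

test_that("location_weight: zero kernel, delta kernel, naive conv oracle", {
  par <- flab_params(4, seed = 7)
  sl <- seeded_matrix(8, 8)
  z <- par
  z$branches[[1]]$loc_w[] <- 0
  expect_true(all(location_weight(sl, z) == 0))
  # centered delta on the avg channel reproduces the avg map
  d <- par
  d$branches[[1]]$loc_w[] <- 0
  d$branches[[1]]$loc_w[4, 4, 1] <- 1
  d$branches[[1]]$loc_b <- 0
  expect_equal(location_weight(sl, d), pooled_pair(sl, 3)$avg)
  for (seed in 1:5) {
    p2 <- flab_params(4, seed = seed + 50)
    x <- seeded_matrix(seed + 200, 8)
    pp <- oracle_pool(x, p2$pool_kernel)
    stack <- array(c(pp$avg, pp$max), c(8, 8, 2))
    ref <- oracle_conv2d(stack, p2$branches[[1]]$loc_w, p2$branches[[1]]$loc_b)
    expect_equal(location_weight(x, p2), ref, tolerance = 1e-9)
  }
})

test_that("flab_forward degenerate cases: zero input and gate saturation", {
  par <- flab_params(4, seed = 9)
  x0 <- array(0, c(1, 4, 6, 6))
  res <- flab_forward(x0, par, return_gates = TRUE)
  expect_true(all(abs(res$gates - 0.5) < 1e-12))    # sigmoid(0) = 0.5
  # gated maps are zero, so the projection output is its bias broadcast
  par_b <- par
  par_b$proj_b <- c(0.3, -0.2)
  res_b <- flab_forward(x0, par_b)
  expect_equal(unique(as.vector(res_b[1, 1, , ])), 0.3)
  expect_equal(unique(as.vector(res_b[1, 2, , ])), -0.2)
  # large constant branch bias saturates the gate: gated -> F_i
  sat <- par
  sat$branches[[1]]$f2_b <- 60
  xs <- array(rnorm(1 * 4 * 6 * 6), c(1, 4, 6, 6))
  g <- flab_forward(xs, sat, return_gates = TRUE)
  expect_true(all(g$gates > 1 - 1e-9))
})

test_that("flab_forward equals the staged composition of its pieces", {
  set.seed(33)
  C <- 4; H <- 6; W <- 6
  par <- flab_params(C, seed = 12)
  x <- array(rnorm(C * H * W), c(1, C, H, W))
  got <- flab_forward(x, par)
  gated <- array(0, c(H, W, C))
  for (i in seq_len(C)) {
    sl <- matrix(x[1, i, , ], H, W)
    wf <- oracle_feature_weight(sl, par$branches[[1]], par$pool_kernel)
    pp <- oracle_pool(sl, par$pool_kernel)
    wl <- oracle_conv2d(array(c(pp$avg, pp$max), c(H, W, 2)),
                        par$branches[[1]]$loc_w, par$branches[[1]]$loc_b)
    gated[, , i] <- (1 / (1 + exp(-(wf + wl)))) * sl
  }
  for (o in seq_len(C / 2)) {
    w_o <- aperm(array(par$proj_w[o, , , ], c(C, 3, 3)), c(2, 3, 1))
    ref <- oracle_conv2d(gated, w_o, par$proj_b[o])
    expect_equal(matrix(got[1, o, , ], H, W), ref, tolerance = 1e-9)
  }
})

test_that("gates stay in (0,1) and gating never amplifies activations", {
  for (seed in 1:10) {
    set.seed(seed)
    C <- sample(c(2L, 4L, 6L), 1)
    H <- sample(7:10, 1)
    par <- flab_params(C, seed = seed)
    x <- array(rnorm(C * H * H, sd = 3), c(1, C, H, H))
    res <- flab_forward(x, par, return_gates = TRUE)
    expect_true(all(res$gates > 0 & res$gates < 1))
    for (i in seq_len(C)) {
      gi <- res$gates[1, i, , ] * x[1, i, , ]
      expect_true(all(abs(gi) <= abs(x[1, i, , ]) + 1e-12))
    }
  }
})

test_that("shape contract: (N, C, H, W) -> (N, C/2, H, W)", {
  for (case in list(c(1, 2, 7, 7), c(2, 4, 9, 12), c(1, 6, 8, 8))) {
    par <- flab_params(case[2], seed = 5)
    x <- array(rnorm(prod(case)), case)
    out <- flab_forward(x, par)
    expect_identical(dim(out), as.integer(c(case[1], case[2] / 2, case[3], case[4])))
  }
  expect_error(flab_forward(array(0, c(1, 3, 8, 8)), flab_params(4)), "even")
  expect_error(flab_params(5), "even")
})

test_that("branch independence under parameter surgery", {
  C <- 4; H <- 8
  par <- flab_params(C, seed = 21)
  x <- array(rnorm(C * H * H), c(1, C, H, H))
  # kill the location branch -> gates driven by the feature branch alone
  noloc <- par
  noloc$branches[[1]]$loc_w[] <- 0
  noloc$branches[[1]]$loc_b <- 0
  res <- flab_forward(x, noloc, return_gates = TRUE)
  for (i in seq_len(C)) {
    wf <- feature_weight(matrix(x[1, i, , ], H, H), noloc)
    expect_equal(matrix(res$gates[1, i, , ], H, H), 1 / (1 + exp(-wf)),
                 tolerance = 1e-12)
  }
  # kill the feature branch -> purely location-gated
  nofeat <- par
  nofeat$branches[[1]]$f2_w[] <- 0
  nofeat$branches[[1]]$f2_b <- 0
  res2 <- flab_forward(x, nofeat, return_gates = TRUE)
  for (i in seq_len(C)) {
    wl <- location_weight(matrix(x[1, i, , ], H, H), nofeat)
    expect_equal(matrix(res2$gates[1, i, , ], H, H), 1 / (1 + exp(-wl)),
                 tolerance = 1e-12)
  }
})

test_that("determinism: identical inputs and params give identical outputs", {
  par <- flab_params(4, seed = 2)
  x <- array(rnorm(4 * 8 * 8), c(1, 4, 8, 8))
  expect_identical(flab_forward(x, par), flab_forward(x, par))
  net1 <- tiny_model(seed = 77)
  net2 <- tiny_model(seed = 77)
  xa <- array(rnorm(12 * 64), c(1, 12, 8, 8))
  expect_identical(flab_apply(net1, 4, xa)$out, flab_apply(net2, 4, xa)$out)
})

test_that("float32 network FLAB matches the double reference", {
  net <- tiny_model(seed = 3)
  for (level in c(3, 4)) {
    C <- 3L * 4L * 2L^(4L - level)
    x <- array(rnorm(C * 16 * 16), c(1, C, 16, 16))
    cpp <- flab_apply(net, level, x)
    par <- flab_params_from_model(net, level)
    ref <- flab_forward(x, par, return_gates = TRUE)
    expect_lt(max(abs(cpp$out - ref$out)) / max(abs(ref$out)), 1e-4)
    expect_lt(max(abs(cpp$gates - ref$gates)), 1e-5)
  }
})

test_that("gradients reach both attention branches (finite differences)", {
  net <- tiny_model(seed = 11)
  set.seed(8)
  x <- array(runif(16 * 16), c(1, 1, 16, 16))
  y <- matrix(0L, 16, 16); y[6:10, 6:10] <- 1L; dim(y) <- c(1, 16, 16)
  lg <- loss_gradients(net, x, y)
  # finite and nonzero gradients in both branch parameter sets
  loc_g <- lg$grads$flab4_loc_w
  feat_g <- c(lg$grads$flab4_f2_w, lg$grads$flab4_f1_w)
  expect_true(all(is.finite(loc_g)) && any(loc_g != 0))
  expect_true(all(is.finite(feat_g)) && any(feat_g != 0))
  # spot finite-difference agreement on smooth parameters
  wts <- model_weights(net)
  fd_of <- function(nm, idx, eps = 5e-3) {
    w2 <- wts; w2[[nm]][idx] <- w2[[nm]][idx] + eps
    set_model_weights(net, w2)
    lp <- loss_gradients(net, x, y)$loss
    w2[[nm]][idx] <- w2[[nm]][idx] - 2 * eps
    set_model_weights(net, w2)
    lm <- loss_gradients(net, x, y)$loss
    set_model_weights(net, wts)
    (lp - lm) / (2 * eps)
  }
  # float32 activations + ReLU kinks limit finite-difference accuracy for
  # parameters deep in the network; the head (a smooth path) is tight.
  for (nm in c("flab4_loc_w", "flab4_f2_w")) {
    idx <- which(abs(lg$grads[[nm]]) == max(abs(lg$grads[[nm]])))[1]
    fd <- fd_of(nm, idx)
    expect_lt(abs(fd - lg$grads[[nm]][idx]) /
                max(abs(fd), abs(lg$grads[[nm]][idx])), 0.2)
  }
  idx <- which.max(abs(lg$grads$head_w))
  fd <- fd_of("head_w", idx)
  expect_lt(abs(fd - lg$grads$head_w[idx]) /
              max(abs(fd), abs(lg$grads$head_w[idx])), 1e-3)
})
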