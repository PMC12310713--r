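#' Sliding-window average and max pooling of one channel
#'
#' Computes the stride-1, same-size average- and max-pooled maps of a single
#' feature-map channel, the first stage of both branches of the
#' feature-location attention block. Window indices are clamped at the image
#' border (edge replication), so pooled statistics near the margin are not
#' biased toward zero.
#'
#' @param slice numeric matrix (height x width), one channel of a feature map.
#' @param pool_kernel odd positive integer, the pooling window side length.
#' @return list with elements `avg` and `max`, both matrices of the same
#'   dimension as `slice`.
#' @examples
#' p <- pooled_pair(matrix(1:16, 4, 4), 3)
#' all(p$avg <= p$max)
#' @export
pooled_pair <- function(slice, pool_kernel = 3L) {
  if (!is.matrix(slice) || !is.numeric(slice))
    stop("slice must be a numeric matrix")
  if (!all(is.finite(slice))) stop("slice must be finite")
  k <- pool_kernel
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1L ||
      as.integer(k) %% 2L == 0L)
    stop("configuration error: pool_kernel must be an odd positive integer, got ",
         deparse(pool_kernel))
  k <- as.integer(k)
  H <- nrow(slice); W <- ncol(slice)
  p <- (k - 1L) %/% 2L
  s <- matrix(0, H, W)
  m <- matrix(-Inf, H, W)
  for (dr in -p:p) {
    ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
    for (dc in -p:p) {
      ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
      sh <- slice[ri, ci, drop = FALSE]
      s <- s + sh
      m <- pmax(m, sh)
    }
  }
  list(avg = s / (k * k), max = m)
}

# dense same-size 2-D cross-correlation with zero padding; w is (k, k, Cin),
# x is (H, W, Cin); returns H x W matrix. Reference path only (double).
conv2d_same_ref <- function(x, w, bias = 0) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  k <- dim(w)[1]
  stopifnot(dim(w)[2] == k, dim(w)[3] == dim(x)[3])
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H < 1 || W < 1) stop("input must be at least 1 x 1")
  p <- (k - 1L) %/% 2L
  out <- matrix(bias, H, W)
  for (ci in seq_len(dim(x)[3])) {
    for (kr in seq_len(k)) {
      dr <- kr - p - 1L
      rs <- max(1L, 1L - dr):min(H, H - dr)   # output rows with valid source
      if (length(rs) == 0L) next
      for (kc in seq_len(k)) {
        dc <- kc - p - 1L
        cs <- max(1L, 1L - dc):min(W, W - dc)
        if (length(cs) == 0L) next
        out[rs, cs] <- out[rs, cs] +
          w[kr, kc, ci] * x[rs + dr, cs + dc, ci, drop = TRUE]
      }
    }
  }
  out
}

#' Create parameters for a feature-location attention block
#'
#' The block holds, per channel (or shared across channels), a feature-aware
#' branch (1x1 conv 2->r, ReLU, 1x1 conv r->1), a location-aware branch
#' (7x7 conv 2->1), and one 3x3 projection convolution that halves the
#' channel count of the whole block. Weights are Kaiming-initialized,
#' biases zero.
#'
#' @param channels even number of input channels C.
#' @param pool_kernel odd pooling window for both branches (default 3).
#' @param hidden_width hidden width r of the feature branch (default 2).
#' @param share_across_channels if `TRUE` (default) one branch parameter set
#'   is applied to every channel; otherwise each channel gets its own.
#' @param seed integer seed for reproducible initialization.
#' @return an object of class `flab_params`.
#' @export
flab_params <- function(channels, pool_kernel = 3L, hidden_width = 2L,
                        share_across_channels = TRUE, seed = 1L) {
  if (channels < 2 || channels %% 2 != 0)
    stop("configuration error: the feature-location attention block requires ",
         "an even channel count, got ", channels)
  if (pool_kernel < 1 || pool_kernel %% 2 == 0)
    stop("configuration error: pool_kernel must be an odd positive integer")
  if (hidden_width < 1) stop("hidden_width must be >= 1")
  set.seed(seed)
  r <- as.integer(hidden_width)
  new_branch <- function() {
    list(
      f1_w = matrix(rnorm(r * 2, sd = sqrt(2 / 2)), r, 2),
      f1_b = rep(0, r),
      f2_w = rnorm(r, sd = sqrt(2 / r)),
      f2_b = 0,
      loc_w = array(rnorm(7 * 7 * 2, sd = sqrt(2 / 98)), c(7, 7, 2)),
      loc_b = 0
    )
  }
  nb <- if (share_across_channels) 1L else as.integer(channels)
  co <- channels %/% 2L
  structure(list(
    channels = as.integer(channels),
    pool_kernel = as.integer(pool_kernel),
    hidden_width = r,
    share_across_channels = share_across_channels,
    branches = replicate(nb, new_branch(), simplify = FALSE),
    proj_w = array(rnorm(co * channels * 9, sd = sqrt(2 / (channels * 9))),
                   c(co, channels, 3, 3)),
    proj_b = rep(0, co)
  ), class = "flab_params")
}

branch_for <- function(params, channel) {
  if (params$share_across_channels) params$branches[[1L]]
  else params$branches[[channel]]
}

#' Feature-aware attention weight for one channel
#'
#' `W_F = conv1x1(ReLU(conv1x1(concat(F_avg, F_max))))`: the pooled pair is
#' stacked as a 2-channel map and passed through two pointwise convolutions
#' with a ReLU in between. Output has the same height and width as the input.
#'
#' @param slice numeric matrix, one channel of the concatenated feature map.
#' @param params a [flab_params()] object.
#' @param channel which channel's branch parameters to use (relevant only
#'   when `share_across_channels = FALSE`).
#' @return numeric matrix of attention logits (unbounded, pre-sigmoid).
#' @export
feature_weight <- function(slice, params, channel = 1L) {
  b <- branch_for(params, channel)
  pp <- pooled_pair(slice, params$pool_kernel)
  out <- matrix(b$f2_b, nrow(slice), ncol(slice))
  for (j in seq_len(params$hidden_width)) {
    h <- b$f1_w[j, 1] * pp$avg + b$f1_w[j, 2] * pp$max + b$f1_b[j]
    out <- out + b$f2_w[j] * pmax(h, 0)
  }
  out
}

#' Location-aware attention weight for one channel
#'
#' `W_L = conv7x7(concat(F_avg, F_max))`: a single zero-padded 7x7
#' convolution over the stacked pooled pair, capturing spatial context.
#'
#' @inheritParams feature_weight
#' @return numeric matrix of attention logits, same size as `slice`.
#' @export
location_weight <- function(slice, params, channel = 1L) {
  b <- branch_for(params, channel)
  pp <- pooled_pair(slice, params$pool_kernel)
  x <- array(c(pp$avg, pp$max), c(nrow(slice), ncol(slice), 2L))
  conv2d_same_ref(x, b$loc_w, b$loc_b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Apply a feature-location attention block (reference implementation)
#'
#' For each channel i the feature weight and location weight are added,
#' squashed by a sigmoid into a gate in (0, 1), and multiplied elementwise
#' with the channel. The gated stack is then projected by a 3x3 convolution
#' that halves the channel count. This is the double-precision reference
#' path; the network module applies the same computation in its float32
#' engine.
#'
#' @param features 4-D numeric array (batch, channels, height, width).
#' @param params a [flab_params()] object matching the channel count.
#' @param return_gates if `TRUE`, also return gates and gated maps.
#' @return 4-D array (batch, channels/2, height, width), or a list when
#'   `return_gates = TRUE`.
#' @export
flab_forward <- function(features, params, return_gates = FALSE) {
  d <- dim(features)
  if (length(d) != 4L) stop("features must be a 4-D (N, C, H, W) array")
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  if (C %% 2 != 0)
    stop("the feature-location attention block requires an even channel ",
         "count to halve it, got C = ", C)
  if (C != params$channels)
    stop("params were built for ", params$channels, " channels, input has ", C)
  co <- C %/% 2L
  out <- array(0, c(N, co, H, W))
  gates <- if (return_gates) array(0, c(N, C, H, W)) else NULL
  for (n in seq_len(N)) {
    gated <- array(0, c(H, W, C))
    for (i in seq_len(C)) {
      sl <- matrix(features[n, i, , ], H, W)
      g <- sigmoid(feature_weight(sl, params, i) + location_weight(sl, params, i))
      gated[, , i] <- g * sl
      if (return_gates) gates[n, i, , ] <- g
    }
    for (o in seq_len(co)) {
      w_o <- aperm(array(params$proj_w[o, , , ], c(C, 3, 3)), c(2, 3, 1))
      out[n, o, , ] <- conv2d_same_ref(gated, w_o, params$proj_b[o])
    }
  }
  if (return_gates) list(out = out, gates = gates) else out
}
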