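# Independent scalar-loop oracles. These deliberately share no code with
# the package implementations: explicit loops, no vectorized shortcuts.

# stride-1 windowed mean/max with edge replication
oracle_pool <- function(slice, k) {
  H <- nrow(slice); W <- ncol(slice); p <- (k - 1) / 2
  avg <- mx <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    vals <- c()
    for (dr in -p:p) for (dc in -p:p) {
      rr <- min(max(r + dr, 1), H)
      cc <- min(max(c + dc, 1), W)
      vals <- c(vals, slice[rr, cc])
    }
    avg[r, c] <- mean(vals)
    mx[r, c] <- max(vals)
  }
  list(avg = avg, max = mx)
}

# dense zero-padded same-size cross-correlation, quadruple loop
oracle_conv2d <- function(x, w, bias = 0) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  k <- dim(w)[1]; H <- dim(x)[1]; W <- dim(x)[2]; p <- (k - 1) / 2
  out <- matrix(bias, H, W)
  for (r in 1:H) for (c in 1:W)
    for (ci in seq_len(dim(x)[3]))
      for (kr in 1:k) for (kc in 1:k) {
        rr <- r + kr - p - 1L
        cc <- c + kc - p - 1L
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
          out[r, c] <- out[r, c] + w[kr, kc, ci] * x[rr, cc, ci]
      }
  out
}

# feature-aware branch evaluated as per-pixel scalar arithmetic
oracle_feature_weight <- function(slice, branch, k) {
  pp <- oracle_pool(slice, k)
  H <- nrow(slice); W <- ncol(slice)
  out <- matrix(0, H, W)
  r <- length(branch$f2_w)
  for (i in 1:H) for (j in 1:W) {
    acc <- branch$f2_b
    for (q in seq_len(r)) {
      h <- branch$f1_w[q, 1] * pp$avg[i, j] + branch$f1_w[q, 2] * pp$max[i, j] +
        branch$f1_b[q]
      acc <- acc + branch$f2_w[q] * max(h, 0)
    }
    out[i, j] <- acc
  }
  out
}

oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# per-class |intersection| / |union|, averaged
oracle_miou <- function(pred, truth) {
  ious <- sapply(c(0, 1), function(cls) {
    inter <- sum(pred == cls & truth == cls)
    uni <- sum(pred == cls | truth == cls)
    if (uni == 0) 1 else inter / uni
  })
  100 * mean(ious)
}

oracle_ce <- function(p, y, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    tot <- tot + -(y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  tot / length(p)
}

oracle_dice_loss <- function(p, y, smooth = 1) {
  num <- 0; sp <- 0; sy <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * y[i]
    sp <- sp + p[i]
    sy <- sy + y[i]
  }
  1 - (2 * num + smooth) / (sp + sy + smooth)
}

# 4-connected component containing the given pixel (flood fill)
component_of <- function(mask, start) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  if (mask[start[1], start[2]] != 1) return(seen)
  queue <- matrix(start, ncol = 2)
  seen[start[1], start[2]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r <- cur[1] + d[1]; c <- cur[2] + d[2]
      if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] == 1 &&
          !seen[r, c]) {
        seen[r, c] <- TRUE
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  seen
}

# small deterministic fixtures
seeded_matrix <- function(seed, H = 8, W = H) {
  set.seed(seed)
  matrix(rnorm(H * W), H, W)
}

seeded_mask <- function(seed, H = 8, W = H, p = 0.4) {
  set.seed(seed)
  matrix(as.integer(runif(H * W) < p), H, W)
}

tiny_model <- function(base = 4, use_flab = TRUE, seed = 1, ...) {
  fla_unet(base_width = base, use_flab = use_flab, seed = seed, ...)
}
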