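# Synthetic OCTA-like data generator, PNG I/O, dataset folders, splits.

test_that("a pure disc mask has the expected area", {
  cfg <- synth_config(n_images = 1, size = 160, state = "normal",
                      faz_radius_range = c(0.12, 0.12),
                      ellipticity_range = c(1, 1),
                      boundary_irregularity = 0, seed = 1)
  mask <- generate_faz_mask(cfg, seed = 1)
  r0 <- 0.12 * 160
  expect_lt(abs(sum(mask) - pi * r0^2) / (pi * r0^2), 0.05)
})

test_that("masks are single 4-connected components containing the center", {
  cfg <- synth_config(n_images = 1, size = 64, state = "diabetic", seed = 1)
  for (seed in 1:30) {
    mask <- generate_faz_mask(cfg, seed = seed)
    ctr <- c(32, 32)
    expect_identical(mask[ctr[1], ctr[2]], 1L)
    comp <- component_of(mask, ctr)
    expect_identical(sum(comp), sum(mask))     # nothing outside the component
  }
})

test_that("mask area respects the configured radius range", {
  cfg <- synth_config(n_images = 1, size = 96, state = "normal", seed = 1)
  rr <- cfg$faz_radius_range * 96
  irr <- cfg$boundary_irregularity
  for (seed in 1:20) {
    a <- sum(generate_faz_mask(cfg, seed = seed))
    expect_gt(a, pi * rr[1]^2 * (1 - irr)^2 * 0.7)
    expect_lt(a, pi * rr[2]^2 * (1 + irr)^2 * 1.3)
  }
})

test_that("disease presets enlarge the FAZ on average", {
  n <- 60
  area <- function(state) {
    cfg <- synth_config(n_images = 1, size = 96, state = state, seed = 1)
    mean(sapply(1:n, function(s) sum(generate_faz_mask(cfg, seed = s))))
  }
  a_norm <- area("normal"); a_myo <- area("myopic"); a_dia <- area("diabetic")
  expect_gt(a_myo, a_norm)
  expect_gt(a_dia, a_myo)
})

test_that("generator is deterministic and seeds differentiate", {
  cfg <- synth_config(n_images = 3, size = 64, state = "mixed", seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  hashes <- sapply(1:50, function(s)
    paste(generate_faz_mask(synth_config(size = 64, seed = s), seed = s),
          collapse = ""))
  expect_identical(length(unique(hashes)), 50L)
})

test_that("rendered images are darker inside the FAZ, in [0,1]", {
  for (state in c("normal", "myopic", "diabetic")) {
    cfg <- synth_config(n_images = 1, size = 64, state = state, seed = 2)
    for (seed in seq(1, 200, by = 3)) {
      mask <- generate_faz_mask(cfg, seed = seed)
      img <- render_octa_image(mask, cfg)
      expect_true(all(img >= 0 & img <= 1))
      expect_lt(mean(img[mask == 1]), mean(img[mask == 0]))
    }
  }
})

test_that("noise-free rendering gives two plateaus away from the boundary", {
  cfg <- synth_config(n_images = 1, size = 64, state = "normal",
                      vessel_density = 0, speckle_sigma = 0, seed = 3)
  mask <- generate_faz_mask(cfg, seed = 3)
  img <- render_octa_image(mask, cfg, seed = 3)
  # erode/dilate by the 2-pass blur radius to stay clear of the soft edge
  inner <- component_of(mask, c(32, 32))
  dist_ok <- function(margin) {
    d <- matrix(TRUE, 64, 64)
    idx <- which(mask == 1, arr.ind = TRUE)
    bnd <- idx[apply(idx, 1, function(rc) {
      any(mask[max(1, rc[1] - 1):min(64, rc[1] + 1),
               max(1, rc[2] - 1):min(64, rc[2] + 1)] == 0)
    }), , drop = FALSE]
    dd <- matrix(Inf, 64, 64)
    for (b in seq_len(nrow(bnd)))
      dd <- pmin(dd, outer((1:64 - bnd[b, 1])^2, rep(1, 64)) +
                   outer(rep(1, 64), (1:64 - bnd[b, 2])^2))
    sqrt(dd) > margin
  }
  far <- dist_ok(4)
  expect_identical(length(unique(img[mask == 1 & far])), 1L)
  expect_identical(length(unique(img[mask == 0 & far])), 1L)
})

test_that("PNG images round-trip through disk", {
  img <- matrix(runif(40 * 30), 40, 30)
  f <- file.path(tempdir(), "t.png")
  write_png_gray(img, f)
  back <- read_png_gray(f)
  expect_identical(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)   # 8-bit quantization only
  q <- round(img * 255) / 255
  expect_equal(back, q, tolerance = 1e-12)
  expect_error(read_png_gray(file.path(tempdir(), "absent.png")), "not found")
  bad <- file.path(tempdir(), "bad.png")
  writeLines("not a png", bad)
  expect_error(read_png_gray(bad), "not a PNG")
})

test_that("dataset folders round-trip and masks binarize at 127", {
  cfg <- synth_config(n_images = 3, size = 48, state = "mixed", seed = 6)
  pairs <- generate_dataset(cfg)
  d <- file.path(tempdir(), "dsx")
  unlink(d, recursive = TRUE)
  write_dataset(pairs, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- load_folder_dataset(file.path(d, "images"), file.path(d, "masks"))
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, pairs[[i]]$mask)
    expect_lt(max(abs(back[[i]]$image - pairs[[i]]$image)), 1 / 255)
    expect_true(all(back[[i]]$mask %in% c(0L, 1L)))
  }
  # unmatched file names and empty folders are explicit errors
  file.remove(file.path(d, "masks", "sample_002.png"))
  expect_error(load_folder_dataset(file.path(d, "images"),
                                   file.path(d, "masks")), "do not match")
  empty <- file.path(tempdir(), "emptydir")
  dir.create(empty, showWarnings = FALSE)
  expect_error(load_folder_dataset(empty, empty), "no samples")
})

test_that("split_dataset gives a seeded, disjoint, exhaustive 7:3 split", {
  pairs <- lapply(1:10, function(i) list(id = i))
  sp <- split_dataset(pairs, 0.7, seed = 5)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  ids <- c(sapply(sp$train, `[[`, "id"), sapply(sp$test, `[[`, "id"))
  expect_setequal(ids, 1:10)
  sp2 <- split_dataset(pairs, 0.7, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(pairs, 0.7, seed = 6)
  expect_false(identical(sapply(sp$train, `[[`, "id"),
                         sapply(sp3$train, `[[`, "id")))
  expect_error(split_dataset(pairs[1], 0.7), "at least 2")
  expect_error(split_dataset(pairs, 1.2), "in \\(0, 1\\)")
})

test_that("synth_config validates its ranges", {
  expect_error(synth_config(size = 16), ">= 32")
  expect_error(synth_config(faz_radius_range = c(0.4, 0.2)), "faz_radius")
  expect_error(synth_config(faz_radius_range = c(0.1, 0.6)), "faz_radius")
  expect_error(synth_config(vessel_density = 1.5), "vessel_density")
  expect_error(synth_config(speckle_sigma = -1), "speckle")
})
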