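#' Configuration of the synthetic OCTA generator
#'
#' The generator emulates the statistical structure of en-face OCTA frames:
#' a dark, roughly elliptical avascular region at the image center (the
#' FAZ), bright branching capillary texture elsewhere, and multiplicative
#' speckle. State presets encode the qualitative clinical ordering of FAZ
#' geometry - diseased eyes (diabetic, myopic) have larger and more
#' irregular FAZ contours than normal eyes - without claiming realism of
#' any specific dataset.
#'
#' @param n_images number of image/mask pairs.
#' @param size square frame side in pixels (default 160, divisible by 16).
#' @param state `"normal"`, `"diabetic"`, `"myopic"`, or `"mixed"` (cycle
#'   through all three).
#' @param faz_radius_range (min, max) mean FAZ radius as a fraction of
#'   `size`; preset by `state` when `NULL`.
#' @param ellipticity_range (min, max) axis ratio of the base ellipse.
#' @param boundary_irregularity amplitude of the smooth periodic radial
#'   perturbation (0 = perfect ellipse); preset by `state` when `NULL`.
#' @param vessel_density fraction of extrafoveal pixels covered by bright
#'   vessel texture, in `[0, 1]`.
#' @param speckle_sigma log-scale standard deviation of multiplicative
#'   speckle (0 = none).
#' @param seed integer seed making the whole dataset reproducible.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_images = 32L, size = 160L, state = "normal",
                         faz_radius_range = NULL, ellipticity_range = c(0.75, 1),
                         boundary_irregularity = NULL, vessel_density = 0.45,
                         speckle_sigma = 0.15, seed = 1L) {
  state <- match.arg(state, c("normal", "diabetic", "myopic", "mixed"))
  presets <- list(
    normal   = list(radius = c(0.10, 0.14), irregularity = 0.05),
    myopic   = list(radius = c(0.12, 0.17), irregularity = 0.15),
    diabetic = list(radius = c(0.15, 0.22), irregularity = 0.25)
  )
  if (is.null(faz_radius_range) && state != "mixed")
    faz_radius_range <- presets[[state]]$radius
  if (is.null(boundary_irregularity) && state != "mixed")
    boundary_irregularity <- presets[[state]]$irregularity
  if (size < 32) stop("size must be >= 32")
  if (!is.null(faz_radius_range)) {
    if (faz_radius_range[1] <= 0 || faz_radius_range[1] > faz_radius_range[2] ||
        faz_radius_range[2] >= 0.5)
      stop("need 0 < faz_radius_min <= faz_radius_max < 0.5")
  }
  if (vessel_density < 0 || vessel_density > 1)
    stop("vessel_density must be in [0, 1]")
  if (speckle_sigma < 0) stop("speckle_sigma must be >= 0")
  structure(list(
    n_images = as.integer(n_images), size = as.integer(size), state = state,
    faz_radius_range = faz_radius_range,
    ellipticity_range = ellipticity_range,
    boundary_irregularity = boundary_irregularity,
    vessel_density = vessel_density, speckle_sigma = speckle_sigma,
    seed = as.integer(seed), presets = presets
  ), class = "synth_config")
}

resolve_state <- function(config, state) {
  cfg <- config
  cfg$state <- state
  if (is.null(config$faz_radius_range))
    cfg$faz_radius_range <- config$presets[[state]]$radius
  if (is.null(config$boundary_irregularity))
    cfg$boundary_irregularity <- config$presets[[state]]$irregularity
  cfg
}

#' Generate one star-convex FAZ ground-truth mask
#'
#' The mask is the region `d(theta) <= r(theta)` around the image center,
#' where `r(theta)` is an ellipse radius modulated by a smooth periodic
#' perturbation `1 + a * s(theta)` built from random low-order harmonics
#' (orders 2-6), `a` = `boundary_irregularity`. Star-convexity guarantees a
#' single 4-connected component containing the center pixel.
#'
#' @param config a [synth_config()] object (state must not be `"mixed"`).
#' @param seed optional integer; when given, makes this call self-contained
#'   and reproducible. When `NULL` the current RNG stream is used.
#' @return integer matrix (size x size) with values 0/1.
#' @export
generate_faz_mask <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$state == "mixed")
    stop("resolve the state before generating a single mask")
  cfg <- resolve_state(config, config$state)
  rr <- cfg$faz_radius_range
  if (rr[1] > rr[2]) stop("degenerate radius range")
  size <- cfg$size
  r0 <- runif(1, rr[1], rr[2]) * size
  q <- runif(1, cfg$ellipticity_range[1], cfg$ellipticity_range[2])
  phi <- runif(1, 0, 2 * pi)
  a_ax <- r0 / sqrt(q)            # semi-axes preserving pi * r0^2 area
  b_ax <- r0 * sqrt(q)
  orders <- 2:6
  amp <- rnorm(length(orders))
  pha <- runif(length(orders), 0, 2 * pi)
  ctr <- (size + 1) / 2
  dx <- matrix(rep(seq_len(size) - ctr, each = size), size, size)   # columns
  dy <- matrix(rep(seq_len(size) - ctr, times = size), size, size)  # rows
  th <- atan2(dy, dx)
  d <- sqrt(dx^2 + dy^2)
  # ellipse radius at angle, rotated by phi
  tr <- th - phi
  re <- a_ax * b_ax / sqrt((b_ax * cos(tr))^2 + (a_ax * sin(tr))^2)
  s <- matrix(0, size, size)
  for (j in seq_along(orders))
    s <- s + amp[j] * cos(orders[j] * th + pha[j])
  mx <- max(abs(s))
  if (mx > 0) s <- s / mx
  perturb <- pmax(1 + cfg$boundary_irregularity * s, 0.2)
  mask <- matrix(as.integer(d <= re * perturb), size, size)
  mask
}

#' Render an OCTA-like grayscale image for a given FAZ mask
#'
#' Background texture is band-pass-filtered white noise thresholded at the
#' configured vessel density (bright capillaries on a dimmer perifoveal
#' floor); the FAZ interior is pulled to a dark floor through a softly
#' blurred mask edge; multiplicative log-normal speckle is applied last and
#' the result clipped to `[0, 1]`.
#'
#' @param mask binary FAZ mask matrix.
#' @param config a [synth_config()] object.
#' @param seed optional integer seed (see [generate_faz_mask()]).
#' @return numeric matrix in `[0, 1]` of the same size as `mask`.
#' @export
render_octa_image <- function(mask, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  size <- nrow(mask)
  bg_floor <- 0.35; vessel_level <- 0.85; faz_floor <- 0.08
  img <- matrix(bg_floor, size, size)
  if (config$vessel_density > 0) {
    z <- matrix(rnorm(size * size), size, size)
    f1 <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
    fr <- sqrt(outer(f1^2, f1^2, "+"))
    f0 <- 1 / 10                          # vessel wavelength ~10 px
    bp <- exp(-((fr - f0)^2) / (2 * (f0 / 2)^2))
    tex <- Re(stats::fft(stats::fft(z) * bp, inverse = TRUE)) / (size * size)
    thr <- quantile(tex, 1 - config$vessel_density)
    img[tex > thr] <- vessel_level
  }
  # soft FAZ boundary: small box blur of the mask as a blending weight
  alpha <- mask
  for (it in 1:2) {
    pad <- rbind(alpha[1, ], alpha, alpha[size, ])
    pad <- cbind(pad[, 1], pad, pad[, size])
    alpha <- (pad[1:size, 1:size] + pad[1:size, 2:(size + 1)] +
              pad[1:size, 3:(size + 2)] + pad[2:(size + 1), 1:size] +
              pad[2:(size + 1), 2:(size + 1)] + pad[2:(size + 1), 3:(size + 2)] +
              pad[3:(size + 2), 1:size] + pad[3:(size + 2), 2:(size + 1)] +
              pad[3:(size + 2), 3:(size + 2)]) / 9
  }
  img <- img * (1 - alpha) + faz_floor * alpha
  if (config$speckle_sigma > 0) {
    s <- config$speckle_sigma
    img <- img * exp(s * matrix(rnorm(size * size), size, size) - s^2 / 2)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic dataset of image/mask pairs
#'
#' @param config a [synth_config()] object; `config$seed` pins the whole
#'   dataset.
#' @return list of `sample_pair` objects, each with `image` (matrix in
#'   `[0, 1]`), `mask` (0/1 integer matrix), and `state`.
#' @export
generate_dataset <- function(config) {
  set.seed(config$seed)
  states <- if (config$state == "mixed")
    rep(c("normal", "diabetic", "myopic"), length.out = config$n_images)
  else rep(config$state, config$n_images)
  lapply(seq_len(config$n_images), function(i) {
    cfg <- resolve_state(config, states[i])
    mask <- generate_faz_mask(cfg)
    image <- render_octa_image(mask, cfg)
    structure(list(image = image, mask = mask, state = states[i]),
              class = "sample_pair")
  })
}

#' Read / write grayscale PNG images
#'
#' Minimal PNG support sufficient for OCTA frames and masks: 8-bit
#' non-interlaced files; RGB(A) inputs are collapsed to luminance on read.
#'
#' @param path file path.
#' @param image for writing: numeric matrix in `[0, 1]` (or integer matrix
#'   in 0..255).
#' @return `read_png_gray()`: numeric matrix in `[0, 1]`;
#'   `write_png_gray()`: `path`, invisibly.
#' @export
read_png_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .png_read_gray(path) / 255
}

#' @rdname read_png_gray
#' @export
write_png_gray <- function(image, path) {
  if (is.double(image) && max(image) <= 1 + 1e-9)
    image <- round(image * 255)
  storage.mode(image) <- "integer"
  .png_write_gray(path, image)
  invisible(path)
}

#' Write a dataset as image/mask PNG folders
#'
#' Produces `images/` and `masks/` subfolders with matching file names
#' (masks stored as 0/255) and a `manifest.csv` (filename, state).
#'
#' @param pairs list of `sample_pair` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  nm <- sprintf("sample_%03d.png", seq_along(pairs))
  for (i in seq_along(pairs)) {
    write_png_gray(pairs[[i]]$image, file.path(dir, "images", nm[i]))
    write_png_gray(pairs[[i]]$mask * 255L, file.path(dir, "masks", nm[i]))
  }
  states <- vapply(pairs, function(p)
    if (is.null(p$state)) NA_character_ else p$state, character(1))
  write.csv(data.frame(filename = nm, state = states),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load an image/mask folder dataset
#'
#' Pairs files by name between the two folders (sorted order), converts
#' images to `[0, 1]` grayscale and binarizes masks at 127/255.
#'
#' @param image_dir folder of image PNGs.
#' @param mask_dir folder of mask PNGs with matching file names.
#' @param strict_square reject non-square frames when `TRUE`.
#' @return list of `sample_pair` objects sorted by filename.
#' @export
load_folder_dataset <- function(image_dir, mask_dir, strict_square = FALSE) {
  imgs <- sort(list.files(image_dir, pattern = "\\.png$", ignore.case = TRUE))
  msks <- sort(list.files(mask_dir, pattern = "\\.png$", ignore.case = TRUE))
  if (length(imgs) == 0) stop("no samples found in ", image_dir)
  if (!identical(imgs, msks))
    stop("image and mask filenames do not match between ", image_dir, " and ",
         mask_dir)
  lapply(imgs, function(f) {
    image <- read_png_gray(file.path(image_dir, f))
    m <- .png_read_gray(file.path(mask_dir, f))
    if (!identical(dim(image), dim(m)))
      stop("image and mask dimensions differ for ", f)
    if (strict_square && nrow(image) != ncol(image))
      stop("non-square frame rejected (strict mode): ", f)
    mask <- matrix(as.integer(m > 127), nrow(m), ncol(m))
    structure(list(image = image, mask = mask, state = NA_character_,
                   filename = f), class = "sample_pair")
  })
}

#' Split pairs into training and testing sets
#'
#' Shuffles by a seeded permutation and takes `round(ratio * n)` pairs for
#' training; the split is disjoint and exhaustive.
#'
#' @param pairs list of sample pairs.
#' @param ratio training fraction in (0, 1); 0.7 gives the 7:3 protocol.
#' @param seed permutation seed.
#' @return list with `train` and `test`.
#' @export
split_dataset <- function(pairs, ratio = 0.7, seed = 1L) {
  n <- length(pairs)
  if (n < 2) stop("need at least 2 pairs to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  set.seed(seed)
  perm <- sample.int(n)
  ntr <- round(ratio * n)
  ntr <- max(1L, min(n - 1L, ntr))
  list(train = pairs[perm[seq_len(ntr)]],
       test = pairs[perm[(ntr + 1L):n]])
}
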