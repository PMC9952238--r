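#' Augmentation configuration
#'
#' Parameters for the deterministic, seedable train-time augmentation
#' stack: random flips, additive Gaussian noise, Gaussian blurring, and
#' affine and elastic deformations, applied sequentially in that fixed
#' order, each with its own probability. Geometric transforms act
#' identically on image (bilinear) and mask (nearest-neighbour, stays
#' binary); intensity transforms act on the image only.
#'
#' @param flip_prob probability of each of horizontal / vertical flip.
#' @param noise_sd additive Gaussian noise sd (image intensity units).
#' @param blur_sigma_range range (min, max) of the Gaussian blur sigma,
#'   in px.
#' @param rotation_deg max |rotation| of the random affine, degrees.
#' @param scale_range range of the random isotropic scale factor.
#' @param translate_px max |translation| along each axis, px.
#' @param elastic_spacing_px spacing of the coarse random-displacement
#'   control grid, px.
#' @param elastic_sd_px sd of the control-point displacements, px.
#' @param p_noise,p_blur,p_affine,p_elastic per-transform apply
#'   probabilities.
#' @param seed integer seed of the augmentation stream; combined with the
#'   draw index to give reproducible, decorrelated draws.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(flip_prob = 0.5,
                           noise_sd = 0.03,
                           blur_sigma_range = c(0.5, 1.5),
                           rotation_deg = 10,
                           scale_range = c(0.9, 1.1),
                           translate_px = 8,
                           elastic_spacing_px = 32,
                           elastic_sd_px = 2,
                           p_noise = 0.5, p_blur = 0.5,
                           p_affine = 0.5, p_elastic = 0.5,
                           seed = 1L) {
  probs <- c(flip_prob, p_noise, p_blur, p_affine, p_elastic)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must lie in [0, 1]")
  if (noise_sd < 0 || elastic_sd_px < 0 || translate_px < 0 || rotation_deg < 0)
    stop_config("spreads must be >= 0")
  structure(list(
    flip_prob = flip_prob, noise_sd = noise_sd,
    blur_sigma_range = blur_sigma_range, rotation_deg = rotation_deg,
    scale_range = scale_range, translate_px = translate_px,
    elastic_spacing_px = elastic_spacing_px, elastic_sd_px = elastic_sd_px,
    p_noise = p_noise, p_blur = p_blur, p_affine = p_affine,
    p_elastic = p_elastic, seed = as.integer(seed)
  ), class = "augment_config")
}

#' Standard input preprocessing
#'
#' Bilinear resize to 256 x 256 followed by intensity normalization
#' `(x - 0.456) / 0.224` (the fixed mean/sd used for network input
#' standardization).
#'
#' @param image numeric matrix with intensities in \[0, 1\].
#' @param size target side length (default 256).
#' @param mean,sd normalization constants (defaults 0.456 and 0.224).
#' @return preprocessed `size x size` matrix.
#' @export
preprocess <- function(image, size = 256, mean = 0.456, sd = 0.224) {
  check_matrix(image)
  out <- resize_bilinear(image, c(size, size))
  (out - mean) / sd
}

# separable Gaussian blur with reflected borders
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  radius <- max(1L, ceiling(3 * sigma))
  x <- (-radius):radius
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur_axis <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), x, "+")
    idx <- pmin(pmax(idx, 1L), n)  # replicate borders
    out <- matrix(0, n, ncol(m))
    for (k in seq_along(kern)) out <- out + kern[k] * m[idx[, k], , drop = FALSE]
    out
  }
  t(blur_axis(t(blur_axis(img))))
}

# inverse-mapped affine warp about the image centre
warp_affine <- function(img, rot_deg, scale, translate, interp, fill) {
  nr <- nrow(img); nc <- ncol(img)
  theta <- rot_deg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r_out <- matrix(seq_len(nr), nr, nc) - cr
  c_out <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # inverse transform: undo translation, rotation, scale
  r1 <- r_out - translate[1]; c1 <- c_out - translate[2]
  r_in <- (cos(theta) * r1 + sin(theta) * c1) / scale + cr
  c_in <- (-sin(theta) * r1 + cos(theta) * c1) / scale + cc
  v <- if (interp == "bilinear") bilinear_sample(img, r_in, c_in, fill)
       else nearest_sample(img, r_in, c_in, fill)
  matrix(v, nr, nc)
}

# elastic warp: coarse Gaussian random displacement grid, bilinearly
# upsampled to a dense field shared by image and mask
elastic_field <- function(shape, spacing_px, sd_px) {
  ng_r <- max(2L, ceiling(shape[1] / spacing_px) + 1L)
  ng_c <- max(2L, ceiling(shape[2] / spacing_px) + 1L)
  dr <- matrix(stats::rnorm(ng_r * ng_c, 0, sd_px), ng_r, ng_c)
  dc <- matrix(stats::rnorm(ng_r * ng_c, 0, sd_px), ng_r, ng_c)
  list(dr = resize_bilinear(dr, shape), dc = resize_bilinear(dc, shape))
}

warp_displacement <- function(img, field, interp, fill) {
  nr <- nrow(img); nc <- ncol(img)
  r_in <- matrix(seq_len(nr), nr, nc) + field$dr
  c_in <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + field$dc
  v <- if (interp == "bilinear") bilinear_sample(img, r_in, c_in, fill)
       else nearest_sample(img, r_in, c_in, fill)
  matrix(v, nr, nc)
}

#' Augment an image/mask pair deterministically
#'
#' Applies the augmentation stack in the fixed order flip, noise, blur,
#' affine, elastic. All randomness comes from a private stream determined
#' by `(config$seed, draw_index)`: the same pair of values reproduces the
#' output bit-exactly, different draw indices give decorrelated draws, and
#' the caller's RNG state is left untouched.
#'
#' @param image numeric matrix.
#' @param mask binary matrix on the same grid.
#' @param config an [augment_config()].
#' @param draw_index non-negative integer selecting the random draw.
#' @param fill out-of-bounds fill value for the image (default 0; use
#'   `-0.456 / 0.224` for images already preprocessed).
#' @return list with augmented `image` and binary `mask`.
#' @export
augment_pair <- function(image, mask, config = augment_config(),
                         draw_index = 0L, fill = 0) {
  stopifnot(inherits(config, "augment_config"))
  check_same_grid(image, mask)
  seed_i <- as.integer((as.numeric(config$seed) * 100003 +
                          as.numeric(draw_index) * 7919 + 1) %% 2147483647)
  with_seed(seed_i, {
    img <- image
    msk <- (mask > 0) * 1L
    # 1. flips
    if (stats::runif(1) < config$flip_prob) { img <- img[, rev(seq_len(ncol(img)))]; msk <- msk[, rev(seq_len(ncol(msk)))] }
    if (stats::runif(1) < config$flip_prob) { img <- img[rev(seq_len(nrow(img))), ]; msk <- msk[rev(seq_len(nrow(msk))), ] }
    # 2. additive noise (image only)
    if (stats::runif(1) < config$p_noise && config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd), nrow(img))
    # 3. blur (image only)
    if (stats::runif(1) < config$p_blur) {
      sigma <- stats::runif(1, config$blur_sigma_range[1], config$blur_sigma_range[2])
      img <- gaussian_blur(img, sigma)
    }
    # 4. affine (image + mask)
    if (stats::runif(1) < config$p_affine) {
      rot <- stats::runif(1, -config$rotation_deg, config$rotation_deg)
      scl <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      tr <- stats::runif(2, -config$translate_px, config$translate_px)
      img <- warp_affine(img, rot, scl, tr, "bilinear", fill)
      msk <- warp_affine(msk, rot, scl, tr, "nearest", 0L)
    }
    # 5. elastic (image + mask, shared displacement field)
    if (stats::runif(1) < config$p_elastic && config$elastic_sd_px > 0) {
      field <- elastic_field(dim(img), config$elastic_spacing_px, config$elastic_sd_px)
      img <- warp_displacement(img, field, "bilinear", fill)
      msk <- warp_displacement(msk, field, "nearest", 0L)
    }
    storage.mode(msk) <- "integer"
    list(image = img, mask = msk)
  })
}
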