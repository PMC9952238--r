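#' Synthetic short-axis cardiac phantom configuration
#'
#' Describes a simple contracting left-ventricle phantom on a short-axis
#' slice: a bright circular blood pool surrounded by a mid-intensity
#' myocardial annulus on a dark background, emulating bSSFP cine contrast
#' ordering (blood > myocardium > background). Radii contract smoothly
#' from end-diastole (frame 0) to end-systole (mid-series) and back.
#'
#' @param image_size pixels per side (square image). Default 256.
#' @param center (row, col) of the ventricle centre in pixels; defaults to
#'   the image centre.
#' @param r_endo_ed,r_epi_ed endocardial / epicardial radii at
#'   end-diastole, in pixels. Must satisfy 0 < r_endo_ed < r_epi_ed <
#'   image_size / 2.
#' @param contraction_fraction peak radial contraction in \[0, 1).
#' @param n_frames number of frames over the cardiac cycle (default 25,
#'   a typical time-resolved cine acquisition length).
#' @param intensity_blood,intensity_myo,intensity_bg mean intensities in
#'   \[0, 1\]; must be strictly decreasing in that order.
#' @param noise_sd additive zero-mean Gaussian noise standard deviation;
#'   images are clipped back to \[0, 1\].
#' @param edge_sigma softening width (px) of tissue edges in the image
#'   (masks are always hard-thresholded at pixel centres).
#' @param seed integer RNG seed for the noise stream.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256,
                           center = NULL,
                           r_endo_ed = 30,
                           r_epi_ed = 45,
                           contraction_fraction = 0.25,
                           n_frames = 25,
                           intensity_blood = 0.9,
                           intensity_myo = 0.5,
                           intensity_bg = 0.1,
                           noise_sd = 0.02,
                           edge_sigma = 0,
                           seed = 1L) {
  if (is.null(center)) center <- c(image_size, image_size) / 2
  cfg <- structure(list(
    image_size = as.integer(image_size), center = as.numeric(center),
    r_endo_ed = r_endo_ed, r_epi_ed = r_epi_ed,
    contraction_fraction = contraction_fraction,
    n_frames = as.integer(n_frames),
    intensity_blood = intensity_blood, intensity_myo = intensity_myo,
    intensity_bg = intensity_bg, noise_sd = noise_sd,
    edge_sigma = edge_sigma, seed = as.integer(seed)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (!(r_endo_ed > 0 && r_epi_ed > r_endo_ed && r_epi_ed < image_size / 2))
      stop_config("radii must satisfy 0 < r_endo_ed < r_epi_ed < image_size/2")
    if (!(intensity_blood > intensity_myo && intensity_myo > intensity_bg))
      stop_config("intensities must satisfy blood > myocardium > background")
    if (contraction_fraction < 0 || contraction_fraction >= 1)
      stop_config("contraction_fraction must lie in [0, 1)")
    if (n_frames < 1) stop_config("n_frames must be >= 1")
    if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  })
  cfg
}

# Smooth periodic contraction law: scale(t) = 1 - cf * sin^2(pi t / (T-1)),
# so frame 0 is end-diastole, the mid-series frame end-systole.
contraction_scale <- function(frame_index, n_frames, contraction_fraction) {
  if (n_frames <= 1) return(1)
  1 - contraction_fraction * sin(pi * frame_index / (n_frames - 1))^2
}

#' Generate one phantom frame
#'
#' @param config a [phantom_config()].
#' @param frame_index 0-based frame index in `[0, n_frames)`.
#' @return list with `image` (numeric matrix in \[0, 1\]) and `mask`
#'   (integer 0/1 matrix of the myocardial annulus), plus `r_endo`,
#'   `r_epi` (the contracted radii of this frame).
#' @export
generate_phantom_frame <- function(config, frame_index) {
  stopifnot(inherits(config, "phantom_config"))
  if (frame_index < 0 || frame_index >= config$n_frames)
    stop_config("frame_index %d out of range [0, %d)", frame_index, config$n_frames)
  n <- config$image_size
  sc <- contraction_scale(frame_index, config$n_frames, config$contraction_fraction)
  r_endo <- config$r_endo_ed * sc
  r_epi <- config$r_epi_ed * sc
  # radius of every pixel centre from the ventricle centre (1-based grid)
  rr <- matrix(seq_len(n), n, n) - 0.5 - config$center[1]
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - 0.5 - config$center[2]
  rad <- sqrt(rr^2 + cc^2)

  mask <- matrix(0L, n, n)
  mask[rad >= r_endo & rad <= r_epi] <- 1L

  img <- matrix(config$intensity_bg, n, n)
  if (config$edge_sigma > 0) {
    # soft edges: blend via logistic ramps on the radius
    s <- config$edge_sigma
    w_blood <- stats::plogis((r_endo - rad) / s)
    w_myo <- stats::plogis((rad - r_endo) / s) * stats::plogis((r_epi - rad) / s)
    img <- config$intensity_bg * (1 - w_blood - w_myo) +
      config$intensity_blood * w_blood + config$intensity_myo * w_myo
  } else {
    img[rad < r_endo] <- config$intensity_blood
    img[mask == 1L] <- config$intensity_myo
  }
  if (config$noise_sd > 0) {
    img <- with_seed(frame_seed(config$seed, frame_index), {
      img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
    })
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, mask = mask, r_endo = r_endo, r_epi = r_epi,
       frame = frame_index)
}

# deterministic per-frame seed, kept within 32-bit integer range
frame_seed <- function(seed, frame_index) {
  as.integer((as.numeric(seed) * 1009 + frame_index * 9973) %% 2147483647)
}

#' Generate a full phantom cine series
#'
#' @param config a [phantom_config()].
#' @return list of `n_frames` frames, each as from
#'   [generate_phantom_frame()].
#' @export
generate_phantom_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  lapply(seq_len(config$n_frames) - 1L,
         function(i) generate_phantom_frame(config, i))
}
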