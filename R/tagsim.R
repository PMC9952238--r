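#' Tagging preparation configuration
#'
#' Parameters of the simulated SPAMM grid-tagging preparation: a train of
#' RF sub-pulses with binomial relative weights (default 1-3-3-1) summing
#' to `total_flip_deg`, interleaved with gradient-induced free precession
#' whose per-pixel phase advances by one cycle per `spacing_px` pixels
#' along each of two orthogonal, rotated tagging axes. Optional T1-driven
#' fading relaxes the tag pattern toward uniform magnetization over the
#' cine frames; tag-line positions are static across frames.
#'
#' @param spacing_px tag-line period in pixels (default 5). Must be >= 2
#'   (at least two pixels per period).
#' @param total_flip_deg total tagging flip angle in degrees (default 70),
#'   in \[0, 180\].
#' @param weights positive relative weights of the RF sub-pulses;
#'   default `c(1, 3, 3, 1)`.
#' @param rotation_deg grid rotation in degrees (default 45, the typical
#'   clinical grid-tag orientation).
#' @param t1_ms longitudinal relaxation time used for fading (default 850,
#'   a nominal 1.5 T myocardial T1).
#' @param frame_interval_ms time between cine frames (default 40).
#' @param fade_enabled if `TRUE`, apply T1 fading as a function of frame
#'   index; default `FALSE` (static tag contrast, matching a transformation
#'   whose tag lines do not evolve with acquisition time).
#' @return an object of class `tag_config`.
#' @export
tag_config <- function(spacing_px = 5,
                       total_flip_deg = 70,
                       weights = c(1, 3, 3, 1),
                       rotation_deg = 45,
                       t1_ms = 850,
                       frame_interval_ms = 40,
                       fade_enabled = FALSE) {
  cfg <- structure(list(
    spacing_px = spacing_px, total_flip_deg = total_flip_deg,
    weights = as.numeric(weights), rotation_deg = rotation_deg,
    t1_ms = t1_ms, frame_interval_ms = frame_interval_ms,
    fade_enabled = isTRUE(fade_enabled)
  ), class = "tag_config")
  validate_tag_config(cfg)
}

validate_tag_config <- function(cfg) {
  if (cfg$spacing_px < 2)
    stop_config("spacing_px must be >= 2 (at least 2 px per tag period)")
  if (cfg$total_flip_deg < 0 || cfg$total_flip_deg > 180)
    stop_config("total_flip_deg must lie in [0, 180]")
  if (length(cfg$weights) == 0 || any(cfg$weights <= 0))
    stop_config("weights must be a non-empty vector of positive values")
  if (cfg$t1_ms < 0) stop_config("t1_ms must be >= 0")
  cfg
}

#' Square-root contrast conversion
#'
#' Grossly approximates the bSSFP (bright-blood cine) to gradient-echo
#' (tagged) contrast change by taking the element-wise square root of the
#' min-max normalized image. Monotone, fixes the range endpoints 0 and 1.
#'
#' @param image numeric matrix of intensities (any non-negative scale; the
#'   image is min-max normalized to \[0, 1\] first).
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
contrast_transform <- function(image) {
  check_matrix(image)
  x <- minmax01(image)
  if (any(x < 0)) stop_config("negative intensities after normalization")
  sqrt(x)
}

#' Simulate the SPAMM longitudinal-magnetization profile
#'
#' Bloch simulation of a SPAMM tagging preparation for a vector of
#' inter-pulse precession phases. Starting from equilibrium M = (0, 0, 1),
#' the magnetization is alternately (a) tipped about the transverse x-axis
#' by `weights[i] / sum(weights) * total_flip_deg` for each RF sub-pulse
#' and (b) precessed about z by the phase `psi` accumulated from the
#' tagging gradient between consecutive sub-pulses. After the train the
#' transverse magnetization is spoiled and the remaining Mz is returned.
#'
#' For a pixel at position u along the tagging axis, `psi = 2*pi*u /
#' spacing_px`, so Mz(psi) is the tag-line intensity profile: at psi = 0
#' the sub-rotations add coherently and Mz = cos(total_flip) (the dark
#' line); binomial weights drive Mz toward +1 between lines.
#'
#' @param phases numeric vector of precession phases psi in radians.
#' @param total_flip_deg total flip angle in degrees.
#' @param weights positive RF sub-pulse weights.
#' @return numeric vector of Mz values, one per phase, each in \[-1, 1\].
#' @export
simulate_spamm_profile <- function(phases, total_flip_deg, weights = c(1, 3, 3, 1)) {
  if (length(weights) == 0 || any(weights <= 0))
    stop_config("weights must be non-empty and positive")
  flips <- weights / sum(weights) * total_flip_deg * pi / 180
  n <- length(phases)
  mx <- numeric(n); my <- numeric(n); mz <- rep(1, n)
  cp <- cos(phases); sp <- sin(phases)
  for (i in seq_along(flips)) {
    if (i > 1) {
      # free precession about z by psi between sub-pulses
      mx_new <- cp * mx - sp * my
      my <- sp * mx + cp * my
      mx <- mx_new
    }
    # RF rotation about the x-axis by the sub-pulse flip angle
    ca <- cos(flips[i]); sa <- sin(flips[i])
    my_new <- ca * my - sa * mz
    mz <- sa * my + ca * mz
    my <- my_new
  }
  # spoiling: transverse components destroyed, Mz survives
  mz
}

#' Build the 2D grid tag modulation field
#'
#' Two sequential orthogonal 1D SPAMM preparations (with spoiling between)
#' multiply: each pixel's modulation is `Mz(psi_u) * Mz(psi_v)` where u, v
#' are the pixel coordinates rotated by `rotation_deg` and
#' `psi = 2*pi*coord / spacing_px`. Pixel (1,1) is a phase-zero point and
#' therefore sits on a dark line crossing. The field is periodic with
#' period `spacing_px` along both rotated axes.
#'
#' @param shape integer length-2 (rows, cols).
#' @param config a [tag_config()].
#' @return numeric matrix of Mz modulation values in \[-1, 1\].
#' @export
make_grid_pattern <- function(shape, config) {
  stopifnot(inherits(config, "tag_config"))
  if (any(shape < 1)) stop_config("shape must be positive")
  nr <- shape[1]; nc <- shape[2]
  theta <- config$rotation_deg * pi / 180
  r0 <- matrix(seq_len(nr) - 1, nr, nc)
  c0 <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  u <- c0 * cos(theta) + r0 * sin(theta)
  v <- -c0 * sin(theta) + r0 * cos(theta)
  mu <- simulate_spamm_profile(2 * pi * u / config$spacing_px,
                               config$total_flip_deg, config$weights)
  mv <- simulate_spamm_profile(2 * pi * v / config$spacing_px,
                               config$total_flip_deg, config$weights)
  matrix(mu * mv, nr, nc)
}

#' Apply T1 fading to a tag modulation field
#'
#' Longitudinal relaxation pulls every pixel's Mz back toward equilibrium:
#' `Mz(t) = 1 + (Mz(0) - 1) * exp(-t / T1)` with
#' `t = frame_index * frame_interval_ms`. Tag-line contrast (max - min of
#' the field) is non-increasing in the frame index. When `fade_enabled`
#' is `FALSE` the pattern is returned unchanged.
#'
#' @param pattern modulation field from [make_grid_pattern()].
#' @param frame_index 0-based frame index (>= 0).
#' @param config a [tag_config()].
#' @return faded modulation field.
#' @export
apply_fading <- function(pattern, frame_index, config) {
  stopifnot(inherits(config, "tag_config"))
  if (frame_index < 0) stop_config("frame_index must be >= 0")
  if (!config$fade_enabled) return(pattern)
  if (config$t1_ms < 0) stop_config("t1_ms must be >= 0")
  t <- frame_index * config$frame_interval_ms
  1 + (pattern - 1) * exp(-t / config$t1_ms)
}

#' Transform a cine image into a tagged-appearing image
#'
#' The full physics-driven transformation: square-root contrast conversion
#' followed by multiplication with the magnitude of the (optionally faded)
#' SPAMM grid modulation field, then min-max renormalization to \[0, 1\].
#' The segmentation mask is transferred untouched: the transformation
#' preserves anatomical structure, so the cine annotation remains valid
#' for the tagged-appearing image. Tag-line positions are static across
#' frames.
#'
#' @param image numeric matrix (cine intensities).
#' @param mask segmentation mask on the same grid (returned bit-identical).
#' @param frame_index 0-based temporal index, used only for fading.
#' @param config a [tag_config()].
#' @return list with `image` (tagged-appearing matrix in \[0, 1\]) and
#'   `mask` (identical to the input mask).
#' @export
transform_cine_to_tagged <- function(image, mask, frame_index = 0,
                                     config = tag_config()) {
  check_matrix(image)
  check_same_grid(image, mask)
  base <- contrast_transform(image)
  pattern <- make_grid_pattern(dim(image), config)
  pattern <- apply_fading(pattern, frame_index, config)
  out <- base * abs(pattern)
  list(image = minmax01(out), mask = mask)
}

#' Measure the tag-line period of a tagged image
#'
#' Samples an intensity profile along the grid-normal direction (the
#' rotated u-axis) by bilinear interpolation and returns the lag of the
#' first off-origin maximum of its autocorrelation — the inter-tag-line
#' period in pixels.
#'
#' @param image tagged image or modulation field (numeric matrix).
#' @param rotation_deg grid rotation used to form the tags (default 45).
#' @param max_lag largest candidate period in px (default 20).
#' @return measured period in pixels (integer-valued numeric).
#' @export
measure_tag_period <- function(image, rotation_deg = 45, max_lag = 20) {
  check_matrix(image)
  theta <- rotation_deg * pi / 180
  nr <- nrow(image); nc <- ncol(image)
  # walk from near one corner through the interior along the u-axis
  n_steps <- floor(0.6 * min(nr, nc))
  t <- seq(0, n_steps)
  r <- nr * 0.2 + t * sin(theta)
  c <- nc * 0.2 + t * cos(theta)
  prof <- bilinear_sample(image, r, c, fill = NA)
  prof <- prof[!is.na(prof)]
  prof <- prof - mean(prof)
  ac <- stats::acf(prof, lag.max = max_lag, plot = FALSE)$acf[-1]
  # first local maximum of the autocorrelation
  for (lag in 2:(length(ac) - 1)) {
    if (ac[lag] > ac[lag - 1] && ac[lag] >= ac[lag + 1]) return(as.numeric(lag))
  }
  as.numeric(which.max(ac))
}
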