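#' @keywords internal
"_PACKAGE"

# Shared internal helpers: argument checking, normalization, interpolation.

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_config("`%s` must be a numeric matrix", name)
  invisible(x)
}

check_same_grid <- function(a, b, what = "image and mask") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop_config("grid mismatch: %s must share the same (rows, cols)", what)
  invisible(NULL)
}

#' Min-max normalize a matrix to [0, 1]
#'
#' Constant matrices are clipped to \[0, 1\] and otherwise returned
#' unchanged, so that a uniform bright image stays bright instead of
#' collapsing to zero. Used before the square-root contrast conversion.
#'
#' @param x numeric matrix.
#' @return matrix with values in \[0, 1\].
#' @keywords internal
minmax01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop_config("non-finite intensities")
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else pmin(pmax(x, 0), 1)
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions
# (1-based). Out-of-bounds positions take `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r <- as.vector(r); c <- as.vector(c)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  inside <- r >= 1 & r <= nr & c >= 1 & c <= nc
  # clamp corner indices so subscripting is always legal
  ra <- pmin(pmax(r0, 1), nr); rb <- pmin(pmax(r0 + 1, 1), nr)
  ca <- pmin(pmax(c0, 1), nc); cb <- pmin(pmax(c0 + 1, 1), nc)
  v <- (1 - fr) * (1 - fc) * img[cbind(ra, ca)] +
       (1 - fr) * fc       * img[cbind(ra, cb)] +
       fr       * (1 - fc) * img[cbind(rb, ca)] +
       fr       * fc       * img[cbind(rb, cb)]
  v[!inside] <- fill
  v
}

# Nearest-neighbour sampling (used for masks so they stay binary).
nearest_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r <- as.vector(r); c <- as.vector(c)
  ri <- round(r); ci <- round(c)
  inside <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  ri <- pmin(pmax(ri, 1), nr); ci <- pmin(pmax(ci, 1), nc)
  v <- img[cbind(ri, ci)]
  v[!inside] <- fill
  v
}

#' Bilinear resize of a 2D image
#'
#' Pixel centres are aligned by the half-pixel convention, so resizing to
#' the input size is the identity.
#'
#' @param img numeric matrix.
#' @param out_shape integer length-2, target (rows, cols).
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, out_shape) {
  check_matrix(img)
  nr_out <- out_shape[1]; nc_out <- out_shape[2]
  if (identical(dim(img), as.integer(out_shape))) return(img)
  sr <- nrow(img) / nr_out
  sc <- ncol(img) / nc_out
  # clamp edge pixel centres into the source grid (replicate borders)
  r <- pmin(pmax((seq_len(nr_out) - 0.5) * sr + 0.5, 1), nrow(img))
  c <- pmin(pmax((seq_len(nc_out) - 0.5) * sc + 0.5, 1), ncol(img))
  grid <- expand.grid(r = r, c = c)
  matrix(bilinear_sample(img, grid$r, grid$c, fill = 0), nr_out, nc_out)
}

# Rolling polynomial hash of a string (mod 2^31 - 1), 8 hex digits.
# Used to stamp transformation parameters into dataset manifests.
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Evaluate an expression with a private RNG stream derived from `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
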