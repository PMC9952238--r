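# Exact 2D Euclidean distance transform (Felzenszwalb & Huttenlocher):
# two passes of the 1D squared-distance transform via the lower envelope
# of parabolas. Pure R; exact to floating point, O(n) per scan line.

dt1d_sq <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  for (q in 2:n) {
    if (!is.finite(f[q])) next
    repeat {
      p <- v[k]
      if (!is.finite(f[p])) { s <- -Inf } else {
        s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
      }
      if (s <= z[k] && k > 1L) { k <- k - 1L } else break
    }
    if (!is.finite(f[v[k]])) {
      v[k] <- q
      z[k + 1] <- Inf
    } else {
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1] <- Inf
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Squared Euclidean distance from every pixel to the nearest TRUE pixel
# of `sites`. Pixels with no site anywhere are Inf.
edt_sq <- function(sites) {
  nr <- nrow(sites); nc <- ncol(sites)
  f <- matrix(Inf, nr, nc)
  f[sites] <- 0
  if (!any(sites)) return(f)
  for (j in seq_len(nc)) if (any(is.finite(f[, j]))) f[, j] <- dt1d_sq(f[, j])
  for (i in seq_len(nr)) f[i, ] <- dt1d_sq(f[i, ])
  f
}

#' Signed normalized Euclidean distance map
#'
#' For each foreground pixel, the (positive) Euclidean distance to the
#' nearest background pixel; for each background pixel, minus the distance
#' to the nearest foreground pixel. Distances are measured between pixel
#' centres, so a foreground pixel adjacent to background has raw distance
#' 1. The map is divided by its maximum absolute value, giving values in
#' \[-1, 1\] with max |value| exactly 1.
#'
#' @param mask binary matrix (0/1 or logical) with at least one foreground
#'   and one background pixel.
#' @param normalize divide by the maximum absolute raw distance
#'   (default `TRUE`).
#' @return numeric matrix of signed distances.
#' @export
signed_distance_map <- function(mask, normalize = TRUE) {
  fg <- mask > 0
  if (all(fg) || !any(fg))
    stop_config("degenerate mask: needs both foreground and background pixels")
  d_to_bg <- sqrt(edt_sq(!fg))
  d_to_fg <- sqrt(edt_sq(fg))
  phi <- ifelse(fg, d_to_bg, -d_to_fg)
  if (normalize) phi <- phi / max(abs(phi))
  phi
}
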