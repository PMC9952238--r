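# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Signed normalized distance map by exhaustive all-pairs search.
sdm_bruteforce <- function(mask, normalize = TRUE) {
  fg <- which(mask > 0, arr.ind = TRUE)
  bg <- which(mask <= 0, arr.ind = TRUE)
  stopifnot(nrow(fg) > 0, nrow(bg) > 0)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      other <- if (mask[r, c] > 0) bg else fg
      d <- sqrt(min((other[, 1] - r)^2 + (other[, 2] - c)^2))
      out[r, c] <- if (mask[r, c] > 0) d else -d
    }
  }
  if (normalize) out <- out / max(abs(out))
  out
}

# Contour by per-pixel 4-neighbour inspection (border = background).
contour_bruteforce <- function(mask, spacing = c(1, 1)) {
  pts <- NULL
  nr <- nrow(mask); nc <- ncol(mask)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (mask[r, c] <= 0) next
      nb <- c(
        if (r > 1) mask[r - 1, c] else 0, if (r < nr) mask[r + 1, c] else 0,
        if (c > 1) mask[r, c - 1] else 0, if (c < nc) mask[r, c + 1] else 0
      )
      # out-of-range neighbours enter nb as 0, so the border case is covered
      if (any(nb <= 0)) pts <- rbind(pts, c(r * spacing[1], c * spacing[2]))
    }
  }
  pts
}

# Directed percentile distance by explicit loops + stats::quantile.
hd_bruteforce <- function(g, p, spacing = c(1, 1), q = 0.95) {
  X <- contour_bruteforce(g, spacing)
  Y <- contour_bruteforce(p, spacing)
  dir_q <- function(A, B) {
    nn <- numeric(nrow(A))
    for (i in seq_len(nrow(A)))
      nn[i] <- sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2))
    unname(quantile(nn, q, type = 7))
  }
  max(dir_q(X, Y), dir_q(Y, X))
}

dice_bruteforce <- function(g, p) {
  inter <- 0; ng <- 0; np <- 0
  for (i in seq_along(g)) {
    gi <- g[i] > 0; pi_ <- p[i] > 0
    inter <- inter + (gi && pi_); ng <- ng + gi; np <- np + pi_
  }
  if (ng + np == 0) 1 else 2 * inter / (ng + np)
}

# SPAMM Mz by explicit 3x3 rotation-matrix composition (column-vector
# convention matching rotations about x and z).
spamm_matrix_oracle <- function(psi, total_flip_deg, weights) {
  flips <- weights / sum(weights) * total_flip_deg * pi / 180
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Rz <- function(s) matrix(c(cos(s), sin(s), 0, -sin(s), cos(s), 0, 0, 0, 1), 3, 3)
  vapply(psi, function(s) {
    M <- c(0, 0, 1)
    for (i in seq_along(flips)) {
      if (i > 1) M <- Rz(s) %*% M
      M <- Rx(flips[i]) %*% M
    }
    M[3]
  }, numeric(1))
}

# Random connected-ish binary mask with both classes present.
random_mask <- function(nr, nc, p = 0.4) {
  repeat {
    m <- matrix(as.integer(runif(nr * nc) < p), nr, nc)
    if (any(m > 0) && any(m == 0)) return(m)
  }
}

# Small centred-square fixture used across loss tests.
square_fixture <- function(n = 8, lo = 3, hi = 6) {
  m <- matrix(0L, n, n)
  m[lo:hi, lo:hi] <- 1L
  m
}
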