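#' Dice similarity coefficient
#'
#' Overlap metric `2|G intersect P| / (|G| + |P|)` between two binary
#' masks. Returns 1 when both masks are empty (perfect agreement by
#' convention) and 0 when exactly one is empty.
#'
#' @param g,p binary matrices on the same grid.
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(g, p) {
  check_same_grid(g, p, "g and p")
  g <- g > 0; p <- p > 0
  denom <- sum(g) + sum(p)
  if (denom == 0) return(1)
  2 * sum(g & p) / denom
}

#' Extract the contour point set of a binary mask
#'
#' The contour is the set of foreground pixels having at least one
#' 4-neighbour outside the mask; the image border counts as background.
#' Coordinates are pixel centres scaled to millimetres by the pixel
#' spacing.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @param spacing_mm pixel spacing in mm/px: scalar (isotropic) or
#'   length-2 `(row_mm, col_mm)`.
#' @return two-column matrix of (row_mm, col_mm) contour coordinates.
#' @export
extract_contour <- function(mask, spacing_mm = 1) {
  fg <- mask > 0
  if (!any(fg)) stop_config("empty mask: no contour")
  nr <- nrow(fg); nc <- ncol(fg)
  # pad with background so border foreground pixels are boundary pixels
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- fg
  core <- padded[2:(nr + 1), 2:(nc + 1)]
  up <- padded[1:nr, 2:(nc + 1)]
  down <- padded[3:(nr + 2), 2:(nc + 1)]
  left <- padded[2:(nr + 1), 1:nc]
  right <- padded[2:(nr + 1), 3:(nc + 2)]
  boundary <- core & !(up & down & left & right)
  idx <- which(boundary, arr.ind = TRUE)
  if (length(spacing_mm) == 1) spacing_mm <- c(spacing_mm, spacing_mm)
  cbind(row_mm = idx[, 1] * spacing_mm[1], col_mm = idx[, 2] * spacing_mm[2])
}

# all pairwise Euclidean distances between two point sets (n x 2 matrices)
pairwise_dist <- function(X, Y) {
  dr <- outer(X[, 1], Y[, 1], "-")
  dc <- outer(X[, 2], Y[, 2], "-")
  sqrt(dr^2 + dc^2)
}

#' Directed percentile surface distance
#'
#' The q-quantile (linear-interpolation quantile) over points x in X of
#' the distance to the nearest point of Y. `q = 1` gives the directed
#' Hausdorff maximum.
#'
#' @param X,Y non-empty point sets: two-column (row, col) matrices in mm.
#' @param q quantile in (0, 1\].
#' @return distance in mm.
#' @export
directed_percentile_distance <- function(X, Y, q = 0.95) {
  if (is.null(nrow(X)) || nrow(X) == 0 || is.null(nrow(Y)) || nrow(Y) == 0)
    stop_config("empty point set")
  if (q <= 0 || q > 1) stop_config("q must lie in (0, 1]")
  nn <- apply(pairwise_dist(X, Y), 1, min)
  unname(stats::quantile(nn, probs = q, type = 7))
}

#' 95th-percentile symmetric Hausdorff distance
#'
#' `max(d_q(X, Y), d_q(Y, X))` on the contours of the two masks, in mm.
#' Robust to outlier boundary pixels compared with the full Hausdorff
#' maximum; symmetric in its mask arguments.
#'
#' @param g,p non-empty binary masks on the same grid.
#' @param spacing_mm pixel spacing in mm/px (scalar or `(row_mm, col_mm)`).
#' @param q percentile as a fraction (default 0.95).
#' @return distance in mm.
#' @export
hausdorff95 <- function(g, p, spacing_mm = 1, q = 0.95) {
  check_same_grid(g, p, "g and p")
  if (!any(g > 0) || !any(p > 0))
    stop_config("empty mask: Hausdorff distance undefined")
  X <- extract_contour(g, spacing_mm)
  Y <- extract_contour(p, spacing_mm)
  max(directed_percentile_distance(X, Y, q),
      directed_percentile_distance(Y, X, q))
}

#' Evaluate prediction/ground-truth mask pairs
#'
#' Computes per-image Dice coefficient and HD-95 for matched mask pairs
#' and aggregates mean and standard deviation. Pairs where either mask is
#' empty get `NA` HD-95 (flagged, excluded from the HD-95 aggregate with
#' a warning) rather than a fabricated 0.
#'
#' @param pred,gt named lists of binary matrices (matched by name), or
#'   directory paths containing PNG masks with matching file names.
#' @param spacing_mm pixel spacing in mm/px.
#' @return an object of class `metrics_report`: list with `per_image`
#'   (data.frame: id, dsc, hd95_mm, empty_pair) and `summary`
#'   (data.frame: metric, mean, sd, n).
#' @export
evaluate_masks <- function(pred, gt, spacing_mm = 1) {
  pred <- load_mask_source(pred)
  gt <- load_mask_source(gt)
  ids <- sort(names(gt))
  if (!setequal(ids, names(pred)))
    stop_config("unmatched ids between prediction and ground-truth sources")
  rows <- lapply(ids, function(id) {
    g <- gt[[id]]; p <- pred[[id]]
    check_same_grid(g, p, sprintf("pair '%s'", id))
    empty <- !any(g > 0) || !any(p > 0)
    data.frame(
      id = id,
      dsc = dice_coefficient(g, p),
      hd95_mm = if (empty) NA_real_ else hausdorff95(g, p, spacing_mm),
      empty_pair = empty,
      stringsAsFactors = FALSE
    )
  })
  per_image <- do.call(rbind, rows)
  if (any(per_image$empty_pair))
    warning(sprintf("%d pair(s) with an empty mask excluded from HD-95 aggregate",
                    sum(per_image$empty_pair)), call. = FALSE)
  hd <- per_image$hd95_mm[!is.na(per_image$hd95_mm)]
  summary <- data.frame(
    metric = c("dsc", "hd95_mm"),
    mean = c(mean(per_image$dsc), if (length(hd)) mean(hd) else NA_real_),
    sd = c(stats::sd(per_image$dsc), if (length(hd) > 1) stats::sd(hd) else NA_real_),
    n = c(nrow(per_image), length(hd)),
    stringsAsFactors = FALSE
  )
  structure(list(per_image = per_image, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report: %d image pair(s)\n", nrow(x$per_image)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# accept a named list of matrices or a directory of PNG masks
load_mask_source <- function(src) {
  if (is.character(src) && length(src) == 1 && dir.exists(src)) {
    files <- sort(list.files(src, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop_config("no PNG masks found in '%s'", src)
    masks <- lapply(files, function(f) (read_png_gray(f) > 0.5) * 1L)
    names(masks) <- tools::file_path_sans_ext(basename(files))
    return(masks)
  }
  if (!is.list(src) || is.null(names(src)) || any(names(src) == ""))
    stop_config("mask source must be a named list of matrices or a directory")
  src
}
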