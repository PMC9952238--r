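# Grayscale PNG helpers around the `png` package.

#' Read a PNG as a grayscale matrix
#'
#' Multi-channel PNGs are averaged over the colour channels; values are
#' in \[0, 1\].
#'
#' @param path PNG file path.
#' @return numeric matrix.
#' @export
read_png_gray <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE], c(1, 2), mean)
  x
}

#' Write a matrix as a grayscale PNG
#'
#' Values are clipped to \[0, 1\] and quantized to 8 bits (exact for
#' binary masks; images round-trip to within 1/255).
#'
#' @param x numeric matrix.
#' @param path output path.
#' @export
write_png_gray <- function(x, path) {
  storage.mode(x) <- "double"
  png::writePNG(pmin(pmax(x, 0), 1), path, dpi = NULL)
  invisible(path)
}
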