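# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No NIfTI package ships with this R stack, so the format is handled
# directly: the fixed 348-byte header plus a raw voxel block. Supported
# datatypes: uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64).
# Endianness is detected from sizeof_hdr; scl_slope/scl_inter are applied
# on read. This covers ACDC-style cine volumes and everything the package
# writes; it is not a general-purpose NIfTI implementation.

nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1, signed = FALSE),
  `4` = list(what = "integer", size = 2, signed = TRUE),
  `8` = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double", size = 4, signed = TRUE),
  `64` = list(what = "double", size = 8, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (array with singleton trailing dims dropped
#'   down to at least 2D), `dim` (full stated dims), `pixdim` (voxel
#'   sizes, mm / ms per stated dim).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.to_int32_swap(sizeof_hdr) != 348L)
      stop_config("'%s' is not a NIfTI-1 file (sizeof_hdr != 348)", path)
  }
  readBin(con, "raw", 36)                                   # unused header fields
  dim_field <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "raw", 14)                                   # intent fields
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian)            # bitpix
  readBin(con, "integer", 1, 2, endian = endian)            # slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop_config("unsupported NIfTI datatype %d in '%s'", datatype, path)
  nd <- dim_field[1]
  dims <- dim_field[2:(1 + max(nd, 1))]
  dims[dims <= 0] <- 1L
  n <- prod(dims)
  # skip the rest of the header up to the voxel block
  already <- 4 + 36 + 16 + 14 + 2 + 2 + 2 + 32 + 4 + 4 + 4
  readBin(con, "raw", max(0, round(vox_offset)) - already)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) != n) stop_config("truncated NIfTI voxel block in '%s'", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = dims)
  keep <- max(2L, max(which(dims > 1L), 2L))
  data <- array(data, dim = dims[seq_len(keep)])
  list(data = data, dim = dims, pixdim = pixdim[2:(1 + max(nd, 1))])
}

.to_int32_swap <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, 4, endian = "little")
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric array, 2 to 4 dimensions.
#' @param path output path (`.nii`, or `.nii.gz` for gzip compression).
#' @param pixdim voxel sizes per dimension, recycled/padded as needed.
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32, default), 64 (float64).
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1, 1), datatype = 16L) {
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop_config("unsupported NIfTI datatype %d", datatype)
  dims <- dim(data)
  if (is.null(dims)) stop_config("`data` must be an array")
  if (length(dims) > 7) stop_config("too many dimensions")
  dim_field <- rep(1L, 8)
  dim_field[1] <- length(dims)
  dim_field[1 + seq_along(dims)] <- as.integer(dims)
  pd <- rep(1, 8)
  pd[1 + seq_along(dims)] <- rep_len(pixdim, length(dims))

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, 4, endian = "little")                 # sizeof_hdr
  writeBin(raw(36), con)
  writeBin(as.integer(dim_field), con, 2, endian = "little")
  writeBin(raw(14), con)                                    # intent fields
  writeBin(as.integer(datatype), con, 2, endian = "little")
  writeBin(as.integer(dt$size * 8), con, 2, endian = "little")  # bitpix
  writeBin(0L, con, 2, endian = "little")                   # slice_start
  writeBin(pd, con, 4, endian = "little")
  writeBin(352, con, 4, endian = "little")                  # vox_offset
  writeBin(1, con, 4, endian = "little")                    # scl_slope
  writeBin(0, con, 4, endian = "little")                    # scl_inter
  n_written <- 4 + 36 + 16 + 14 + 2 + 2 + 2 + 32 + 4 + 4 + 4
  writeBin(raw(348 - n_written), con)                       # rest of header
  writeBin(raw(4), con)                                     # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, dt$size, endian = "little")
  }
  invisible(path)
}
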