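#' Normalised difference vegetation index
#'
#' Per-pixel `(NIR - VIS) / (NIR + VIS)`. Photosynthetically active
#' vegetation reflects strongly in the near infra-red while absorbing
#' visible red light, so vegetation scores close to +1 and soil near or
#' below 0. Pixels where `NIR + VIS = 0` (no signal) map to 0.
#'
#' @param nir near infra-red channel, non-negative matrix.
#' @param vis visible (red) channel, same shape, non-negative.
#' @return numeric matrix with values in `[-1, 1]`.
#' @seealso [quantize_ndvi()]
#' @export
compute_ndvi <- function(nir, vis) {
  if (!identical(dim(nir), dim(vis))) stop("channel shape mismatch")
  if (anyNA(nir) || anyNA(vis) || any(nir < 0) || any(vis < 0))
    stop("channels must be finite and non-negative")
  s <- nir + vis
  out <- (nir - vis) / s
  out[s == 0] <- 0
  out
}

#' Quantize an NDVI field to 8-bit grey levels
#'
#' Linear mapping of `[-1, 1]` onto the integer range `[0, 255]` with
#' round-half-up, so that the grey-level machinery (max-tree levels,
#' extinction values in the range 1-255) operates on 8-bit data:
#' `v -> round((v + 1) / 2 * 255)`.
#'
#' @param field numeric matrix with values in `[-1, 1]`.
#' @return integer matrix in `[0, 255]` with attribute
#'   `provenance = "computed"`.
#' @export
quantize_ndvi <- function(field) {
  if (anyNA(field) || any(field < -1) || any(field > 1))
    stop("NDVI values must lie in [-1, 1]")
  q <- matrix(as.integer(floor((field + 1) / 2 * 255 + 0.5)),
              nrow(field), ncol(field))
  attr(q, "provenance") <- "computed"
  q
}

#' Read an image file
#'
#' Reads 8- or 16-bit PNG or TIFF. A 4-channel file is returned as an
#' `rgbn_image` (list of `red`, `green`, `blue`, `nir` matrices on the
#' native integer scale); a single-channel file is treated as an
#' already-quantized NDVI image and must fit in `[0, 255]`. Any other
#' channel count is an error.
#'
#' @param path file path (.png, .tif or .tiff).
#' @return an `rgbn_image` list or an integer NDVI matrix with attributes
#'   `provenance = "loaded"` and `bits`.
#' @export
read_image <- function(path) {
  arr <- read_raster(path)
  bits <- attr(arr, "bits")
  if (length(dim(arr)) == 2L) {
    img <- round(arr * (2^bits - 1))
    if (max(img) > 255) stop("single-channel image does not fit in [0, 255]")
    img <- matrix(as.integer(img), nrow(img), ncol(img))
    attr(img, "provenance") <- "loaded"
    attr(img, "bits") <- bits
    return(img)
  }
  if (dim(arr)[3] != 4L)
    stop(sprintf("expected 1 or 4 channels, found %d", dim(arr)[3]))
  scale <- 2^bits - 1
  structure(
    list(red = arr[, , 1] * scale, green = arr[, , 2] * scale,
         blue = arr[, , 3] * scale, nir = arr[, , 4] * scale),
    bits = bits, class = "rgbn_image"
  )
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop("unsupported image format: ", ext)
  }
  attr(arr, "bits") <- bits
  arr
}

#' Write a single-channel image
#'
#' @param image integer matrix; must fit the requested bit depth.
#' @param path output file (.png, .tif or .tiff).
#' @param bits bit depth, 8 or 16.
#' @export
write_image <- function(image, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  scale <- 2^bits - 1
  if (any(image < 0) || any(image > scale)) stop("image out of range for bit depth")
  ext <- tolower(tools::file_ext(path))
  vals <- image / scale
  if (ext == "png") {
    png::writePNG(vals, path)  # 8-bit PNG
    if (bits != 8L) stop("PNG output is written as 8-bit; use TIFF for 16-bit")
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(vals, path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Masks are stored as single-channel 8-bit PNG with 0 = background and
#' 255 = foreground (vegetation).
#'
#' @param path PNG file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 2L) stop("mask must be single-channel")
  arr >= 0.5
}

#' Write a binary mask
#'
#' @param mask logical matrix.
#' @param path output PNG file.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write a region label image as 16-bit TIFF
#'
#' @param labels integer matrix of region labels (0 = background).
#' @param path output file (.tif/.tiff).
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L) stop("too many labels for 16-bit output")
  write_image(labels, path, bits = 16L)
}
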