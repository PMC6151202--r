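#' Construct a texture image
#'
#' A texture image is an `H x W x 3` array of RGB intensities in `[0, 255]`.
#' Grayscale matrices are promoted to RGB by channel replication. Images must
#' be at least 32 x 32 so that every feature extractor (4-level wavelet
#' decomposition, co-occurrence offsets up to 8 pixels) is well defined.
#'
#' @param pixels An `H x W x 3` numeric array, or an `H x W` matrix
#'   (replicated across channels), with values in `[0, 255]`.
#' @return An object of class `aes_texture`: the validated pixel array.
#' @examples
#' img <- texture_image(array(128, dim = c(32, 32, 3)))
#' dim(img)
#' @export
texture_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array or an H x W matrix", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) stop("empty image", call. = FALSE)
  if (d[1] < 32L || d[2] < 32L) {
    stop("texture images must be at least 32 x 32 pixels", call. = FALSE)
  }
  if (any(!is.finite(pixels))) stop("non-finite pixel values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(pixels, class = c("aes_texture", class(array())))
}

#' @export
print.aes_texture <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<aes_texture> %d x %d RGB, range [%g, %g]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Convert an RGB texture to a luminance image
#'
#' Uses the ITU-R BT.601 weights 0.299 R + 0.587 G + 0.114 B. The result is a
#' real-valued `H x W` matrix on the `[0, 255]` scale, the common input of the
#' co-occurrence, Tamura and wavelet extractors.
#'
#' @param image An [texture_image()] (or a bare H x W x 3 array in `[0, 255]`).
#' @return An `H x W` numeric matrix.
#' @export
as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Read a texture image from a PNG or TIFF file
#'
#' 8-bit RGB expected; grayscale is promoted by channel replication, alpha
#' channels are dropped. JPEG is not read natively; convert to PNG first.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`, `.tiff`).
#' @return An [texture_image()].
#' @export
read_texture <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      rlang::check_installed("png")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      rlang::check_installed("tiff")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(arr)[3] == 2L) arr <- array(rep(arr[, , 1], 3L), dim = c(dim(arr)[1:2], 3L))
  texture_image(round(arr * 255))
}

#' Write a texture image to a PNG file
#'
#' @param image An [texture_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_texture <- function(image, path) {
  rlang::check_installed("png")
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}
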