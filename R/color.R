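#' Mean HSV color features
#'
#' Converts the image from RGB to HSV and averages each channel over all
#' pixels. Hue, saturation and value are all reported on the `[0, 1]` scale;
#' the hue of achromatic pixels (R = G = B) is defined as 0, and the
#' saturation of black pixels as 0.
#'
#' @param image An [texture_image()] or bare H x W x 3 array in `[0, 255]`.
#' @return Named numeric vector `c(col_mean_h, col_mean_s, col_mean_v)`,
#'   each in `[0, 1]`.
#' @examples
#' img <- texture_image(array(rep(c(255, 0, 0), each = 32 * 32), c(32, 32, 3)))
#' color_means(img)  # saturated red: H = 0, S = 1, V = 1
#' @export
color_means <- function(image) {
  if (is.matrix(image) || length(dim(image)) != 3L || prod(dim(image)) == 0) {
    stop("`image` must be a non-empty H x W x 3 array", call. = FALSE)
  }
  rgb <- rbind(
    r = as.vector(image[, , 1]),
    g = as.vector(image[, , 2]),
    b = as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  # grDevices conventions: achromatic pixels get h = 0 (and s = 0); black has
  # v = 0. Guard against any NaN from a 0/0 just in case.
  hsv[!is.finite(hsv)] <- 0
  c(col_mean_h = mean(hsv["h", ]),
    col_mean_s = mean(hsv["s", ]),
    col_mean_v = mean(hsv["v", ]))
}
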