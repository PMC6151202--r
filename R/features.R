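#' The fixed 106-feature catalog
#'
#' One row per feature, in extraction order: 3 HSV color means, 64
#' co-occurrence statistics (distance 2/4/6/8 x orientation 0/45/90/135 x
#' contrast/correlation/energy/homogeneity), 3 Tamura features, and 36
#' wavelet energy signatures (level 1-4 x subband h/v/d x L1/L2/entropy).
#'
#' @return A tibble with columns `id`, `category`, `parameter`, `name`.
#' @examples
#' dplyr::count(feature_catalog(), category)
#' @export
feature_catalog <- function() {
  color <- tibble::tibble(
    id = c("col_mean_h", "col_mean_s", "col_mean_v"),
    category = "color",
    parameter = c("hue", "saturation", "value"),
    name = c("Mean of hue", "Mean of saturation", "Mean of value")
  )
  grid_g <- expand.grid(stat = glcm_stat_names, theta = glcm_orientations,
                        d = glcm_distances, stringsAsFactors = FALSE)
  glcm <- tibble::tibble(
    id = paste0("glcm_d", grid_g$d, "_a", grid_g$theta, "_", grid_g$stat),
    category = "glcm",
    parameter = paste0("d=", grid_g$d, ", theta=", grid_g$theta),
    name = c(Contrast = "Contrast", correlation = "Correlation",
             energy = "Energy", homogeneity = "Homogeneity"
             )[match(grid_g$stat, glcm_stat_names)]
  )
  glcm$name <- c("Contrast", "Correlation", "Energy",
                 "Homogeneity")[match(grid_g$stat, glcm_stat_names)]
  tamura <- tibble::tibble(
    id = c("tam_coarseness", "tam_contrast", "tam_directionality"),
    category = "tamura",
    parameter = "",
    name = c("Coarseness", "Contrast", "Directionality")
  )
  grid_w <- expand.grid(stat = c("l1norm", "l2norm", "entropy"),
                        band = c("h", "v", "d"), level = 1:4,
                        stringsAsFactors = FALSE)
  band_name <- c(h = "Horizontal", v = "Vertical", d = "Diagonal")
  wav <- tibble::tibble(
    id = paste0("wav_", grid_w$band, grid_w$level, "_", grid_w$stat),
    category = "wavelet",
    parameter = paste0(band_name[grid_w$band], " subband at level ",
                       grid_w$level),
    name = c(l1norm = "L1 norm", l2norm = "L2 norm",
             entropy = "Shannon entropy")[grid_w$stat]
  )
  dplyr::bind_rows(color, glcm, tamura, wav)
}

#' Extract the 106 low-level features of one texture
#'
#' Computes, in catalog order, the HSV color means, the 64 co-occurrence
#' statistics of the luminance image, the three Tamura features and the 36
#' wavelet energy signatures. The function is pure: identical images give
#' bit-identical feature vectors.
#'
#' @param image An [texture_image()] or bare H x W x 3 array in `[0, 255]`.
#' @param glcm_levels Gray levels used by the co-occurrence matrices
#'   (default 16).
#' @return Named numeric vector of length 106 (names are catalog ids).
#' @examples
#' img <- gen_texture(texture_recipe("grating", size = c(64, 64)))
#' fv <- extract_features(img)
#' length(fv)
#' @export
extract_features <- function(image, glcm_levels = 16L) {
  gray <- as_gray(image)
  out <- c(
    color_means(image),
    glcm_feature_block(gray, levels = glcm_levels),
    tam_coarseness = tamura_coarseness(gray),
    tam_contrast = tamura_contrast(gray),
    tam_directionality = tamura_directionality(gray),
    wavelet_signatures(gray)
  )
  bad <- !is.finite(out)
  if (any(bad)) {
    stop("non-finite feature value(s): ", paste(names(out)[bad], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Extract features for a set of textures into a table
#'
#' @param images A named list of textures (names become `texture_id`), or the
#'   `image` list-column of [gen_texture_suite()] output.
#' @param ids Optional character vector of texture ids (defaults to list
#'   names, else `tex_001` style).
#' @inheritParams extract_features
#' @return A tibble: `texture_id` plus 106 feature columns in catalog order.
#' @export
extract_features_tbl <- function(images, ids = NULL, glcm_levels = 16L) {
  if (is.null(ids)) {
    ids <- names(images) %||% sprintf("tex_%03d", seq_along(images))
  }
  rows <- purrr::map(images, extract_features, glcm_levels = glcm_levels)
  dplyr::bind_cols(
    tibble::tibble(texture_id = ids),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

#' Write a feature table and its catalog sidecar
#'
#' @param features Tibble from [extract_features_tbl()].
#' @param path Output CSV path (one row per image, 107 columns).
#' @param catalog_path Optional path for a JSON catalog mapping each column to
#'   its category, parameters and human-readable name.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, catalog_path = NULL) {
  utils::write.csv(features, path, row.names = FALSE)
  if (!is.null(catalog_path)) {
    jsonlite::write_json(feature_catalog(), catalog_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
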