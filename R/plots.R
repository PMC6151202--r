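#' Plot a texture image
#'
#' @param image An [texture_image()].
#' @return A ggplot raster plot.
#' @export
plot_texture <- function(image) {
  d <- dim(image)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(as.vector(image[, , 1]), as.vector(image[, , 2]),
                            as.vector(image[, , 3]), maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Feature-weight plot for an NCA fit
#'
#' @param object An `aes_nca`.
#' @param top_k Show only the `top_k` largest weights (default all).
#' @param ... Unused.
#' @return A ggplot bar chart of weights in rank order.
#' @export
autoplot.aes_nca <- function(object, top_k = NULL, ...) {
  td <- tidy(object)
  if (!is.null(top_k)) td <- dplyr::slice_head(td, n = top_k)
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$feature, -.data$rank),
    y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "NCA weight")
}

#' Predicted-versus-observed plot for a fitted hierarchy
#'
#' Held-out textures are shown as filled points, training textures hollow;
#' one facet per property.
#'
#' @param object An `aes_hierarchy_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aes_hierarchy_fit <- function(object, ...) {
  schema <- property_schema()
  long <- function(tbl, what) {
    tidyr::pivot_longer(tbl, -"texture_id", names_to = "property",
                        values_to = what)
  }
  df <- dplyr::inner_join(long(object$predictions, "predicted"),
                          long(object$observed, "observed"),
                          by = c("texture_id", "property"))
  test_ids <- object$observed$texture_id[object$split$test]
  df$set <- ifelse(df$texture_id %in% test_ids, "test", "train")
  df$property <- factor(df$property, levels = schema$property)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                   shape = .data$set)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(train = 1, test = 16)) +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::labs(x = "observed rating", y = "predicted rating",
                  shape = NULL)
}
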