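#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an NCA fit
#'
#' @param x An `aes_nca`.
#' @param ... Unused.
#' @return Tibble with `feature`, `weight`, `rank` (1 = largest weight).
#' @export
tidy.aes_nca <- function(x, ...) {
  tibble::tibble(
    feature = names(x$weights),
    weight = unname(x$weights),
    rank = rank(-x$weights, ties.method = "first")
  ) |> dplyr::arrange(.data$rank)
}

#' @rdname tidy.aes_nca
#' @export
glance.aes_nca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$weights),
    objective = x$trace[length(x$trace)],
    iterations = length(x$trace) - 1L,
    converged = x$converged,
    lambda = x$lambda
  )
}

#' Tidy a fitted hierarchy
#'
#' One row per property: layer, fitted expression (as text), complexity, and
#' train/test mean absolute error and Pearson correlation.
#'
#' @param x An `aes_hierarchy_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.aes_hierarchy_fit <- function(x, ...) {
  dplyr::mutate(x$metrics,
                expression = purrr::map_chr(.data$property, function(p) {
                  format(x$model$expressions[[p]])
                }),
                .after = "layer")
}

#' @rdname tidy.aes_hierarchy_fit
#' @export
glance.aes_hierarchy_fit <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$split$train),
    n_test = length(x$split$test),
    mean_r_test = mean(x$metrics$r_test),
    mean_mae_test = mean(x$metrics$mae_test),
    total_complexity = sum(x$metrics$complexity),
    thresholds = list(x$model$thresholds)
  )
}
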