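#' Model evaluation metrics
#'
#' Mean absolute error, Pearson correlation, and (when a model expression is
#' supplied) the expression complexity ([expr_complexity()]), the three
#' quantities used to compare fitted models: the best model has the greatest
#' correlation and the least mean absolute error at acceptable complexity.
#'
#' @param predicted,observed Equal-length numeric vectors, `n >= 2`.
#' @param model Optional `aes_expr` (or `aes_hmodel` whose total complexity is
#'   reported).
#' @return One-row tibble with columns `mae`, `r`, `complexity` (NA when no
#'   model is given).
#' @examples
#' model_metrics(c(1, 2, 3), c(1.5, 2, 2.5))
#' @export
model_metrics <- function(predicted, observed, model = NULL) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::var(observed) == 0) {
    stop("`observed` has zero variance; correlation is undefined",
         call. = FALSE)
  }
  cx <- if (is.null(model)) NA_integer_
  else if (inherits(model, "aes_expr")) expr_complexity(model)
  else if (inherits(model, "aes_hmodel")) {
    sum(vapply(model$expressions, expr_complexity, integer(1)))
  } else stop("`model` must be an aes_expr or aes_hmodel", call. = FALSE)
  tibble::tibble(
    mae = mean(abs(predicted - observed)),
    r = stats::cor(predicted, observed),
    complexity = cx
  )
}
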