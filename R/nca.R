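# Neighborhood component analysis for regression (diagonal metric), used to
# weight and rank features against a continuous rating. Each sample softly
# selects neighbours with probability p_ij proportional to
# exp(-sum_m w_m^2 |x_im - x_jm|) (p_ii = 0); the objective is the expected
# leave-one-out absolute prediction error sum_ij p_ij |y_i - y_j| / n plus an
# L2 penalty on the weights, minimized by gradient descent with a
# backtracking step size. Everything is deterministic: weights start at 1.

nca_objective <- function(w, A, Lmat, lambda) {
  D <- Reduce(`+`, Map(function(a, wm) wm^2 * a, A, as.list(w)))
  diag(D) <- Inf
  E <- exp(-(D - apply(D, 1L, min)))
  P <- E / rowSums(E)
  sum(P * Lmat) / nrow(Lmat) + lambda * sum(w^2)
}

nca_grad <- function(w, A, Lmat, lambda) {
  n <- nrow(Lmat)
  D <- Reduce(`+`, Map(function(a, wm) wm^2 * a, A, as.list(w)))
  diag(D) <- Inf
  E <- exp(-(D - apply(D, 1L, min)))
  P <- E / rowSums(E)
  PL <- P * Lmat
  li <- rowSums(PL)
  g <- vapply(seq_along(w), function(m) {
    t1 <- sum(li * rowSums(P * A[[m]]))
    t2 <- sum(PL * A[[m]])
    2 * w[m] * (t1 - t2) / n
  }, numeric(1))
  g + 2 * lambda * w
}

#' Fit regression NCA feature weights
#'
#' Learns one non-negative relevance weight per feature by minimizing the
#' soft-neighbour leave-one-out absolute error of the response (see package
#' vignette for the objective). Weights enter the distance squared, so their
#' sign is immaterial and they are reported as magnitudes.
#'
#' @param x Numeric feature matrix or data frame (`n x p`, `n >= 3`), no
#'   non-finite entries.
#' @param y Numeric response, length `n`.
#' @param lambda L2 regularization (default `1/n`).
#' @param max_iter,tol Gradient-descent iteration cap and relative objective
#'   tolerance.
#' @param standardize Center/scale columns before fitting (default TRUE);
#'   strongly recommended since the distance is scale-sensitive.
#' @return Object of class `aes_nca`: `weights` (named, `>= 0`), `trace`
#'   (objective per accepted iteration, non-increasing), `converged`,
#'   `lambda`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' fit <- nca_fit(x, 2 * x[, 1] + rnorm(20, sd = 0.1))
#' tidy(fit)
#' @export
nca_fit <- function(x, y, lambda = NULL, max_iter = 150L, tol = 1e-6,
                    standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(y) != n) stop("`y` length must match rows of `x`", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in `x` or `y`", call. = FALSE)
  }
  if (is.null(lambda)) lambda <- 1 / n
  nms <- colnames(x) %||% paste0("x", seq_len(p))
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0
  }
  # per-feature absolute-difference matrices, computed once
  A <- lapply(seq_len(p), function(m) abs(outer(x[, m], x[, m], `-`)))
  Lmat <- abs(outer(y, y, `-`))

  w <- rep(1, p)
  obj <- nca_objective(w, A, Lmat, lambda)
  trace <- obj
  if (stats::var(y) == 0) {
    rlang::inform("response is constant: NCA gradient is zero, returning initial weights")
    return(structure(list(weights = stats::setNames(w, nms), trace = trace,
                          converged = TRUE, lambda = lambda),
                     class = "aes_nca"))
  }
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- nca_grad(w, A, Lmat, lambda)
    repeat {
      w_new <- w - step * g
      obj_new <- nca_objective(w_new, A, Lmat, lambda)
      if (is.finite(obj_new) && obj_new <= obj) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) { converged <- TRUE; break }
    rel <- (obj - obj_new) / max(abs(obj), 1e-12)
    w <- w_new; obj <- obj_new
    trace <- c(trace, obj)
    step <- step * 1.2
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(
    list(weights = stats::setNames(abs(w), nms), trace = trace,
         converged = converged, lambda = lambda),
    class = "aes_nca"
  )
}

#' @export
print.aes_nca <- function(x, ...) {
  cat(sprintf("<aes_nca> %d features, objective %.6g after %d iterations%s\n",
              length(x$weights), x$trace[length(x$trace)],
              length(x$trace) - 1L,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Rank features by weight and keep the top k
#'
#' Indices are ordered by descending weight; ties are broken by the lower
#' catalog index. Selected features receive the symbolic labels `f1`, `f2`,
#' ... in rank order, the names the model equations use.
#'
#' @param weights An `aes_nca` fit or a numeric weight vector (names taken as
#'   feature ids).
#' @param k Number of features to keep (`1 <= k <= p`).
#' @param catalog Optional catalog tibble (as [feature_catalog()]) joined in
#'   by feature id.
#' @return Tibble with columns `f_label`, `index`, `id`, `weight` (plus
#'   catalog columns if supplied), ordered `f1` .. `fk`.
#' @export
rank_and_select <- function(weights, k, catalog = NULL) {
  w <- if (inherits(weights, "aes_nca")) weights$weights else weights
  p <- length(w)
  if (k < 1L || k > p) stop("`k` must be between 1 and ", p, call. = FALSE)
  ord <- order(-w, seq_len(p))[seq_len(k)]
  out <- tibble::tibble(
    f_label = paste0("f", seq_len(k)),
    index = ord,
    id = names(w)[ord] %||% as.character(ord),
    weight = unname(w[ord])
  )
  if (!is.null(catalog)) {
    out <- dplyr::left_join(out, catalog, by = "id")
  }
  out
}

#' The published selected-feature catalog
#'
#' The frozen mapping of the ten selected features `f1` .. `f10` (with their
#' published NCA weights) onto the 106-feature catalog: mean saturation, five
#' co-occurrence statistics, the Tamura coarseness and directionality, and
#' two level-1 wavelet norms. This is the default selection used by the model
#' pipeline, since re-running NCA requires rating data.
#'
#' @return Tibble with columns `f_label`, `id`, `weight`, `category`,
#'   `parameter`, `name`.
#' @examples
#' reference_catalog()
#' @export
reference_catalog <- function() {
  out <- tibble::tibble(
    f_label = paste0("f", 1:10),
    id = c("col_mean_s",
           "glcm_d8_a45_contrast", "glcm_d6_a45_contrast",
           "glcm_d8_a135_contrast", "glcm_d8_a90_homogeneity",
           "glcm_d4_a45_contrast",
           "tam_coarseness", "tam_directionality",
           "wav_h1_l2norm", "wav_v1_l1norm"),
    weight = c(4.8884, 4.2978, 3.3620, 3.0538, 2.9077, 2.4637, 1.8981,
               1.8723, 1.7262, 1.5843)
  )
  cat_tbl <- feature_catalog()
  dplyr::left_join(out, cat_tbl, by = "id")
}

#' Pull selected feature values out of a 106-feature table
#'
#' @param features Tibble from [extract_features_tbl()] (`texture_id` +
#'   feature columns).
#' @param selection A selection tibble with columns `f_label` and `id`
#'   (default [reference_catalog()]).
#' @return Tibble: `texture_id` plus columns `f1` .. `fk`.
#' @export
select_features <- function(features, selection = reference_catalog()) {
  missing <- setdiff(selection$id, names(features))
  if (length(missing)) {
    stop("feature table lacks selected column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- features[, c("texture_id", selection$id)]
  names(out) <- c("texture_id", selection$f_label)
  tibble::as_tibble(out)
}
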