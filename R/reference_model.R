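# The frozen reference model: the published fitted equations of the
# three-layer hierarchy, transcribed term by term. Evaluation is exact
# double-precision arithmetic on the printed coefficients; no hidden scaling.

ref_affective_exprs <- function() {
  list(
    G1 = aes_expr(list(
      .t(-8094.8087),
      .t(812.5336, "f8"),
      .t(45616.6421, "f9"),
      .t(912.3156, "f10"),
      .t(-12.2778, "f1"),
      .t(-193.0201, "f1", "f9"),
      .t(-3851, "f8", "f9"),
      .t(-5152.5354, "f9", "f10")
    )),
    G2 = aes_expr(list(
      .t(-2.4097),
      .t(2.4427e-3, "f7")
    )),
    G3 = aes_expr(list(
      .t(-17383.3439),
      .t(1632.0393, "f1"),
      .t(-8.4352, "f3"),
      .t(4091.5619, "f10"),
      .t(-179.9276, "f1", "f7"),
      .t(-1740.2929, "f1", "f9"),
      .t(-239.9238, "f10^2")
    ))
  )
}

ref_judgment_exprs <- function(eq7 = c("ratio", "product")) {
  eq7 <- match.arg(eq7)
  # The T1 equation's middle term is typeset ambiguously in the source; the
  # fraction reading -(f8*G3)/(f1*f3*G1) is the default, the plain product
  # -f8*G3*f1*f3*G1 is kept for sensitivity checks.
  t1_mid <- if (eq7 == "ratio") {
    .t(-1, "f8", "G3", "1/f1", "1/f3", "1/G1")
  } else {
    .t(-1, "f8", "G3", "f1", "f3", "G1")
  }
  list(
    T1 = aes_expr(list(
      .t(-5802.8782),
      .t(-2.6621, "f1"),
      .t(1376.0294, "f10"),
      .t(1, "G3"),
      .t(0.5044, "f3", "G3"),
      t1_mid,
      .t(-81.5644, "f10^2")
    )),
    T2 = aes_expr(list(
      .t(-120.8679),
      .t(18.7771, "f10"),
      .t(6.2114, "f3", "f4"),
      .t(-16.5658, "f2", "f4"),
      .t(-5.0154, "f4", "f9"),
      .t(14.4728, "G1", "f9^2")
    )),
    T3 = aes_expr(list(
      .t(-525.3141),
      .t(22064.1366, "f4"),
      .t(1, "f7"),
      .t(61.6075, "f10"),
      .t(-92.5762, "f1", "f8"),
      .t(-152.7179, "f1", "f2"),
      .t(228.3617, "f9^2"),
      .t(-5175.2472, "f3", "f4", "f10"),
      .t(303.4996, "f3", "f4", "f10^2")
    )),
    T4 = aes_expr(list(
      .t(4.3881e3),
      .t(1.8217, "G2"),
      .t(71.5439, "f9"),
      .t(0.8139, "f7")
    ))
  )
}

ref_emotional_expr <- function() {
  aes_expr(list(
    .t(38.4474),
    .t(-10.7260, "f1"),
    .t(-57.6083, "f8"),
    .t(0.0914, "T3"),
    .t(1.4546, "f1", "G1")
  ))
}

#' The frozen reference hierarchy
#'
#' Returns the published fitted model of the three-layer hierarchy as
#' inspectable expression trees: three affective activations (G1-G3 from
#' features), four judgment activations (T1-T4 from features and G), and one
#' emotional activation (Q from features, G and T). The layer thresholds are
#' 0 here because the printed equations absorb them into their intercepts.
#'
#' @param eq7 Reading of the ambiguously typeset middle term of the T1
#'   equation: `"ratio"` (default) for `-(f8*G3)/(f1*f3*G1)` or `"product"`.
#' @return Object of class `aes_hmodel`: list with `expressions` (named list
#'   of `aes_expr`, names G1..G3, T1..T4, Q) and `thresholds`
#'   (`R0`, `R1`, `R2`).
#' @examples
#' m <- reference_model()
#' m$expressions$G2
#' expr_complexity(m$expressions$G2)
#' @export
reference_model <- function(eq7 = c("ratio", "product")) {
  eq7 <- match.arg(eq7)
  structure(
    list(
      expressions = c(ref_affective_exprs(), ref_judgment_exprs(eq7),
                      list(Q = ref_emotional_expr())),
      thresholds = c(R0 = 0, R1 = 0, R2 = 0)
    ),
    class = "aes_hmodel"
  )
}

#' @export
print.aes_hmodel <- function(x, ...) {
  cat("<aes_hmodel> three-layer hierarchical model\n")
  for (p in names(x$expressions)) {
    cat(sprintf("  %-3s = %s\n", p, format(x$expressions[[p]])))
  }
  cat(sprintf("  thresholds: R0 = %g, R1 = %g, R2 = %g\n",
              x$thresholds["R0"], x$thresholds["R1"], x$thresholds["R2"]))
  invisible(x)
}

as_f_tbl <- function(f) {
  if (is.data.frame(f)) return(tibble::as_tibble(f))
  if (is.numeric(f) && !is.null(names(f))) return(tibble::as_tibble(as.list(f)))
  stop("`f` must be a data frame or a named numeric vector (f1..f10)",
       call. = FALSE)
}

check_finite_inputs <- function(tbl, what) {
  bad <- vapply(tbl, function(col) any(!is.finite(col)), logical(1))
  if (any(bad)) {
    stop("non-finite ", what, " value(s): ",
         paste(names(tbl)[bad], collapse = ", "), call. = FALSE)
  }
}

#' Evaluate the affective layer of the reference model
#'
#' @param f Selected feature values: a named numeric vector or data frame with
#'   columns `f1` .. `f10`.
#' @param model An `aes_hmodel` (default [reference_model()]).
#' @return Tibble with columns `G1`, `G2`, `G3` (one row per input row).
#' @export
eval_affective <- function(f, model = reference_model()) {
  f <- as_f_tbl(f)
  check_finite_inputs(f, "feature")
  tibble::as_tibble(purrr::map(model$expressions[c("G1", "G2", "G3")],
                               function(e) eval_expr(e, f) +
                                 model$thresholds[["R0"]]))
}

#' Evaluate the judgment layer of the reference model
#'
#' The T1 equation contains the ratio term `-(f8*G3)/(f1*f3*G1)`; a zero
#' denominator `f1*f3*G1` raises a domain error naming the term.
#'
#' @inheritParams eval_affective
#' @param G Affective values: data frame or named vector with `G1`, `G2`, `G3`.
#' @return Tibble with columns `T1` .. `T4`.
#' @export
eval_judgment <- function(f, G, model = reference_model()) {
  f <- as_f_tbl(f); G <- as_f_tbl(G)
  check_finite_inputs(f, "feature"); check_finite_inputs(G, "affective")
  data <- dplyr::bind_cols(f, G)
  uses_ratio <- any(vapply(model$expressions$T1$terms, function(tm) {
    any(vapply(tm$factors, function(fc) fc$pow < 0, logical(1)))
  }, logical(1)))
  if (uses_ratio) {
    den <- data$f1 * data$f3 * data$G1
    if (any(den == 0)) {
      stop("zero denominator in the T1 ratio term f8*G3/(f1*f3*G1)",
           call. = FALSE)
    }
  }
  tibble::as_tibble(purrr::map(model$expressions[c("T1", "T2", "T3", "T4")],
                               function(e) eval_expr(e, data) +
                                 model$thresholds[["R1"]]))
}

#' Evaluate the emotional layer of the reference model
#'
#' @inheritParams eval_judgment
#' @param T_ Judgment values: data frame or named vector with `T1` .. `T4`.
#' @return Tibble with column `Q`.
#' @export
eval_emotional <- function(f, G, T_, model = reference_model()) {
  f <- as_f_tbl(f); G <- as_f_tbl(G); T_ <- as_f_tbl(T_)
  check_finite_inputs(f, "feature"); check_finite_inputs(G, "affective")
  check_finite_inputs(T_, "judgment")
  data <- dplyr::bind_cols(f, G, T_)
  tibble::tibble(Q = eval_expr(model$expressions$Q, data) +
                   model$thresholds[["R2"]])
}

#' Feed-forward prediction of all layer values
#'
#' Evaluates the hierarchy in order: affective values from the selected
#' features, judgment values from features and affective outputs, and the
#' emotional value from all of the above. Information flows only forward.
#'
#' @inheritParams eval_affective
#' @param transform Optional transform record from [preprocess_features()]
#'   applied to the feature columns before evaluation; by default features are
#'   used as given.
#' @return Tibble with columns `G1`..`G3`, `T1`..`T4`, `Q`.
#' @examples
#' predict_layers(c(f1 = 1, f2 = 1, f3 = 1, f4 = 1, f5 = 1,
#'                  f6 = 1, f7 = 1, f8 = 1, f9 = 1, f10 = 1))
#' @export
predict_layers <- function(f, model = reference_model(), transform = NULL) {
  f <- as_f_tbl(f)
  if (!is.null(transform)) f <- apply_transform(transform, f)
  G <- eval_affective(f, model)
  T_ <- eval_judgment(f, G, model)
  Q <- eval_emotional(f, G, T_, model)
  dplyr::bind_cols(G, T_, Q)
}

#' Save / load a hierarchy model as a JSON expression tree
#'
#' @param model An `aes_hmodel`.
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   `aes_hmodel`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    thresholds = as.list(model$thresholds),
    expressions = purrr::map(model$expressions, expr_to_list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(
    list(
      expressions = purrr::map(obj$expressions, expr_from_list),
      thresholds = unlist(obj$thresholds)
    ),
    class = "aes_hmodel"
  )
}
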