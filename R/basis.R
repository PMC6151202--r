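# Candidate-term basis over named input columns. The term family mirrors the
# shapes of the reference equations: a constant, linear terms, squares,
# pairwise products (degree 2), optional unary transforms of single inputs,
# and optional pairwise quotients.

term_name <- function(tm) {
  if (!length(tm$factors)) return("1")
  paste(vapply(tm$factors, function(fc) {
    s <- fc$var
    if (fc$fn != "identity") s <- paste0(fc$fn, "(", s, ")")
    if (fc$pow == 2L) s <- paste0(s, "^2")
    if (fc$pow < 0L) s <- paste0("1/", s)
    s
  }, character(1)), collapse = "*")
}

#' Build a candidate term basis
#'
#' Enumerates candidate regression terms over the given input columns, drawn
#' from the operator library of the fitter: constants; addition, subtraction,
#' multiplication and division of inputs (up to pairwise interactions);
#' squares; and unary trigonometric/exponential transforms. Terms that
#' produce any non-finite value on `data` (e.g. `log` of a non-positive
#' column, division by zero) are dropped and reported via a message.
#'
#' @param data Data frame of input columns (training rows only — domain
#'   screening must not see test rows).
#' @param degree Maximum interaction degree (1 or 2; default 2).
#' @param unaries Character vector of unary operators to include, from
#'   `sin`, `cos`, `tan`, `exp`, `log`, `sqrt` (default none).
#' @param ratios Include pairwise quotient candidates `x/y` (default FALSE;
#'   domain-fragile).
#' @return Object of class `aes_basis`: tibble with columns `name`, `term`
#'   (list of unit-coefficient terms).
#' @examples
#' build_basis(data.frame(x1 = 1:3, x2 = 4:6))$name
#' @export
build_basis <- function(data, degree = 2L, unaries = character(),
                        ratios = FALSE) {
  if (!is.data.frame(data) || ncol(data) == 0L) {
    stop("`data` must be a data frame with at least one column", call. = FALSE)
  }
  vars <- names(data)
  terms <- list(expr_term(1, list()))                       # constant
  for (v in vars) terms <- c(terms, list(.t(1, v)))         # linear
  if (degree >= 2L) {
    for (v in vars) terms <- c(terms, list(.t(1, paste0(v, "^2"))))
    if (length(vars) >= 2L) {
      pairs <- utils::combn(vars, 2L, simplify = FALSE)
      for (pr in pairs) terms <- c(terms, list(.t(1, pr[1], pr[2])))
    }
  }
  for (fn in unaries) {
    stopifnot(fn %in% c("sin", "cos", "tan", "exp", "log", "sqrt"))
    for (v in vars) terms <- c(terms, list(.t(1, paste0(fn, "(", v, ")"))))
  }
  if (ratios && length(vars) >= 2L) {
    for (v1 in vars) for (v2 in setdiff(vars, v1)) {
      terms <- c(terms, list(.t(1, v1, paste0("1/", v2))))
    }
  }
  nms <- vapply(terms, term_name, character(1))
  keepers <- !duplicated(nms)
  terms <- terms[keepers]; nms <- nms[keepers]
  ok <- vapply(terms, function(tm) {
    all(is.finite(eval_expr(aes_expr(list(tm)), data)))
  }, logical(1))
  if (any(!ok)) {
    rlang::inform(paste0("dropped ", sum(!ok),
                         " domain-violating candidate term(s): ",
                         paste(utils::head(nms[!ok], 5L), collapse = ", "),
                         if (sum(!ok) > 5L) ", ..." else ""))
  }
  structure(tibble::tibble(name = nms[ok], term = terms[ok]),
            class = c("aes_basis", class(tibble::tibble())))
}

# evaluate every candidate term on a data frame -> n x k matrix
basis_matrix <- function(basis, data) {
  mat <- vapply(basis$term, function(tm) {
    eval_expr(aes_expr(list(tm)), data)
  }, numeric(nrow(data)))
  colnames(mat) <- basis$name
  mat
}
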