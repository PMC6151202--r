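# Symbolic expressions for the white-box models.
#
# An expression is a sum of terms; a term is a coefficient times a product of
# factors; a factor is a variable raised to an integer power (negative powers
# denote division, as in the ratio term of the judgment layer), optionally
# wrapped in a unary function. This family covers every printed reference
# equation as well as everything the greedy fitter can build.

expr_factor <- function(var, pow = 1L, fn = "identity") {
  list(var = var, pow = as.integer(pow), fn = fn)
}

expr_term <- function(coef, factors = list()) {
  list(coef = coef, factors = factors)
}

# shorthand used when transcribing models: .t(coef, "f1", "f8", "f9^2", "1/f3",
# "sin(f2)")
.t <- function(coef, ...) {
  specs <- c(...)
  factors <- lapply(specs, function(s) {
    fn <- "identity"
    m <- regmatches(s, regexec("^([a-z]+)\\((.+)\\)$", s))[[1]]
    if (length(m) == 3L) {
      fn <- m[2]; s <- m[3]
    }
    pow <- 1L
    if (grepl("^1/", s)) { pow <- -1L; s <- sub("^1/", "", s) }
    if (grepl("\\^2$", s)) { pow <- 2L * pow; s <- sub("\\^2$", "", s) }
    expr_factor(s, pow, fn)
  })
  expr_term(coef, factors)
}

#' Build a model expression from terms
#'
#' @param terms List of terms, each created by the internal term constructors;
#'   most users get expressions from [fit_layer()] or [reference_model()]
#'   rather than building them by hand.
#' @return An object of class `aes_expr`.
#' @keywords internal
aes_expr <- function(terms) {
  structure(list(terms = terms), class = "aes_expr")
}

unary_fns <- list(
  identity = identity, sin = sin, cos = cos, tan = tan,
  exp = exp, log = log, sqrt = sqrt
)

#' Evaluate a model expression on a data frame
#'
#' @param expr An `aes_expr`.
#' @param data Data frame or named list; each variable in the expression must
#'   be a column.
#' @return Numeric vector, one value per row.
#' @export
eval_expr <- function(expr, data) {
  n <- if (is.data.frame(data)) nrow(data) else length(data[[1]])
  out <- numeric(n)
  for (tm in expr$terms) {
    v <- rep(tm$coef, n)
    for (fc in tm$factors) {
      col <- data[[fc$var]]
      if (is.null(col)) stop("expression variable `", fc$var,
                             "` not found in data", call. = FALSE)
      x <- unary_fns[[fc$fn]](col)
      v <- v * x^fc$pow
    }
    out <- out + v
  }
  out
}

#' Variables an expression depends on
#'
#' Symbolic dependence extraction: the set of variable names appearing in any
#' term of the expression.
#'
#' @param expr An `aes_expr`.
#' @return Character vector of variable names.
#' @export
expr_vars <- function(expr) {
  unique(unlist(lapply(expr$terms, function(tm) {
    vapply(tm$factors, `[[`, character(1), "var")
  })))
}

#' Expression complexity (node count)
#'
#' Counts the nodes of the binary expression tree: every constant, variable
#' occurrence and operator (+, x, /, unary function) contributes 1. A
#' squared variable counts as two variable occurrences joined by a product; a
#' coefficient of exactly 1 on a non-constant term contributes no node. The
#' affective-layer reference equation `c0 + c1 * f7` therefore counts 5.
#'
#' @param expr An `aes_expr`.
#' @return Positive integer.
#' @export
expr_complexity <- function(expr) {
  term_nodes <- vapply(expr$terms, function(tm) {
    units <- 0L; fns <- 0L
    for (fc in tm$factors) {
      units <- units + abs(fc$pow)
      if (fc$fn != "identity") fns <- fns + 1L
    }
    coef_node <- if (tm$coef != 1 || units == 0L) 1L else 0L
    operands <- coef_node + units
    operands + max(operands - 1L, 0L) + fns
  }, integer(1))
  sum(term_nodes) + (length(expr$terms) - 1L)
}

format_factor <- function(fc) {
  s <- fc$var
  if (fc$fn != "identity") s <- paste0(fc$fn, "(", s, ")")
  if (abs(fc$pow) == 2L) s <- paste0(s, "^2")
  s
}

#' @export
format.aes_expr <- function(x, digits = 6, ...) {
  parts <- vapply(x$terms, function(tm) {
    num <- Filter(function(fc) fc$pow > 0, tm$factors)
    den <- Filter(function(fc) fc$pow < 0, tm$factors)
    s <- paste(vapply(num, format_factor, character(1)), collapse = "*")
    if (length(den)) {
      s <- paste0(if (nzchar(s)) s else "1", "/(",
                  paste(vapply(den, format_factor, character(1)),
                        collapse = "*"), ")")
    }
    cf <- signif(tm$coef, digits)
    if (!nzchar(s)) as.character(cf)
    else if (tm$coef == 1) s
    else paste0(cf, "*", s)
  }, character(1))
  paste(parts, collapse = " + ")
}

#' @export
print.aes_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

expr_to_list <- function(expr) {
  lapply(expr$terms, function(tm) {
    list(coef = tm$coef,
         factors = lapply(tm$factors, function(fc) {
           list(var = fc$var, pow = fc$pow, fn = fc$fn)
         }))
  })
}

expr_from_list <- function(lst) {
  aes_expr(lapply(lst, function(tm) {
    expr_term(as.numeric(tm$coef), lapply(tm$factors, function(fc) {
      expr_factor(fc$var, fc$pow, fc$fn)
    }))
  }))
}
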