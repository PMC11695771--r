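#' Growth-rate-dependent stoichiometric coefficients
#'
#' ME models couple gene expression to metabolism through stoichiometric
#' coefficients that are rational functions of the growth rate `mu` (h^-1),
#' e.g. the dilution term `-mu/keff` that ties enzyme demand to catalyzed
#' flux. `parse_mu_expression()` turns a coefficient string into an
#' evaluable `mu_expr` object.
#'
#' The grammar admits decimal/scientific literals, the symbol `mu`, the
#' operators `+ - * /`, unary minus, and parentheses. Any other symbol or
#' call is rejected.
#'
#' @param text A single character string, e.g. `"-mu/65"` or `"3.5"`.
#' @return An object of class `mu_expr`.
#' @examples
#' e <- parse_mu_expression("-mu/65")
#' eval_mu(e, 0.1)
#' @export
parse_mu_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  expr <- tryCatch(str2lang(text),
                   error = function(e) stop("cannot parse mu-expression '", text,
                                            "': ", conditionMessage(e), call. = FALSE))
  check_mu_ast(expr, text)
  structure(list(text = text, expr = expr), class = "mu_expr")
}

check_mu_ast <- function(node, text) {
  if (is.numeric(node)) {
    return(invisible(TRUE))
  }
  if (is.symbol(node)) {
    if (!identical(as.character(node), "mu")) {
      stop("unknown symbol '", as.character(node), "' in mu-expression '",
           text, "' (only 'mu' is allowed)", call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(node)) {
    op <- as.character(node[[1L]])
    if (!op %in% c("+", "-", "*", "/", "(")) {
      stop("operator '", op, "' not allowed in mu-expression '", text, "'",
           call. = FALSE)
    }
    if (op == "/" && is.numeric(node[[3L]]) && node[[3L]] == 0) {
      stop("division by a literal zero in mu-expression '", text, "'",
           call. = FALSE)
    }
    for (k in seq.int(2L, length(node))) check_mu_ast(node[[k]], text)
    return(invisible(TRUE))
  }
  stop("invalid token in mu-expression '", text, "'", call. = FALSE)
}

#' Evaluate a coefficient at a growth rate
#'
#' Plain numerics pass through, so model stoichiometries may freely mix
#' constants and `mu_expr` objects.
#'
#' @param x A numeric or a `mu_expr`.
#' @param mu Growth rate(s), h^-1. Vectorized.
#' @return Numeric of the same length as `mu` (or the constant).
#' @export
eval_mu <- function(x, mu) {
  if (is.numeric(x)) {
    return(if (length(mu) > 1L) rep(x, length(mu)) else x)
  }
  stopifnot(inherits(x, "mu_expr"))
  val <- eval(x$expr, list(mu = mu))
  if (length(val) == 1L && length(mu) > 1L) val <- rep(val, length(mu))
  val
}

#' @export
format.mu_expr <- function(x, ...) x$text

#' @export
print.mu_expr <- function(x, ...) {
  cat("<mu_expr> ", x$text, "\n", sep = "")
  invisible(x)
}

#' Check a coefficient for poles on the search interval
#'
#' Evaluates the expression on a dense grid over `[0, mu_hi]` and flags
#' non-finite values or magnitudes beyond `huge` (a pole passing between
#' grid points still produces such values near it at this resolution).
#'
#' @param x A numeric or `mu_expr`.
#' @param mu_hi Upper end of the growth-rate search interval, h^-1.
#' @param n Number of grid points.
#' @param huge Magnitude threshold treated as evidence of a pole.
#' @return `TRUE` if the coefficient is finite on the interval.
#' @export
mu_expr_finite_on <- function(x, mu_hi, n = 401L, huge = 1e12) {
  if (is.numeric(x)) return(is.finite(x))
  grid <- seq(0, mu_hi, length.out = n)
  val <- tryCatch(eval_mu(x, grid), error = function(e) NaN)
  all(is.finite(val)) && all(abs(val) < huge)
}

## internal: coefficient is an affine or general function of mu?
is_constant_coef <- function(x) is.numeric(x)

## internal: coerce a serialized coefficient (string or number) to internal form
coef_from_json <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  e <- parse_mu_expression(as.character(x))
  ## collapse constant expressions (no mu symbol) to plain numerics
  if (!("mu" %in% all.vars(e$expr))) return(eval_mu(e, 0))
  e
}

## internal: serialize a coefficient
coef_to_json <- function(x) {
  if (is.numeric(x)) return(x)
  x$text
}
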