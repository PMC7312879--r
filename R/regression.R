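#' Polynomial regression baseline
#'
#' Ordinary least-squares fit of a degree-1 (simple linear) or degree-2
#' (quadratic) polynomial of the time index, the conventional baselines
#' against which the grey models are compared. The reported correlation
#' coefficient R is the multiple correlation — the Pearson correlation
#' between observed and fitted values — which for degree 1 equals the
#' absolute correlation of response with time and for degree 2 equals
#' \eqn{\sqrt{R^2}} of the quadratic fit.
#'
#' @param t numeric time-index vector.
#' @param x numeric response vector, same length as `t`.
#' @param degree 1 or 2.
#' @return An object of class `poly_fit`: list with `degree`,
#'   `coefficients` (intercept first), `R`, `fitted`, `residuals`, and
#'   the inputs `t`, `x`. `R` is `NA` when observed or fitted values are
#'   constant (the correlation is then undefined).
#' @examples
#' f <- fit_poly(1:17, metallurgy_deaths()$values, 1)
#' coef(f)   # 41.441, 0.029
#' f$R       # 0.007 to 3 d.p.
#' @export
fit_poly <- function(t, x, degree = 1L) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L))
    stop("'degree' must be 1 or 2", call. = FALSE)
  t <- as.double(t); x <- as.double(x)
  if (length(t) != length(x))
    stop("'t' and 'x' must have equal length", call. = FALSE)
  if (length(t) < degree + 2L)
    stop("need at least degree + 2 observations", call. = FALSE)
  fit <- stats::lm(x ~ stats::poly(t, degree, raw = TRUE))
  beta <- unname(stats::coef(fit))
  if (any(is.na(beta)) || fit$rank < degree + 1L)
    stop("degenerate fit: collinear design (constant or repeated time ",
         "index)", call. = FALSE)
  fv <- unname(stats::fitted(fit))
  R <- if (stats::sd(x) == 0 || stats::sd(fv) == 0) NA_real_
       else stats::cor(x, fv)
  structure(
    list(degree = degree, coefficients = beta, R = R, fitted = fv,
         residuals = x - fv, t = t, x = x),
    class = "poly_fit"
  )
}

#' Regression baseline for a 0/1 event indicator
#'
#' Fits the same polynomial baselines to a binary occurred/not-occurred
#' annual indicator — a linear probability model. It is retained
#' deliberately despite its well-known inadequacy for binary outcomes
#' (fitted "probabilities" outside [0, 1], every future year predicted
#' above/below 0.5): the comparison motivates the grey catastrophe
#' approach.
#'
#' @param t numeric time-index vector.
#' @param s 0/1 indicator vector.
#' @param degree 1 or 2.
#' @return A `poly_fit` object (see [fit_poly()]).
#' @examples
#' f <- fit_indicator(1:16, severe_accident_indicator(), 1)
#' round(f$fitted[1], 5)  # 0.28676
#' @export
fit_indicator <- function(t, s, degree = 1L) {
  s <- as.double(s)
  if (!all(s %in% c(0, 1)))
    stop("'s' must contain only 0 and 1", call. = FALSE)
  fit_poly(t, s, degree)
}

#' @export
coef.poly_fit <- function(object, ...) object$coefficients

#' @export
fitted.poly_fit <- function(object, ...) object$fitted

#' @export
residuals.poly_fit <- function(object, ...) object$residuals

# "41.441 + 0.029t" / "-0.75t2 + 13.608t - 1.559" style formula text
poly_formula_text <- function(x, digits = 3) {
  b <- x$coefficients
  term <- function(coef, suffix) {
    sprintf("%s %s%s", if (coef < 0) "-" else "+",
            format(abs(round(coef, digits))), suffix)
  }
  if (x$degree == 1L) {
    txt <- paste(format(round(b[1L], digits)), term(b[2L], "t"))
  } else {
    txt <- paste(sub("^\\+ ", "", term(b[3L], "t^2")), term(b[2L], "t"),
                 term(b[1L], ""))
  }
  trimws(txt)
}

#' @export
print.poly_fit <- function(x, digits = 3, ...) {
  kind <- if (x$degree == 1L) "Simple linear" else "Quadratic"
  cat(sprintf("%s regression baseline\n", kind))
  cat("  x =", poly_formula_text(x, digits), "\n")
  cat(sprintf("  correlation coefficient R = %.3f\n", x$R))
  invisible(x)
}
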