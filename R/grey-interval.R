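#' Grey interval bound functions on the accumulated scale
#'
#' For an annual series with extremes \eqn{\sigma_{max} = \max_k
#' x^{(0)}(k)} and \eqn{\sigma_{min} = \min_k x^{(0)}(k)}, the grey
#' interval method bounds the future accumulated series by straight lines
#' through its last point:
#' \deqn{f_u(n+t) = x^{(1)}(n) + t\,\sigma_{max}, \quad
#'       f_l(n+t) = x^{(1)}(n) + t\,\sigma_{min}, \quad
#'       f_b(n+t) = \frac{f_u(n+t) + f_l(n+t)}{2}.}
#' No future annual value can exceed the historical extremes under the
#' method's assumption, so the accumulated series is sandwiched between
#' these lines.
#'
#' @param series an [annual_series()].
#' @param t non-negative forecast horizon in steps beyond \eqn{n}
#'   (vectorized).
#' @return A list with vectors `f_upper`, `f_lower`, `f_basic` (one per
#'   horizon), plus `sigma_max`, `sigma_min` and `x1_n` (the last
#'   accumulated value).
#' @examples
#' bound_functions(metallurgy_deaths(), 2)  # 879, 741, 810
#' @export
bound_functions <- function(series, t) {
  if (is.numeric(series)) series <- annual_series(series, 1L)
  stopifnot(inherits(series, "annual_series"))
  t <- as.double(t)
  if (any(t < 0)) stop("horizon t must be >= 0", call. = FALSE)
  x0 <- series$values
  x1n <- sum(x0)
  smax <- max(x0)
  smin <- min(x0)
  fu <- x1n + t * smax
  fl <- x1n + t * smin
  list(f_upper = fu, f_lower = fl, f_basic = (fu + fl) / 2,
       sigma_max = smax, sigma_min = smin, x1_n = x1n)
}

#' Grey interval forecast of an annual value
#'
#' Produces the (lower, basic, upper) forecast interval for the annual
#' observation at series index `target_index` (> n) by differencing
#' consecutive accumulated-scale bound functions:
#' \eqn{\hat x^{(0)}(k) = f(n+t) - f(n+t-1)} with
#' \eqn{t = k - n}. For the first step the difference pairs
#' \eqn{f(n+1)} with the observed \eqn{x^{(1)}(n)} (which equals
#' \eqn{f(n+0)}), so every step yields the same interval
#' \eqn{(\sigma_{min},\ (\sigma_{min}+\sigma_{max})/2,\ \sigma_{max})}:
#' the interval width is constant in the horizon, a documented
#' limitation of the method.
#'
#' @param series an [annual_series()].
#' @param target_index series index `k > n` of the year to forecast.
#' @return An object of class `interval_forecast`: list with `year`,
#'   `target_index`, `horizon` (`t = k - n`), original-scale `lower`,
#'   `basic`, `upper`, accumulated-scale `f_lower`, `f_basic`, `f_upper`
#'   at the target horizon, and `sigma_min`, `sigma_max`.
#' @examples
#' interval_forecast(metallurgy_deaths(), 20)  # year 2020: 16, 50.5, 85
#' @export
interval_forecast <- function(series, target_index) {
  if (is.numeric(series)) series <- annual_series(series, 1L)
  stopifnot(inherits(series, "annual_series"))
  n <- length(series$values)
  target_index <- as.integer(target_index)
  if (length(target_index) != 1L || is.na(target_index) || target_index <= n)
    stop("'target_index' must be a single index beyond the observed series ",
         "(> ", n, ")", call. = FALSE)
  t <- target_index - n
  at_t <- bound_functions(series, t)
  at_prev <- bound_functions(series, t - 1)
  structure(
    list(year = series$first_year + target_index - 1L,
         target_index = target_index, horizon = t,
         lower = at_t$f_lower - at_prev$f_lower,
         basic = at_t$f_basic - at_prev$f_basic,
         upper = at_t$f_upper - at_prev$f_upper,
         f_lower = at_t$f_lower, f_basic = at_t$f_basic,
         f_upper = at_t$f_upper,
         sigma_min = at_t$sigma_min, sigma_max = at_t$sigma_max),
    class = "interval_forecast"
  )
}

#' @export
print.interval_forecast <- function(x, ...) {
  cat(sprintf("Grey interval forecast for year %d (index %d, horizon %d):\n",
              x$year, x$target_index, x$horizon))
  cat(sprintf("  lower %g, basic %g, upper %g\n", x$lower, x$basic, x$upper))
  invisible(x)
}

#' @export
as.data.frame.interval_forecast <- function(x, ...) {
  data.frame(year = x$year, lower = x$lower, basic = x$basic,
             upper = x$upper)
}
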