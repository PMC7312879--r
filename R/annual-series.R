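#' Annual observation series
#'
#' An `annual_series` holds an ordered sequence of annual observations
#' \eqn{x^{(0)}(k)}, \eqn{k = 1, \dots, n}, anchored to a first calendar
#' year so that index \eqn{k} corresponds to the year
#' `first_year + k - 1`. It is the raw-data container for every grey-model
#' stage: accumulation, GM(1,1) fitting, interval prediction, and
#' catastrophe prediction.
#'
#' Values are stored as doubles even when integer-valued (death counts),
#' so all downstream least-squares fits are uniform. Grey modelling
#' assumes non-negative observations; negative values are accepted by the
#' container (some diagnostics exploit them) but rejected by [fit_gm11()].
#'
#' @param values numeric vector of finite observations, length >= 1.
#' @param first_year integer calendar year of the first observation.
#' @param label optional free-text description of the series.
#' @return An object of class `annual_series` with elements `values`,
#'   `first_year` and `label`.
#' @seealso [ago()], [fit_gm11()], [interval_forecast()],
#'   [metallurgy_deaths()] for the bundled 2001-2017 series.
#' @examples
#' s <- annual_series(c(16, 16, 19), 2001, "annual deaths")
#' series_years(s)
#' @export
annual_series <- function(values, first_year, label = "") {
  values <- as.double(values)
  if (length(values) < 1L)
    stop("'values' must contain at least one observation", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all series values must be finite", call. = FALSE)
  first_year <- as.integer(first_year)
  if (length(first_year) != 1L || is.na(first_year))
    stop("'first_year' must be a single calendar year", call. = FALSE)
  structure(
    list(values = values, first_year = first_year,
         label = as.character(label)[1L]),
    class = "annual_series"
  )
}

#' @export
length.annual_series <- function(x) length(x$values)

#' Calendar years covered by a series
#'
#' @param x an [annual_series()].
#' @return Integer vector of years, one per observation.
#' @export
series_years <- function(x) {
  stopifnot(inherits(x, "annual_series"))
  x$first_year + seq_along(x$values) - 1L
}

#' @export
print.annual_series <- function(x, ...) {
  cat("Annual series", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat(sprintf("  %d observations, %d-%d\n", length(x$values),
              x$first_year, x$first_year + length(x$values) - 1L))
  print(stats::setNames(x$values, series_years(x)))
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = series_years(x), value = x$values)
}

#' First-order accumulating generation operator (1-AGO)
#'
#' Transforms an irregular annual series into its cumulative-sum series
#' \eqn{x^{(1)}(k) = \sum_{i=1}^{k} x^{(0)}(i)}, the smoother monotone
#' series on which the GM(1,1) whitenization equation is posed.
#'
#' @param series an [annual_series()].
#' @return An object of class `accumulated_series` with the cumulative
#'   values and a reference to the source series.
#' @examples
#' ago(annual_series(c(16, 16, 19), 2001))$values  # 16 32 51
#' @export
ago <- function(series) {
  if (is.numeric(series)) series <- annual_series(series, 1L)
  stopifnot(inherits(series, "annual_series"))
  structure(
    list(values = cumsum(series$values), source = series),
    class = "accumulated_series"
  )
}

#' @export
length.accumulated_series <- function(x) length(x$values)

#' @export
print.accumulated_series <- function(x, ...) {
  cat("1-AGO series of", length(x$values), "values\n")
  print(x$values)
  invisible(x)
}

#' Inverse accumulating generation (first differencing)
#'
#' Restores the original-scale series from an accumulated one via
#' \eqn{x^{(0)}(k) = x^{(1)}(k) - x^{(1)}(k-1)} with
#' \eqn{x^{(0)}(1) = x^{(1)}(1)}. `inverse_ago(ago(s))` reproduces `s`
#' exactly.
#'
#' @param acc an `accumulated_series` as returned by [ago()], or a plain
#'   numeric vector of accumulated values.
#' @param first_year first calendar year, used only when `acc` is a bare
#'   numeric vector (defaults to 1).
#' @return An [annual_series()].
#' @export
inverse_ago <- function(acc, first_year = NULL) {
  if (inherits(acc, "accumulated_series")) {
    v <- acc$values
    if (is.null(first_year)) first_year <- acc$source$first_year
    label <- acc$source$label
  } else {
    v <- as.double(acc)
    if (length(v) < 1L)
      stop("accumulated series must be non-empty", call. = FALSE)
    if (is.null(first_year)) first_year <- 1L
    label <- ""
  }
  annual_series(c(v[1L], diff(v)), first_year, label)
}

#' Background value series
#'
#' The background values \eqn{z^{(1)}(k+1) = \frac{1}{2}[x^{(1)}(k+1) +
#' x^{(1)}(k)]} are the adjacent means of the accumulated series and act
#' as the regressor in the GM(1,1) least-squares step.
#'
#' @param acc an `accumulated_series` from [ago()] or a numeric vector of
#'   accumulated values; must have length >= 2.
#' @return An object of class `background_series` holding the `n - 1`
#'   background values (indices 2..n of the accumulated series).
#' @examples
#' background(ago(annual_series(c(16, 16, 19), 2001)))$values  # 24 41.5
#' @export
background <- function(acc) {
  v <- if (inherits(acc, "accumulated_series")) acc$values else as.double(acc)
  n <- length(v)
  if (n < 2L)
    stop("background values require at least two accumulated values",
         call. = FALSE)
  structure(list(values = (v[-1L] + v[-n]) / 2), class = "background_series")
}

#' @export
length.background_series <- function(x) length(x$values)

#' @export
print.background_series <- function(x, ...) {
  cat("Background (adjacent-mean) series of", length(x$values), "values\n")
  print(x$values)
  invisible(x)
}

#' Read or write an annual series as CSV
#'
#' The on-disk format is a two-column CSV with header `year,value`, one
#' row per observation in calendar order.
#'
#' @param path file path.
#' @param label label to attach to the series read.
#' @return `read_series_csv()` returns an [annual_series()];
#'   `write_series_csv()` invisibly returns `path`.
#' @export
read_series_csv <- function(path, label = "") {
  df <- utils::read.csv(path)
  if (!all(c("year", "value") %in% names(df)))
    stop("series CSV must have columns 'year' and 'value'", call. = FALSE)
  df <- df[order(df$year), , drop = FALSE]
  if (nrow(df) > 1L && !all(diff(df$year) == 1L))
    stop("series years must be consecutive", call. = FALSE)
  annual_series(df$value, df$year[1L], label)
}

#' @rdname read_series_csv
#' @param series an [annual_series()].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "annual_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' JSON round-trip of series objects
#'
#' Serializes an annual, accumulated or background series to JSON and
#' back. The JSON carries a `type` discriminator so `series_from_json()`
#' restores the exact class.
#'
#' @param x an `annual_series`, `accumulated_series` or
#'   `background_series`.
#' @return `series_to_json()` a JSON string; `series_from_json()` the
#'   restored object.
#' @export
series_to_json <- function(x) {
  if (inherits(x, "annual_series")) {
    obj <- list(type = "annual_series", first_year = x$first_year,
                label = x$label, values = x$values)
  } else if (inherits(x, "accumulated_series")) {
    obj <- list(type = "accumulated_series", values = x$values,
                source = jsonlite::fromJSON(series_to_json(x$source)))
  } else if (inherits(x, "background_series")) {
    obj <- list(type = "background_series", values = x$values)
  } else stop("not a series object", call. = FALSE)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' @rdname series_to_json
#' @param json a JSON string produced by `series_to_json()`.
#' @export
series_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  switch(obj$type,
    annual_series = annual_series(obj$values, obj$first_year, obj$label),
    accumulated_series = {
      src <- annual_series(obj$source$values, obj$source$first_year,
                           obj$source$label)
      acc <- ago(src)
      stopifnot(isTRUE(all.equal(acc$values, obj$values)))
      acc
    },
    background_series = structure(list(values = as.double(obj$values)),
                                  class = "background_series"),
    stop("unknown series type: ", obj$type, call. = FALSE)
  )
}
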