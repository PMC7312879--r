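#' Catastrophe (outlier-date) series
#'
#' Grey catastrophe prediction models the *dates* on which an outlier
#' event (here, a severe accident) occurred, rather than the magnitude of
#' the series. A `catastrophe_series` stores the strictly increasing
#' year indices of those events relative to a base year, so that index
#' `i` corresponds to calendar year `base_year + i`.
#'
#' @param indices strictly increasing positive integers; may be empty.
#' @param base_year calendar year mapped to index 0.
#' @param indicator optional 0/1 annual vector from which the indices
#'   were derived (kept for provenance; its 1-positions must equal
#'   `indices`).
#' @return An object of class `catastrophe_series`.
#' @seealso [extract_catastrophe_series()], [extract_from_threshold()],
#'   [predict_occurrences()], [severe_accident_dates()] for the bundled
#'   severe-accident date series.
#' @export
catastrophe_series <- function(indices, base_year, indicator = NULL) {
  indices <- as.integer(indices)
  if (any(is.na(indices)) || any(indices <= 0L))
    stop("catastrophe indices must be positive integers", call. = FALSE)
  if (length(indices) > 1L && any(diff(indices) <= 0L))
    stop("catastrophe indices must be strictly increasing", call. = FALSE)
  if (!is.null(indicator)) {
    indicator <- as.integer(indicator)
    if (!all(indicator %in% c(0L, 1L)))
      stop("'indicator' must be a 0/1 vector", call. = FALSE)
    if (!identical(which(indicator == 1L), indices))
      stop("'indicator' 1-positions do not match 'indices'", call. = FALSE)
  }
  structure(
    list(indices = indices, base_year = as.integer(base_year),
         indicator = indicator),
    class = "catastrophe_series"
  )
}

#' @export
length.catastrophe_series <- function(x) length(x$indices)

#' Calendar years of the catastrophe events
#'
#' The mapping is the exact inverse of index extraction:
#' `year = base_year + index`.
#'
#' @param x a [catastrophe_series()].
#' @return Integer vector of years.
#' @export
catastrophe_years <- function(x) {
  stopifnot(inherits(x, "catastrophe_series"))
  x$base_year + x$indices
}

#' @export
print.catastrophe_series <- function(x, ...) {
  cat("Catastrophe date series (base year", paste0(x$base_year, "):\n"))
  if (length(x$indices) == 0L) cat("  no events\n")
  else cat("  indices:", paste(x$indices, collapse = ", "),
           " years:", paste(catastrophe_years(x), collapse = ", "), "\n")
  if (isTRUE(attr(x, "too_short")))
    cat("  note: fewer than 4 events; too short for a GM(1,1) fit\n")
  invisible(x)
}

#' Extract a catastrophe date series from a 0/1 indicator
#'
#' Scans an annual 0/1 indicator (1 = an outlier event occurred that
#' year) and returns the positions of the 1s as a strictly increasing
#' date series. With fewer than 4 events the result is still returned
#' but flagged (attribute `too_short`) and a warning is raised, since a
#' GM(1,1) fit needs at least 4 dates.
#'
#' @param indicator non-empty annual 0/1 vector; entry `i` covers year
#'   `base_year + i`.
#' @param base_year calendar year mapped to index 0.
#' @return A [catastrophe_series()].
#' @examples
#' extract_catastrophe_series(severe_accident_indicator(), 2000)
#' @export
extract_catastrophe_series <- function(indicator, base_year) {
  indicator <- as.integer(indicator)
  if (length(indicator) < 1L)
    stop("'indicator' must be non-empty", call. = FALSE)
  if (!all(indicator %in% c(0L, 1L)))
    stop("'indicator' must contain only 0 and 1", call. = FALSE)
  out <- catastrophe_series(which(indicator == 1L), base_year, indicator)
  if (length(out) < 4L) {
    attr(out, "too_short") <- TRUE
    warning("fewer than 4 events: too short for a GM(1,1) fit",
            call. = FALSE)
  }
  out
}

#' Extract a catastrophe date series by thresholding an annual series
#'
#' The outlier threshold is subjective by nature; this helper marks as
#' catastrophes the years whose value reaches the threshold (`mode =
#' "upper"`, value >= threshold) or falls to it (`mode = "lower"`,
#' value <= threshold).
#'
#' @param series an [annual_series()].
#' @param threshold numeric outlier threshold.
#' @param mode `"upper"` for upper catastrophes (default) or `"lower"`.
#' @return A [catastrophe_series()] with `base_year = first_year - 1`,
#'   so index k of the series keeps its calendar year.
#' @examples
#' extract_from_threshold(metallurgy_deaths(), 76)  # 2007, 2010, 2012
#' @export
extract_from_threshold <- function(series, threshold,
                                   mode = c("upper", "lower")) {
  if (is.numeric(series)) series <- annual_series(series, 1L)
  stopifnot(inherits(series, "annual_series"))
  mode <- match.arg(mode)
  hit <- if (mode == "upper") series$values >= threshold
         else series$values <= threshold
  catastrophe_series(which(hit), series$first_year - 1L)
}

#' Predict the timing of future catastrophes
#'
#' Fits a GM(1,1) model to the catastrophe date series (the dates are the
#' data, their order the index) and extrapolates `m` steps beyond the
#' last observed event. Each predicted fractional index is mapped to
#' `base_year + index` and reported as the bracketing pair
#' `(floor(year), ceiling(year))` — a prediction of 2018.85 reads
#' "2018 or 2019". The relative-error accuracy report of the underlying
#' fit is attached; it should be inspected before trusting the timing.
#'
#' @param cat a [catastrophe_series()] with at least 4 dates.
#' @param m number of future events to predict (>= 0).
#' @return An object of class `catastrophe_prediction`: list with
#'   `predicted_indices`, `predicted_years` (fractional),
#'   `year_ranges` (m x 2 matrix of floor/ceiling years), `model` (the
#'   [fit_gm11()] object) and `accuracy` (see [relative_errors()]).
#' @examples
#' predict_occurrences(severe_accident_dates(), 2)  # 2018-2019, 2021-2022
#' @export
predict_occurrences <- function(cat, m = 1L) {
  stopifnot(inherits(cat, "catastrophe_series"))
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 0L)
    stop("'m' must be a single non-negative integer", call. = FALSE)
  if (length(cat) < 4L)
    stop("catastrophe prediction needs at least 4 event dates",
         call. = FALSE)
  dates <- annual_series(cat$indices, 1L, "catastrophe dates")
  model <- fit_gm11(dates)
  n <- length(cat)
  idx <- if (m > 0L) predict_original(model, n - 1L + seq_len(m))
         else double(0)
  yrs <- cat$base_year + idx
  structure(
    list(predicted_indices = idx, predicted_years = yrs,
         year_ranges = cbind(floor(yrs), ceiling(yrs)),
         model = model, accuracy = relative_errors(model),
         base_year = cat$base_year),
    class = "catastrophe_prediction"
  )
}

#' @export
print.catastrophe_prediction <- function(x, ...) {
  cat("Grey catastrophe prediction\n")
  print(x$model)
  if (length(x$predicted_indices) == 0L) {
    cat("  no future events requested\n")
  } else {
    for (i in seq_along(x$predicted_indices)) {
      cat(sprintf("  event %d: index %.2f -> %.2f (%d or %d)\n", i,
                  x$predicted_indices[i], x$predicted_years[i],
                  x$year_ranges[i, 1L], x$year_ranges[i, 2L]))
    }
  }
  cat(sprintf("  accuracy: mean relative error %.4f%%, %s level, usable: %s\n",
              100 * x$accuracy$mean_rel_error, x$accuracy$level,
              x$accuracy$usable))
  invisible(x)
}
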