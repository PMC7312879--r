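#' Accident type taxonomy
#'
#' The closed vocabulary of twelve accident types used to classify
#' casualty accidents for employees working in companies (the Chinese
#' national classification standard): poisoning/asphyxiation, explosions
#' of furnaces or ladles, thermal injury, and so on.
#'
#' @return Character vector of the 12 accident type names.
#' @export
accident_types <- function() {
  c("Poisoning and asphyxiation", "Other explosion", "Thermal injury",
    "Collapse", "Fall from a high place", "Object strike", "Drowning",
    "Container explosion", "Electric shock", "Mechanical injury",
    "Fire disaster", "Lifting injury")
}

#' Accident grade bands
#'
#' Production accidents are graded ordinary, major, severe or
#' extraordinarily severe on half-open bands of deaths, serious injuries
#' and direct economic loss; an accident exceeding the severe range on
#' any criterion is extraordinarily severe.
#'
#' @return A data.frame with one row per grade giving the lower bound
#'   (inclusive) of each criterion band; the upper bound is the next
#'   grade's lower bound, the last band is unbounded.
#' @export
grade_bands <- function() {
  data.frame(
    grade = grade_levels(),
    deaths_lo = c(0, 3, 10, 30),
    serious_injuries_lo = c(0, 10, 50, 100),
    direct_loss_yuan_lo = c(0, 1e7, 5e7, 1e8)
  )
}

grade_levels <- function() {
  c("ordinary", "major", "severe", "extraordinarily severe")
}

#' Classify accident grade from casualties and loss
#'
#' Applies the half-open grade bands per criterion (so 10 deaths is
#' severe and 30 deaths extraordinarily severe) and combines them by
#' maximum: any single criterion in a higher band raises the overall
#' grade. Direct economic loss is optional since it is rarely reported;
#' when `NULL` or `NA` it is ignored.
#'
#' @param deaths non-negative integer vector.
#' @param serious_injuries non-negative integer vector.
#' @param direct_loss optional non-negative loss in yuan (vector or
#'   `NULL`); `NA` entries are ignored.
#' @return An ordered factor with levels ordinary < major < severe <
#'   extraordinarily severe.
#' @examples
#' classify_grade(32, 6)   # extraordinarily severe
#' classify_grade(21, 9)   # severe
#' @export
classify_grade <- function(deaths, serious_injuries, direct_loss = NULL) {
  deaths <- as.double(deaths)
  serious_injuries <- as.double(serious_injuries)
  if (any(deaths < 0, na.rm = TRUE) ||
      any(serious_injuries < 0, na.rm = TRUE) ||
      any(direct_loss < 0, na.rm = TRUE))
    stop("casualty and loss inputs must be non-negative", call. = FALSE)
  n <- max(length(deaths), length(serious_injuries), length(direct_loss))
  band <- function(v, breaks) findInterval(v, breaks) + 1L  # 1..4
  g <- pmax(band(rep_len(deaths, n), c(3, 10, 30)),
            band(rep_len(serious_injuries, n), c(10, 50, 100)))
  if (!is.null(direct_loss)) {
    gl <- band(rep_len(as.double(direct_loss), n), c(1e7, 5e7, 1e8))
    g <- pmax(g, gl, na.rm = TRUE)
  }
  factor(grade_levels()[g], levels = grade_levels(), ordered = TRUE)
}

#' Accident record table
#'
#' Validates and classifies a table of accident records. Each record
#' carries a date, company, accident type (from the closed
#' [accident_types()] vocabulary), death and serious-injury counts, and
#' optionally the direct economic loss in yuan. A `grade` column is
#' derived with [classify_grade()].
#'
#' @param df a data.frame with columns `date` (Date or ISO-8601 text),
#'   `company`, `accident_type`, `deaths`, `serious_injuries`, and
#'   optionally `direct_loss_yuan`.
#' @return The validated data.frame with class `accident_records`, dates
#'   as `Date`, and a derived ordered-factor `grade` column.
#' @seealso [read_accident_csv()], [tally()], [annual_death_series()]
#' @export
accident_records <- function(df) {
  req <- c("date", "company", "accident_type", "deaths", "serious_injuries")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing record columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$date <- as.Date(df$date)
  if (any(is.na(df$date)))
    stop("invalid dates in record table", call. = FALSE)
  bad <- setdiff(unique(df$accident_type), accident_types())
  if (length(bad))
    stop("unknown accident types: ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$deaths <- as.integer(df$deaths)
  df$serious_injuries <- as.integer(df$serious_injuries)
  if (any(is.na(df$deaths)) || any(df$deaths < 0) ||
      any(is.na(df$serious_injuries)) || any(df$serious_injuries < 0))
    stop("deaths and serious_injuries must be non-negative integers",
         call. = FALSE)
  if (is.null(df$direct_loss_yuan))
    df$direct_loss_yuan <- rep(NA_real_, nrow(df))
  df$direct_loss_yuan <- as.double(df$direct_loss_yuan)
  df$grade <- classify_grade(df$deaths, df$serious_injuries,
                             df$direct_loss_yuan)
  class(df) <- c("accident_records", "data.frame")
  df
}

weekday_names <- function() {
  c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday", "Saturday",
    "Sunday")
}

#' Tally accidents and deaths by a dimension
#'
#' Aggregates an accident record table into per-category accident counts
#' and death sums. For the calendar dimensions (`year`, `month`,
#' `weekday`) categories with no records are included with zero counts;
#' weekdays are ordered Monday-first (the first day of the workweek).
#'
#' @param records an [accident_records()] table.
#' @param dimension one of `"year"`, `"month"`, `"weekday"`, `"type"`,
#'   `"grade"`.
#' @return A data.frame with columns `category`, `accidents`, `deaths`.
#' @export
tally <- function(records,
                  dimension = c("year", "month", "weekday", "type",
                                "grade")) {
  stopifnot(inherits(records, "accident_records"))
  if (nrow(records) == 0L)
    stop("record table is empty", call. = FALSE)
  dimension <- match.arg(dimension)
  key <- switch(dimension,
    year = as.integer(format(records$date, "%Y")),
    month = factor(month.name[as.integer(format(records$date, "%m"))],
                   levels = month.name),
    weekday = factor(weekday_names()[as.integer(format(records$date, "%u"))],
                     levels = weekday_names()),
    type = factor(records$accident_type, levels = accident_types()),
    grade = records$grade
  )
  if (dimension == "year")
    key <- factor(key, levels = seq(min(key), max(key)))
  acc <- table(key)
  dth <- tapply(records$deaths, key, sum, default = 0L)
  data.frame(category = names(acc), accidents = as.integer(acc),
             deaths = as.integer(dth), row.names = NULL)
}

#' Annual death series from accident records
#'
#' Sums deaths per calendar year over `first_year..last_year` (zeros for
#' years without records) and returns the result as an
#' [annual_series()], ready for GM(1,1) fitting or interval prediction.
#'
#' @param records an [accident_records()] table (may be empty).
#' @param first_year,last_year inclusive calendar range.
#' @return An [annual_series()] of per-year death totals.
#' @export
annual_death_series <- function(records, first_year, last_year) {
  if (last_year < first_year)
    stop("'last_year' must be >= 'first_year'", call. = FALSE)
  years <- seq(first_year, last_year)
  totals <- stats::setNames(numeric(length(years)), years)
  if (nrow(records) > 0L) {
    yr <- format(records$date, "%Y")
    keep <- yr %in% as.character(years)
    s <- tapply(records$deaths[keep], yr[keep], sum)
    totals[names(s)] <- s
  }
  annual_series(unname(totals), first_year, "annual deaths")
}

#' Read or write accident records as CSV
#'
#' The schema is `date` (ISO-8601), `company`, `accident_type`,
#' `deaths`, `serious_injuries`, `direct_loss_yuan` (blank allowed).
#' A write followed by a read restores an identical record set.
#'
#' @param path file path.
#' @return `read_accident_csv()` returns an [accident_records()] table;
#'   `write_accident_csv()` invisibly returns `path`.
#' @export
read_accident_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(company = "character"))
  accident_records(df)
}

#' @rdname read_accident_csv
#' @param records an [accident_records()] table.
#' @export
write_accident_csv <- function(records, path) {
  stopifnot(inherits(records, "accident_records"))
  out <- as.data.frame(records)
  out$grade <- NULL  # derived, recomputed on read
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
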