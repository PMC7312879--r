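#' Configuration for the synthetic accident-record generator
#'
#' Default values emulate the qualitative shape of the surveillance data
#' the package's methods target: roughly 8.4 fatal accidents per year
#' over 18 years (about 150 records), per-accident deaths mostly in the
#' major band (3-9) with a declining profile, an (approximately) even
#' chance each year of one severe (>= 10 deaths) event,
#' poisoning/asphyxiation as the modal accident type at about 40%
#' followed by furnace/ladle explosions, a September/January excess and
#' February deficit across months, and a Monday excess across weekdays.
#' These defaults are for documentation and testing of the pipeline;
#' they are not fitted to any real record set.
#'
#' @param seed integer seed; a fixed seed makes [gen_records()] output
#'   byte-identical.
#' @param n_years number of calendar years to simulate.
#' @param base_year first simulated calendar year.
#' @param annual_accident_rate mean fatal accidents per year (the yearly
#'   count is 1 + Poisson(rate - 1), so every year has at least one
#'   record and the mean equals the rate).
#' @param death_distribution named numeric weights over per-accident
#'   death counts (names are the counts); defaults cover 3..9.
#' @param severe_death_distribution named weights over death counts for
#'   severe events (>= 10).
#' @param type_weights named weights over the 12 [accident_types()].
#' @param month_weights 12 non-negative month weights.
#' @param weekday_weights 7 non-negative weights, Monday first.
#' @param severe_probability per-year probability of one severe event.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_years = 18L,
                             base_year = 2001L,
                             annual_accident_rate = 8.4,
                             death_distribution = c(
                               "3" = 0.45, "4" = 0.20, "5" = 0.12,
                               "6" = 0.08, "7" = 0.06, "8" = 0.05,
                               "9" = 0.04),
                             severe_death_distribution = c(
                               "10" = 0.25, "12" = 0.25, "13" = 0.20,
                               "17" = 0.10, "20" = 0.10, "21" = 0.05,
                               "32" = 0.05),
                             type_weights = c(
                               "Poisoning and asphyxiation" = 0.40,
                               "Other explosion" = 0.15,
                               "Thermal injury" = 0.09,
                               "Collapse" = 0.06,
                               "Fall from a high place" = 0.06,
                               "Object strike" = 0.06,
                               "Drowning" = 0.02,
                               "Container explosion" = 0.04,
                               "Electric shock" = 0.04,
                               "Mechanical injury" = 0.04,
                               "Fire disaster" = 0.02,
                               "Lifting injury" = 0.02),
                             month_weights = c(8, 5, 8, 9, 8, 8, 8, 8, 11,
                                               8, 8, 8),
                             weekday_weights = c(1.5, 1, 1.1, 1, 1, 0.9,
                                                 1.1),
                             severe_probability = 0.5) {
  check_weights <- function(w, what, len = NULL) {
    if (!is.null(len) && length(w) != len)
      stop(what, " must have length ", len, call. = FALSE)
    if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
      stop(what, " must be non-negative and normalizable", call. = FALSE)
  }
  check_weights(death_distribution, "'death_distribution'")
  check_weights(severe_death_distribution, "'severe_death_distribution'")
  if (any(as.integer(names(death_distribution)) < 3L))
    stop("fatal-accident death counts start at 3", call. = FALSE)
  if (any(as.integer(names(severe_death_distribution)) < 10L))
    stop("severe death counts start at 10", call. = FALSE)
  check_weights(type_weights, "'type_weights'", 12L)
  if (!setequal(names(type_weights), accident_types()))
    stop("'type_weights' names must be the 12 accident types",
         call. = FALSE)
  check_weights(month_weights, "'month_weights'", 12L)
  check_weights(weekday_weights, "'weekday_weights'", 7L)
  if (n_years < 1L) stop("'n_years' must be >= 1", call. = FALSE)
  if (annual_accident_rate < 1)
    stop("'annual_accident_rate' must be >= 1", call. = FALSE)
  if (severe_probability < 0 || severe_probability > 1)
    stop("'severe_probability' must be in [0, 1]", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_years = as.integer(n_years),
         base_year = as.integer(base_year),
         annual_accident_rate = annual_accident_rate,
         death_distribution = death_distribution,
         severe_death_distribution = severe_death_distribution,
         type_weights = type_weights, month_weights = month_weights,
         weekday_weights = weekday_weights,
         severe_probability = severe_probability),
    class = "generator_config"
  )
}

# run expr with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# one calendar date in `year`: month by month_weights, then a day of that
# month weighted by the weekday profile
sample_date <- function(year, month_weights, weekday_weights) {
  m <- sample.int(12L, 1L, prob = month_weights)
  first <- as.Date(sprintf("%d-%02d-01", year, m))
  days <- seq(first, by = "day",
              length.out = 31L)
  days <- days[as.integer(format(days, "%m")) == m]
  wd <- as.integer(format(days, "%u"))
  days[sample.int(length(days), 1L, prob = weekday_weights[wd])]
}

#' Generate a synthetic accident-record table
#'
#' Draws a reproducible table of fatal accident records with the
#' configured calendar, severity and type structure: yearly counts are
#' `1 + Poisson(rate - 1)` (every year records at least one fatal
#' accident), per-record deaths are drawn from the configured major-band
#' distribution (all >= 3: only fatal accidents are modelled), and with
#' probability `severe_probability` one record per year is upgraded to a
#' severe (>= 10 deaths) event. With `severe_probability = 0` no record
#' reaches 10 deaths.
#'
#' @param cfg a [generator_config()].
#' @return An [accident_records()] table, sorted by date. Identical for
#'   identical configs (the caller's RNG state is left untouched).
#' @examples
#' r <- gen_records(generator_config(seed = 42, n_years = 5))
#' tally(r, "grade")
#' @export
gen_records <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_private_seed(cfg$seed, {
    rows <- list()
    for (y in cfg$base_year + seq_len(cfg$n_years) - 1L) {
      n_y <- 1L + stats::rpois(1L, cfg$annual_accident_rate - 1)
      deaths <- as.integer(sample(names(cfg$death_distribution), n_y,
                                  replace = TRUE,
                                  prob = cfg$death_distribution))
      if (stats::runif(1L) < cfg$severe_probability) {
        up <- sample.int(n_y, 1L)
        deaths[up] <- as.integer(sample(
          names(cfg$severe_death_distribution), 1L,
          prob = cfg$severe_death_distribution))
      }
      dates <- as.Date(vapply(seq_len(n_y), function(i)
        as.character(sample_date(y, cfg$month_weights,
                                 cfg$weekday_weights)), character(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        date = dates,
        company = sprintf("Synthetic Metallurgical Co. %d-%02d", y,
                          seq_len(n_y)),
        accident_type = sample(names(cfg$type_weights), n_y,
                               replace = TRUE, prob = cfg$type_weights),
        deaths = deaths,
        serious_injuries = stats::rpois(n_y, 0.8 * deaths),
        direct_loss_yuan = NA_real_
      )
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$date), , drop = FALSE]
    rownames(out) <- NULL
    accident_records(out)
  })
}

#' Exact exponential series for parameter-recovery tests
#'
#' Builds the homogeneous series whose 1-AGO follows the grey prediction
#' form \eqn{x^{(1)}(k) = [x^{(0)}(1) - b/a] e^{-a(k-1)} + b/a}, i.e.
#' \eqn{x^{(0)}(k) = (1 - e^{a})[x^{(0)}(1) - b/a] e^{-a(k-2)} e^{a}}
#' for k >= 2 — a geometric progression with ratio \eqn{e^{-a}}.
#' Feeding the result to [fit_gm11()] recovers the closed-form discrete
#' parameters (for geometric ratio r, \eqn{\hat a = 2(1-r)/(1+r)}, which
#' approaches the continuous `a` only as \eqn{|a| \to 0}).
#'
#' @param a non-zero continuous developing coefficient.
#' @param b grey input.
#' @param x0_1 initial observation \eqn{x^{(0)}(1)}.
#' @param n series length, >= 4.
#' @param first_year calendar anchor (default 1).
#' @return An [annual_series()] of length `n`.
#' @export
gen_exponential_series <- function(a, b, x0_1, n, first_year = 1L) {
  if (a == 0) stop("'a' must be non-zero", call. = FALSE)
  n <- as.integer(n)
  if (n < 4L) stop("'n' must be >= 4", call. = FALSE)
  k <- seq_len(n)
  x1 <- (x0_1 - b / a) * exp(-a * (k - 1)) + b / a
  inverse_ago(x1, first_year)
}

#' Irregularly fluctuating positive series with fixed extremes
#'
#' Emulates the "saddle-type" year-to-year fluctuation of annual
#' accident data: a positive series oscillating irregularly between
#' configured extremes. The minimum and maximum are attained exactly (at
#' seeded random positions), so [interval_forecast()] on the result
#' returns exactly `(sigma_min, (sigma_min + sigma_max)/2, sigma_max)`.
#'
#' @param n_years series length, >= 2.
#' @param first_year calendar anchor.
#' @param sigma_min,sigma_max positive extremes, `sigma_min <=
#'   sigma_max`; equal values give a constant series.
#' @param seed integer seed; output is reproducible.
#' @return An [annual_series()].
#' @export
gen_fluctuating_series <- function(n_years = 17L, first_year = 2001L,
                                   sigma_min = 16, sigma_max = 85,
                                   seed = 1L) {
  n_years <- as.integer(n_years)
  if (n_years < 2L) stop("'n_years' must be >= 2", call. = FALSE)
  if (sigma_min <= 0 || sigma_max < sigma_min)
    stop("extremes must satisfy 0 < sigma_min <= sigma_max",
         call. = FALSE)
  with_private_seed(seed, {
    mid <- (sigma_min + sigma_max) / 2
    amp <- (sigma_max - sigma_min) / 2
    k <- seq_len(n_years)
    # two superposed waves + noise give the multi-modal "saddle" look
    v <- mid + amp * (0.6 * sin(2 * pi * k / 9) +
                      0.4 * sin(2 * pi * k / 4 + 1)) +
      stats::rnorm(n_years, 0, amp / 6)
    v <- pmin(pmax(v, sigma_min), sigma_max)
    at <- sample.int(n_years, 2L)
    v[at[1L]] <- sigma_min
    v[at[2L]] <- sigma_max
    annual_series(v, first_year, "synthetic fluctuating series")
  })
}
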