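# The two in-package data series, unwrapped for convenience
deaths_series <- metallurgy_deaths()
deaths_values <- deaths_series$values
severe_T0 <- c(4, 6, 7, 8, 10, 11, 12, 15, 16)

# random strictly positive series for property-style loops
random_positive_series <- function(n, first_year = 2001L) {
  annual_series(stats::runif(n, 1, 100), first_year)
}

# a tiny record table built in code
make_records <- function(dates, deaths,
                         types = "Poisoning and asphyxiation",
                         injuries = 0L) {
  accident_records(data.frame(
    date = as.Date(dates),
    company = sprintf("Co %d", seq_along(dates)),
    accident_type = rep_len(types, length(dates)),
    deaths = deaths,
    serious_injuries = rep_len(injuries, length(dates))
  ))
}
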