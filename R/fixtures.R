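#' Annual deaths from fatal metallurgical accidents, 2001-2017
#'
#' The worked data series of the package: annual deaths from fatal
#' (major, severe and extraordinarily severe) accidents in the Chinese
#' metallurgical industry, 2001-2017. 2018 is excluded because only a
#' half year of records was available. The series fluctuates irregularly
#' ("saddle-type"), which is why the GM(1,1) point forecast fails its
#' accuracy test on it and grey interval prediction is used instead.
#'
#' @return An [annual_series()] of 17 values anchored at 2001.
#' @examples
#' ago(metallurgy_deaths())$values[17]  # cumulative total 709
#' @export
metallurgy_deaths <- function() {
  annual_series(
    c(16, 16, 19, 52, 47, 53, 85, 47, 35, 76, 45, 81, 47, 20, 24, 19, 27),
    2001, "annual deaths, fatal metallurgical accidents, China"
  )
}

#' Severe-accident occurrence indicator, 2001-2016
#'
#' Annual 0/1 indicator of whether at least one severe accident
#' (10-29 deaths) occurred in the Chinese metallurgical industry; entry
#' i covers year 2000 + i. Note this indicator spans 16 years while the
#' death series spans 17 — the two fixtures end in different years in
#' the source records and are kept as reported.
#'
#' @return Integer 0/1 vector of length 16.
#' @export
severe_accident_indicator <- function() {
  c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 0L, 0L, 1L, 1L)
}

#' Severe-accident date series
#'
#' The catastrophe date series derived from
#' [severe_accident_indicator()]: the year indices (base year 2000) in
#' which a severe accident occurred, i.e. (4, 6, 7, 8, 10, 11, 12, 15,
#' 16) for 2004, 2006, 2007, 2008, 2010, 2011, 2012, 2015, 2016. Years
#' with two severe accidents (2007, 2012) appear once, since the date
#' series must be strictly increasing.
#'
#' @return A [catastrophe_series()] with base year 2000.
#' @examples
#' predict_occurrences(severe_accident_dates(), 2)
#' @export
severe_accident_dates <- function() {
  catastrophe_series(c(4L, 6L, 7L, 8L, 10L, 11L, 12L, 15L, 16L), 2000L,
                     severe_accident_indicator())
}

#' Severe and extraordinarily severe accident records, 2001-2018
#'
#' The eleven reported severe and extraordinarily severe accidents in
#' the Chinese metallurgical industry between 2001 and 2018 (one
#' extraordinarily severe, ten severe; 175 deaths in total), shipped as
#' a plain-text CSV fixture. The "Significant fall" type of the source
#' table is recorded under the taxonomy name "Fall from a high place".
#'
#' @return An [accident_records()] table of 11 records.
#' @export
severe_accident_records <- function() {
  read_accident_csv(system.file("extdata", "severe_accidents.csv",
                                package = "greyrisk", mustWork = TRUE))
}

#' Bow tie for fatal accidents in metallurgical enterprises
#'
#' The packaged worked example of a qualitative bow tie: the top event
#' "fatal accident in a metallurgical enterprise" with four causes
#' (insufficient safety training, lack of inspection in fieldwork,
#' incomplete safe operation guidelines, lack of accident prevention
#' measures), three consequences (casualties, equipment trouble,
#' environmental pollution), four preventive barriers (one per cause)
#' and ten mitigative barriers. The source diagram does not enumerate
#' the ten mitigative measures by name, so their labels here are
#' reconstructed plausible measures with the correct count, as flagged
#' in the file's `notes` field.
#'
#' @return A [bowtie()] object, loaded from the packaged JSON fixture.
#' @examples
#' validate_bowtie(metallurgy_bowtie())  # character(0): valid
#' @export
metallurgy_bowtie <- function() {
  bowtie_from_json(system.file("extdata", "bowtie_fatal_accidents.json",
                               package = "greyrisk", mustWork = TRUE))
}
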