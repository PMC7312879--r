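test_that("grade classification matches the banded criteria", {
  expect_identical(as.character(classify_grade(32, 6)),
                   "extraordinarily severe")
  expect_identical(as.character(classify_grade(21, 9)), "severe")
  expect_identical(as.character(classify_grade(0, 0, 0)), "ordinary")
  # half-open boundaries: 10 deaths is severe, 30 extraordinarily severe
  expect_identical(as.character(classify_grade(c(3, 10, 30), 0)),
                   c("major", "severe", "extraordinarily severe"))
  # any criterion suffices: injuries alone can raise the grade
  expect_identical(as.character(classify_grade(0, 55)), "severe")
  expect_identical(as.character(classify_grade(2, 1, 6e7)), "severe")
  expect_error(classify_grade(-1, 0), "non-negative")
})

test_that("grade classification is monotone in every criterion", {
  set.seed(13)
  for (i in 1:50) {
    d <- sample(0:40, 1); inj <- sample(0:120, 1)
    g <- as.integer(classify_grade(d, inj))
    expect_gte(as.integer(classify_grade(d + sample(0:10, 1), inj)), g)
    expect_gte(as.integer(classify_grade(d, inj + sample(0:30, 1))), g)
    expect_gte(as.integer(classify_grade(d, inj, 2e8)), g)
  }
})

test_that("tallies count records and conserve totals", {
  rec <- make_records(c("2021-09-06", "2021-09-08"), c(3, 5))  # Mon, Wed
  wt <- tally(rec, "weekday")
  expect_identical(wt$category, c("Monday", "Tuesday", "Wednesday",
                                  "Thursday", "Friday", "Saturday",
                                  "Sunday"))
  expect_identical(wt$accidents, c(1L, 0L, 1L, 0L, 0L, 0L, 0L))
  mt <- tally(rec, "month")
  expect_identical(mt$accidents[9], 2L)
  expect_identical(mt$deaths[9], 8L)

  rec <- gen_records(generator_config(seed = 9, n_years = 3,
                                      annual_accident_rate = 7))
  for (dim in c("year", "month", "weekday", "type", "grade")) {
    tb <- tally(rec, dim)
    expect_identical(sum(tb$accidents), nrow(rec))
    expect_identical(sum(tb$deaths), sum(rec$deaths))
  }
  # brute-force filter-and-count oracle on the type dimension
  tb <- tally(rec, "type")
  for (i in seq_len(nrow(tb))) {
    sel <- rec$accident_type == tb$category[i]
    expect_identical(tb$accidents[i], sum(sel))
    expect_identical(tb$deaths[i], sum(rec$deaths[sel]))
  }
  expect_error(tally(rec, "shift"), "arg")
})

test_that("annual death series aggregates records with zero fill", {
  empty <- make_records(character(0), integer(0))
  s <- annual_death_series(empty, 2001, 2005)
  expect_equal(s$values, rep(0, 5))

  rec <- make_records(c("2001-03-01", "2001-07-09", "2002-05-04",
                        "2003-11-11"), c(6, 10, 16, 19))
  s <- annual_death_series(rec, 2001, 2003)
  expect_equal(s$values, c(16, 16, 19))
  expect_identical(s$first_year, 2001L)

  rec <- gen_records(generator_config(seed = 4, n_years = 6))
  s <- annual_death_series(rec, 2001, 2006)
  expect_equal(sum(s$values), sum(rec$deaths))
})

test_that("record tables survive a CSV round trip", {
  rec <- gen_records(generator_config(seed = 2, n_years = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_accident_csv(rec, path)
  back <- read_accident_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("the bundled severe-accident table matches its published
           summary", {
  rec <- severe_accident_records()
  expect_identical(nrow(rec), 11L)
  expect_identical(sum(rec$deaths), 175L)
  gr <- tally(rec, "grade")
  expect_identical(gr$accidents[gr$category == "severe"], 10L)
  expect_identical(
    gr$accidents[gr$category == "extraordinarily severe"], 1L)
})

test_that("record validation rejects malformed tables", {
  expect_error(accident_records(data.frame(date = "2020-01-01")),
               "missing record columns")
  expect_error(make_records("2020-01-01", 3, types = "Meteor strike"),
               "unknown accident types")
  expect_error(make_records("2020-01-01", -2), "non-negative")
})
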