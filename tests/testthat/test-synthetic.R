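test_that("record generation is deterministic in the seed and leaves the
           caller's RNG state untouched", {
  cfg <- generator_config(seed = 31, n_years = 4)
  set.seed(999)
  before <- .Random.seed
  r1 <- gen_records(cfg)
  expect_identical(.Random.seed, before)
  r2 <- gen_records(cfg)
  expect_identical(r1, r2)
  r3 <- gen_records(generator_config(seed = 32, n_years = 4))
  expect_false(identical(r1, r3))
})

test_that("generated records honour the severity configuration", {
  none <- gen_records(generator_config(seed = 8, n_years = 10,
                                       severe_probability = 0))
  expect_true(all(none$deaths < 10))
  expect_true(all(none$deaths >= 3))  # fatal accidents only
  always <- gen_records(generator_config(seed = 8, n_years = 10,
                                         severe_probability = 1))
  per_year <- tally(always, "year")
  expect_identical(per_year$accidents > 0, rep(TRUE, 10))
  sev <- tapply(always$deaths >= 10, format(always$date, "%Y"), sum)
  expect_true(all(sev == 1))
})

test_that("empirical type frequencies track the configured weights", {
  cfg <- generator_config(seed = 77, n_years = 60,
                          annual_accident_rate = 40)
  rec <- gen_records(cfg)
  n <- nrow(rec)
  expect_gt(n, 2000)
  p <- cfg$type_weights / sum(cfg$type_weights)
  obs <- table(factor(rec$accident_type, levels = names(p))) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(as.numeric(obs) - p) <= 3.5 * se + 1e-9))
})

test_that("exponential series generation matches the geometric
           construction and boundary conditions", {
  s <- gen_exponential_series(a = -log(2), b = -2 * (-log(2)), x0_1 = 2,
                              n = 4)
  expect_equal(s$values, c(2, 4, 8, 16), tolerance = 1e-12)
  expect_error(gen_exponential_series(0, 1, 1, 6), "non-zero")
  expect_error(gen_exponential_series(0.1, 1, 1, 3), ">= 4")
  expect_silent(gen_exponential_series(0.1, 1, 1, 4))
  # the refit recovers the discrete closed form exactly; the gap to the
  # generating (continuous) coefficient is the a^3-order discretization
  # bias of the adjacent-mean background
  for (a in c(-0.05, -0.01, 0.01, 0.05)) {
    s <- gen_exponential_series(a, b = 3, x0_1 = 6, n = 10)
    m <- fit_gm11(s)
    r <- exp(-a)
    a_d <- 2 * (1 - r) / (1 + r)
    expect_equal(m$a, a_d, tolerance = 1e-9)
    expect_equal(m$restore_coeff, (1 - exp(a_d)) * (6 - 3 / a),
                 tolerance = 1e-9)
    gen_coeff <- (1 - exp(a)) * (6 - 3 / a)
    expect_lt(abs(m$restore_coeff - gen_coeff),
              abs(a)^3 * abs(6 - 3 / a))
  }
  # with |a| small and a moderate asymptote the bias is below 1e-6
  a <- 0.005
  s <- gen_exponential_series(a, b = 8 * a, x0_1 = 6, n = 10)
  m <- fit_gm11(s)
  expect_lt(abs(m$restore_coeff - (1 - exp(a)) * (6 - 8)), 1e-6)
})

test_that("fluctuating series hit their configured extremes exactly, so
           the interval forecast returns them", {
  s <- gen_fluctuating_series(17, 2001, 16, 85, seed = 5)
  expect_identical(min(s$values), 16)
  expect_identical(max(s$values), 85)
  fc <- interval_forecast(s, 20)
  expect_equal(c(fc$lower, fc$basic, fc$upper), c(16, 50.5, 85))
  const <- gen_fluctuating_series(6, 2001, 9, 9, seed = 1)
  expect_equal(const$values, rep(9, 6))
  expect_identical(gen_fluctuating_series(10, 2001, 5, 50, seed = 3),
                   gen_fluctuating_series(10, 2001, 5, 50, seed = 3))
})

test_that("the full synthetic pipeline runs end to end and conserves
           deaths", {
  for (seed in 1:50) {
    cfg <- generator_config(seed = seed, n_years = 8,
                            annual_accident_rate = 5)
    rec <- gen_records(cfg)
    s <- annual_death_series(rec, cfg$base_year, cfg$base_year + 7)
    expect_equal(sum(s$values), sum(rec$deaths))
    acc <- relative_errors(fit_gm11(s))
    expect_true(is.finite(acc$mean_rel_error))
  }
})

test_that("generator configuration validates weights", {
  expect_error(generator_config(month_weights = rep(1, 11)), "length 12")
  expect_error(generator_config(type_weights = c(a = 1)), "length 12")
  expect_error(generator_config(weekday_weights = c(-1, rep(1, 6))),
               "non-negative")
  expect_error(generator_config(severe_probability = 2), "0, 1")
})
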