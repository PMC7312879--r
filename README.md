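# greyrisk

Grey-system forecasting and risk analysis of fatal industrial accidents.

Occupational-safety surveillance series are short and irregular: one or
two decades of annual death counts that swing between extremes, plus
rare severe mass-casualty events. Trend regression on such data is close
to useless, and that is precisely the regime grey system theory targets.
`greyrisk` is for safety researchers and surveillance analysts working
with this kind of data. It provides:

* **GM(1,1) grey modelling** — first-order accumulating generation
  (1-AGO), adjacent-mean background values, least-squares estimation of
  the developing coefficient *a* and grey input *b* from
  x⁽⁰⁾(k) = −a·z⁽¹⁾(k) + b, the restored exponential prediction
  x̂⁽⁰⁾(k+1) = (1−eᵃ)[x⁽⁰⁾(1) − b/a]e⁻ᵃᵏ, and the relative-error
  accuracy test (Δₖ graded at 0.01/0.05/0.10/0.20).
* **Grey interval prediction** — bounding the accumulated series by
  lines of slope σmax/σmin through its last point, then differencing
  back to per-year forecast intervals, for series too irregular for any
  point forecast.
* **Grey catastrophe prediction** — fitting GM(1,1) to the *dates* on
  which an outlier (severe accident) occurred, to predict the timing of
  the next occurrences.
* Linear and quadratic **regression baselines** with the multiple
  correlation coefficient R, accident **grade classification** and
  descriptive tallies, a qualitative **bow-tie** risk structure with
  JSON/DOT export, and a seeded **synthetic record generator**.

The bundled worked data are the fatal-accident statistics of the Chinese
metallurgical industry: annual deaths 2001–2017 and the severe-accident
(10+ deaths) occurrence record 2001–2016.

## Worked example

```r
library(greyrisk)

# A point forecast of annual deaths fails the accuracy test...
m <- fit_gm11(metallurgy_deaths())
m
#> GM(1,1) grey model
#>   developing coefficient a = 0.0104, grey input b = 47.2142
#>   restored prediction: x^(0)(k+1) = 47.2933e^{-0.0104t}
relative_errors(m)$level
#> [1] "fail"           # mean relative error 55.7%: unusable
```

The fitted exponential is a slowly decaying ~47 deaths/year, but the
observed series swings between 16 and 85, so several steps miss by more
than 100% — the model is formally rejected. The interval method brackets
instead of pointing:

```r
interval_forecast(metallurgy_deaths(), 20)
#> Grey interval forecast for year 2020 (index 20, horizon 3):
#>   lower 16, basic 50.5, upper 85
```

i.e. 2020 deaths are bracketed by the historical extremes, with a basic
(midpoint) value of 50.5. Timing of the next severe accidents comes from
the catastrophe model on the severe-accident date series (4, 6, 7, 8,
10, 11, 12, 15, 16; base year 2000):

```r
predict_occurrences(severe_accident_dates(), 2)
#> Grey catastrophe prediction
#> GM(1,1) grey model
#>   developing coefficient a = -0.1385, grey input b = 5.2478
#>   restored prediction: x^(0)(k+1) = 5.4180e^{0.1385t}
#>   event 1: index 18.85 -> 2018.85 (2018 or 2019)
#>   event 2: index 21.65 -> 2021.65 (2021 or 2022)
#>   accuracy: mean relative error 3.3349%, second level, usable: TRUE
```

This model *passes* the accuracy test (mean Δ = 3.3%, second level), so
its timing forecast — a severe accident expected in 2018/2019 and again
in 2021/2022 — is usable in the grey-theoretic sense.

A thin command-line front end over the same functions is installed at
`exec/greyrisk.R` (subcommands `gm11`, `interval`, `catastrophe`,
`baseline`, `describe`, `bowtie`, `simulate`).

See `vignettes/grey-accident-forecasting.Rmd` for the model details,
design choices and limitations.

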