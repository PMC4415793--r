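test_that("cohort generator is consistent with its generating model", {
  ph <- ref_phenology()
  n <- 1e5
  coh <- generate_cohort(ph, 25, n = c(egg = n, larva = 2, pupa = 2,
                                       adult = 2), seed = 10)
  egg <- coh$records[coh$records$stage == "egg", ]
  # mortality within one percentage point of the Wang value
  m_true <- eval_mortality(ph$mortality$egg, 25)
  expect_lt(abs(mean(egg$outcome == "died") - m_true), 0.01)
  # empirical day-grid CDF within Kolmogorov distance 0.01 of the logit law
  comp <- egg$event_day[egg$outcome == "completed"]
  days <- 1:30
  emp <- vapply(days, function(d) mean(comp <= d), 1)
  thr <- eval_dev_time_cdf(ph$dev_time$egg, 25, days)
  expect_lt(max(abs(emp - thr)), 0.01)
  # interpolated median within 1% of the model median 3.60 d
  lo <- max(days[emp < 0.5]); hi <- lo + 1
  flo <- mean(comp <= lo); fhi <- mean(comp <= hi)
  med <- lo + (0.5 - flo) / (fhi - flo)
  expect_lt(abs(med - 3.60) / 3.60, 0.01)
})

test_that("cohort generator is deterministic under its seed", {
  ph <- ref_phenology()
  a <- generate_cohort(ph, c(20, 25), n = c(egg = 50, larva = 30, pupa = 20,
                                            adult = 10), seed = 42)
  b <- generate_cohort(ph, c(20, 25), n = c(egg = 50, larva = 30, pupa = 20,
                                            adult = 10), seed = 42)
  expect_identical(a$records, b$records)
  expect_identical(a$eggs, b$eggs)
  expect_equal(attr(a, "seed"), 42)
  expect_error(generate_cohort(ph, 23, seed = 1), "available")
})

test_that("egg schedules respect totals and overdispersion settings", {
  ph <- ref_phenology()
  coh <- generate_cohort(ph, 25, n = c(egg = 2, larva = 2, pupa = 2,
                                       adult = 40), seed = 3)
  tot <- tapply(coh$eggs$eggs, coh$eggs$female_id, sum)
  fT <- eval_total_fecundity(ph$fecundity, 25)
  # Poisson totals: mean within 5 relative SE of f(T)
  expect_lt(abs(mean(tot) - fT), 5 * sqrt(fT / length(tot)) + 1e-9)
  expect_true(all(coh$eggs$eggs >= 0))
  expect_true(all(coh$eggs$age_day >= 1))
})

test_that("weather generator produces the configured annual structure", {
  flat <- generate_weather(year_mean = 25, amplitude = 0, diurnal_range = 10,
                          noise_sd = 0, seed = 1)
  expect_equal(unique(flat$tmax), 30)
  expect_equal(unique(flat$tmin), 20)
  w <- generate_weather(year_mean = 25, amplitude = 8, diurnal_range = 10,
                        noise_sd = 0, seed = 1)
  expect_equal(diff(range(w$tmax)), 16, tolerance = 0.05)
  expect_true(all(w$tmin <= w$tmax))
  expect_identical(generate_weather(seed = 7), generate_weather(seed = 7))
})

test_that("climate raster generator honours gradient and determinism", {
  flat <- generate_climate_raster(3, 3, south_north_gradient = 0, seed = 2)
  expect_equal(length(unique(as.vector(flat$tmax[, , 6]))), 1L)
  grad <- generate_climate_raster(2, 2, south_north_gradient = 5, seed = 2)
  expect_equal(grad$tmax[2, 1, 1] - grad$tmax[1, 1, 1], 5)
  expect_identical(generate_climate_raster(2, 2, seed = 9),
                   generate_climate_raster(2, 2, seed = 9))
  withb <- generate_climate_raster(2, 2, nodata_border = TRUE, seed = 2)
  expect_equal(dim(withb$tmin), c(4, 4, 12))
  expect_true(all(is.na(withb$tmin[1, , ])))
  expect_false(anyNA(withb$tmin[2:3, 2:3, ]))
})

test_that("fitters tolerate whole-day discretization of development times", {
  ph <- ref_phenology()
  coh <- generate_cohort(ph, c(15, 20, 25, 30), n = c(egg = 400, larva = 2,
                                                      pupa = 2, adult = 2),
                         seed = 17)
  fit <- fit_dev_time_distribution(coh$records[coh$records$stage == "egg", ],
                                   "egg")
  expect_lt(abs(fit$slope - 10.51) / 10.51, 0.15)
  for (tc in c(15, 25))
    expect_lt(abs(median_dev_time(fit, tc) -
                  median_dev_time(ph$dev_time$egg, tc)) /
              median_dev_time(ph$dev_time$egg, tc), 0.05)
})
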