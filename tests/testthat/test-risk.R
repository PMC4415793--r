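test_that("establishment risk index is a product of survivable fractions", {
  expect_equal(establishment_risk_index(0, 0, 0), 1)
  expect_equal(establishment_risk_index(1, 0.3, 0.9), 0)
  expect_equal(establishment_risk_index(0.5, 0.5, 0.5), 0.125)
  # monotone nonincreasing in each argument
  expect_lte(establishment_risk_index(0.6, 0.2, 0.1),
             establishment_risk_index(0.5, 0.2, 0.1))
  expect_error(establishment_risk_index(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("generation index averages annualized generation counts", {
  expect_equal(generation_index(rep(36.5, 365)), 10)
  expect_equal(generation_index(rep(365, 365)), 1)
  # half the days at 10 generations/yr, half at 5 (364-day even split)
  expect_equal(generation_index(rep(c(36.5, 73), each = 182)), 7.5)
  expect_error(generation_index(c(rep(30, 364), -1)), "positive")
})

test_that("activity index is a log-scale sum, additive over sub-periods", {
  expect_equal(activity_index(rep(1, 365)), 0)
  expect_equal(activity_index(rep(10, 365)), 365)
  expect_equal(activity_index(rep(exp(0.1), 365)), 365 * 0.1 / log(10),
               tolerance = 1e-9)
  lam <- exp(runif(365, -0.05, 0.2))
  expect_equal(activity_index(lam),
               activity_index(lam[1:182]) + activity_index(lam[183:365]),
               tolerance = 1e-9)
  expect_error(activity_index(c(rep(1.1, 364), 0)), "positive")
})

test_that("location risk combines survivability flags and responses", {
  ph <- ref_phenology()
  responses <- list(rm = const_response(0.18, "rm"),
                    T = const_response(36.5, "T"))
  # a benign constant year: every stage survivable, constant responses
  s <- temperature_series(1:365, rep(24, 365), rep(28, 365))
  lr <- location_risk(ph, responses, s)
  expect_equal(lr$ERI, 1)
  expect_equal(lr$GI, 10)
  expect_equal(lr$AI, 365 * 0.18 / log(10), tolerance = 1e-9)
  # negative rm response gives a nonpositive activity index
  cold <- list(rm = const_response(-0.05, "rm"), T = const_response(80, "T"))
  lr2 <- location_risk(ph, cold, s)
  expect_lte(lr2$AI, 0)
  # lethal days are counted per stage: a 100-day block at 45 C mean, where
  # every Wang curve exceeds 0.99, then a benign remainder (the block's
  # last day blends into the following cool day via the half-day rule)
  hot <- temperature_series(1:365, c(rep(43, 100), rep(22, 265)),
                            c(rep(47, 100), rep(26, 265)))
  lr3 <- location_risk(ph, responses, hot)
  for (s in c("egg", "larva", "pupa")) {
    n_lethal <- sum(lr3$detail[[paste0("nonsurv_", s)]])
    expect_gte(n_lethal, 99)
    expect_lte(n_lethal, 100)
  }
  expect_equal(lr3$ERI, (1 - 100 / 365)^3, tolerance = 0.02)
})

test_that("grid risk equals the single-location result on a uniform grid", {
  ph <- ref_phenology()
  responses <- list(rm = const_response(0.1, "rm"),
                    T = const_response(40, "T"))
  cs <- generate_climate_raster(2, 2, south_north_gradient = 0, seed = 5)
  g <- grid_risk(cs, ph, responses)
  loc <- location_risk(ph, responses,
                       monthly_to_daily(data.frame(tmin = cs$tmin[1, 1, ],
                                                   tmax = cs$tmax[1, 1, ])))
  expect_equal(unique(as.vector(g$layers$ERI)), loc$ERI)
  expect_equal(unique(as.vector(g$layers$GI)), loc$GI)
  expect_equal(unique(as.vector(g$layers$AI)), loc$AI)
  # deterministic: identical inputs give identical layers
  g2 <- grid_risk(cs, ph, responses)
  expect_identical(g$layers, g2$layers)
})

test_that("ERI does not decrease along a cold-to-warm gradient", {
  ph <- ref_phenology()
  responses <- list(rm = const_response(0.1, "rm"),
                    T = const_response(40, "T"))
  # north rows cold enough for lethal winter days, south rows mild
  cs <- generate_climate_raster(4, 1, south_north_gradient = 18,
                                base_mean = 12, seed = 6)
  g <- grid_risk(cs, ph, responses)
  expect_true(all(diff(g$layers$ERI[, 1]) >= -1e-12))
})

test_that("change maps subtract layers and propagate nodata", {
  base <- risk_grid(list(ERI = matrix(c(0.5, 0.4, NA, 0.2), 2)),
                    list(xll = 0, yll = 0, cellsize = 1))
  fut <- risk_grid(list(ERI = matrix(c(0.6, 0.4, 0.3, NA), 2)),
                   list(xll = 0, yll = 0, cellsize = 1))
  ch <- change_map(base, fut)
  expect_equal(ch$layers$ERI_change[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(ch$layers$ERI_change[2, 1], 0)
  expect_true(is.na(ch$layers$ERI_change[1, 2]))
  expect_true(is.na(ch$layers$ERI_change[2, 2]))
  # identical grids give zero change
  z <- change_map(base, base)
  expect_true(all(z$layers$ERI_change == 0, na.rm = TRUE))
  other <- risk_grid(list(ERI = matrix(0, 3, 3)), list(xll = 0, yll = 0))
  expect_error(change_map(base, other), "geometry")
})

test_that("masking keeps exactly the covered cells", {
  g <- risk_grid(list(AI = matrix(as.numeric(1:12), 3, 4)),
                 list(xll = 0, yll = 0, cellsize = 1))
  full <- apply_mask(g, matrix(1, 3, 4))
  expect_identical(full$layers$AI, g$layers$AI)
  half <- matrix(0, 3, 4); half[, 1:2] <- 1
  hm <- apply_mask(g, half)
  expect_equal(sum(!is.na(hm$layers$AI)), 6)
  expect_identical(hm$layers$AI[, 1:2], g$layers$AI[, 1:2])
  expect_warning(empty <- apply_mask(g, matrix(0, 3, 4)), "no cells")
  expect_true(all(is.na(empty$layers$AI)))
})

test_that("ASCII grids round-trip bit-exactly including nodata", {
  m <- matrix(runif(20) * 37, 4, 5)
  m[2, 3] <- NA
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(m, p, list(xll = 70.25, yll = 8.5, cellsize = 0.5))
  back <- read_ascii_grid(p)
  expect_identical(back$data, m)
  expect_equal(back$geometry$xll, 70.25)
  expect_equal(back$geometry$cellsize, 0.5)
  # climate stack round trip
  cs <- generate_climate_raster(3, 2, south_north_gradient = 4, seed = 8)
  d <- tempfile(); write_climate_stack(cs, d)
  cs2 <- read_climate_stack(d)
  expect_identical(cs2$tmin, cs$tmin)
  expect_identical(cs2$tmax, cs$tmax)
})
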