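test_that("life-table parameters satisfy the demographic identities", {
  # point schedule: all reproduction at exactly one age has a closed form
  sched <- data.frame(age = c(10, 21.8, 30), lx = 1,
                      mx = c(0, 50.6, 0))
  p <- life_table_parameters(sched)
  expect_equal(p$Ro, 50.6)
  expect_equal(p$rm, log(50.6) / 21.8, tolerance = 1e-6)
  expect_equal(p$lambda, exp(p$rm), tolerance = 1e-10)
  expect_equal(p$Dt, log(2) / p$rm, tolerance = 1e-10)
  expect_equal(p$T, log(p$Ro) / p$rm, tolerance = 1e-10)
  # the printed summary values at the most favourable temperature
  expect_equal(exp(0.18), 1.2, tolerance = 0.005)
  expect_equal(log(2) / 0.18, 3.85, tolerance = 0.001)
})

test_that("a schedule without reproduction is flagged, not an error", {
  sched <- data.frame(age = 1:10, lx = seq(1, 0.1, length.out = 10), mx = 0)
  p <- life_table_parameters(sched)
  expect_equal(p$Ro, 0)
  expect_equal(p$GRR, 0)
  expect_true(is.na(p$rm))
  expect_true("no_reproduction" %in% attr(p, "flags"))
})

test_that("cohort counts are conserved without mortality or reproduction", {
  ph <- toy_phenology()
  ph$mortality <- lapply(ph$mortality, function(m) {
    m$H <- 0; m
  })
  ph$fecundity <- fecundity_model("exp_quadratic", -50, 0, 0)  # ~no eggs
  set.seed(1)
  pop <- init_population(200, ph)
  # before any adult can senesce (immature stages sum to ~16 d at 25 C)
  for (d in 1:10) pop <- step_cohorts(pop, ph, 25)$population
  expect_equal(sum(pop$alive), 200)
})

test_that("physiological age accumulates exactly by rate summation", {
  ph <- toy_phenology()
  r <- eval_development_rate(ph$dev_rate$egg, 25)
  set.seed(2)
  pop <- init_population(5, ph)
  pop$theta[] <- 1e9   # suppress transitions
  ph0 <- ph
  ph0$mortality$egg$H <- 0
  # constant temperature given as 96 identical sub-steps equals the scalar
  for (d in 1:7) pop <- step_cohorts(pop, ph0, rep(25, 96))$population
  expect_equal(pop$phys, rep(7 * r, 5), tolerance = 1e-12)
  # zero development rate leaves physiological age unchanged
  popz <- init_population(3, ph)
  phz <- ph
  phz$dev_rate$egg <- dev_rate_model("egg", 1e-8, 290, 2e4, 8e4, 300)
  before <- popz$phys
  popz <- step_cohorts(popz, phz, -40)$population
  expect_lt(max(abs(popz$phys - before)), 1e-6)
})

test_that("half the cohort has moulted by just past the median time", {
  ph <- ref_phenology()
  set.seed(3)
  pop <- init_population(4000, ph)
  # egg median at 25 C is 3.60 days: by the end of day 4 at least half of
  # the survivors should have left the egg stage
  for (d in 1:4) pop <- step_cohorts(pop, ph, 25)$population
  alive <- which(pop$alive)
  expect_gt(mean(pop$stage[alive] > 1L), 0.5)
})

test_that("simulation is reproducible and obeys Ro <= GRR", {
  ph <- toy_phenology()
  a <- simulate_life_table(ph, 25, n_eggs = 80, reps = 2, seed = 123)
  b <- simulate_life_table(ph, 25, n_eggs = 80, reps = 2, seed = 123)
  expect_identical(a$per_rep, b$per_rep)
  expect_equal(a$seed, 123)
  expect_true(all(a$per_rep$Ro <= a$per_rep$GRR + 1e-9))
  ok <- is.finite(a$per_rep$rm)
  expect_equal(a$per_rep$lambda[ok], exp(a$per_rep$rm[ok]), tolerance = 1e-6)
  expect_equal(a$per_rep$Dt[ok], log(2) / a$per_rep$rm[ok], tolerance = 1e-6)
})

test_that("stochastic means agree with the deterministic oracle", {
  # two phenologies x two temperatures, 3-SE agreement on Ro and rm
  for (ph in list(toy_phenology(), toy_phenology(H_scale = 2, fec_a = 3))) {
    for (tc in c(24, 28)) {
      det <- attr(deterministic_life_table(ph, tc), "parameters")
      sim <- simulate_life_table(ph, tc, n_eggs = 400, reps = 30,
                                 seed = round(tc * 7))
      s <- sim$summary
      for (v in c("Ro", "rm")) {
        se <- s$sd[s$parameter == v] / sqrt(sim$n_reps)
        expect_lt(abs(s$mean[s$parameter == v] - det[[v]]), 3 * se + 1e-9)
      }
    }
  }
})

test_that("deterministic oracle: full survival and fecundity linearity", {
  ph <- toy_phenology()
  ph0 <- ph
  ph0$mortality <- lapply(ph0$mortality, function(m) { m$H <- 0; m })
  sched <- deterministic_life_table(ph0, 25)
  # with no immature mortality, lx stays 1 until adult death begins
  first_drop <- min(which(sched$lx < 1 - 1e-9))
  adult_entry <- sum(1 / vapply(c("egg", "larva", "pupa"), function(s)
    eval_development_rate(ph0$dev_rate[[s]], 25), 1))
  expect_gt(first_drop, 0.5 * adult_entry)
  # doubling fecundity doubles Ro and GRR exactly and raises rm
  ph2 <- ph
  ph2$fecundity$a <- ph$fecundity$a + log(2)
  p1 <- attr(deterministic_life_table(ph, 25), "parameters")
  p2 <- attr(deterministic_life_table(ph2, 25), "parameters")
  expect_equal(p2$Ro, 2 * p1$Ro, tolerance = 1e-8)
  expect_equal(p2$GRR, 2 * p1$GRR, tolerance = 1e-8)
  expect_gt(p2$rm, p1$rm)
})

test_that("doubling all mortality intensities never increases Ro", {
  ph <- toy_phenology()
  ph2 <- toy_phenology(H_scale = 2)
  for (tc in c(22, 26, 30)) {
    r1 <- attr(deterministic_life_table(ph, tc), "parameters")$Ro
    r2 <- attr(deterministic_life_table(ph2, tc), "parameters")$Ro
    expect_lte(r2, r1 + 1e-12)
  }
})

test_that("quadratic parameter responses recover exact inputs and warn on extrapolation", {
  tab <- data.frame(temperature = c(20, 25, 30, 35),
                    value = 2 - 0.1 * c(20, 25, 30, 35) +
                      0.002 * c(20, 25, 30, 35)^2)
  pr <- fit_parameter_response(tab, "rm")
  expect_equal(pr$a, 2, tolerance = 1e-8)
  expect_equal(pr$b, -0.1, tolerance = 1e-9)
  expect_equal(pr$c, 0.002, tolerance = 1e-10)
  expect_equal(pr$range, c(20, 35))
  expect_warning(eval_parameter_response(pr, 40), "extrapolation")
  expect_error(eval_parameter_response(pr, 40, clip = FALSE), "outside")
  # symmetric values put the vertex at the centre
  sym <- data.frame(temperature = c(25, 27.5, 30), value = c(1, 2, 1))
  pv <- fit_parameter_response(sym, "rm")
  expect_equal(-pv$b / (2 * pv$c), 27.5, tolerance = 1e-8)
  expect_error(fit_parameter_response(tab[1:2, ], "rm"), ">= 3")
})

test_that("validation reports signed differences against observations", {
  pred <- data.frame(parameter = c("egg_days", "Ro"), value = c(2.87, 76.72))
  obs <- data.frame(parameter = c("egg_days", "Ro"), value = c(3.13, 91.84))
  cmp <- validate_against_observations(pred, obs)
  expect_equal(cmp$difference[1], -0.26, tolerance = 1e-9)
  same <- validate_against_observations(pred, pred)
  expect_true(all(same$difference == 0))
  expect_error(validate_against_observations(pred, obs[0, ]), "empty")
  expect_error(
    validate_against_observations(pred,
                                  data.frame(parameter = "x", value = 1)),
    "lacks")
})
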