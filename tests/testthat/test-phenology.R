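test_that("phenology JSON parameter file round-trips", {
  ph <- ref_phenology()
  p <- tempfile(fileext = ".json")
  write_phenology(ph, p)
  back <- read_phenology(p)
  tc <- c(15, 25, 35)
  for (s in c("egg", "larva", "pupa", "female", "male")) {
    expect_equal(vapply(tc, median_dev_time, 1, dist = back$dev_time[[s]]),
                 vapply(tc, median_dev_time, 1, dist = ph$dev_time[[s]]))
    expect_equal(eval_development_rate(back$dev_rate[[s]], tc),
                 eval_development_rate(ph$dev_rate[[s]], tc))
  }
  for (s in c("egg", "larva", "pupa"))
    expect_equal(eval_mortality(back$mortality[[s]], tc),
                 eval_mortality(ph$mortality[[s]], tc))
  expect_equal(eval_total_fecundity(back$fecundity, tc),
               eval_total_fecundity(ph$fecundity, tc))
  expect_equal(back$oviposition$shape, ph$oviposition$shape)
  expect_equal(sex_ratio_at(back, 25), sex_ratio_at(ph, 25))
  # the file pins the gas constant and carries a version
  obj <- jsonlite::read_json(p)
  expect_equal(obj$gas_constant, 1.987)
  expect_true(nzchar(obj$format_version))
})

test_that("cohort CSV round-trips records and egg schedules", {
  ph <- ref_phenology()
  coh <- generate_cohort(ph, c(25, 30), n = c(egg = 20, larva = 10,
                                              pupa = 10, adult = 5),
                         seed = 5)
  p <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, p)
  back <- read_cohort_csv(p)
  expect_equal(nrow(back$records), nrow(coh$records))
  expect_equal(sum(back$eggs$eggs), sum(coh$eggs$eggs))
  key <- function(e) e[order(e$female_id, e$age_day),
                       c("female_id", "age_day", "eggs")]
  expect_equal(key(back$eggs)$eggs, key(coh$eggs)$eggs)
})

test_that("a full phenology model is fitted from synthetic cohort data", {
  ph <- ref_phenology()
  coh <- generate_cohort(ph, c(15, 20, 25, 30, 35, 38),
                         n = c(egg = 300, larva = 150, pupa = 150,
                               adult = 25), seed = 99)
  fit <- fit_phenology(coh)
  expect_s3_class(fit$phenology, "phenology_model")
  expect_true(all(c("dev_time", "dev_rate", "mortality", "fecundity",
                    "oviposition") %in% fit$goodness$submodel))
  # recovered pieces stay close to the generating model
  expect_lt(abs(fit$phenology$dev_time$egg$slope - 10.51) / 10.51, 0.2)
  expect_lt(abs(fit$phenology$mortality$larva$Topt -
                ph$mortality$larva$Topt), 2)
  peak <- -fit$phenology$fecundity$b / (2 * fit$phenology$fecundity$c)
  expect_lt(abs(peak - 26.5), 2)
  expect_lt(abs(fit$phenology$oviposition$shape - 5.99), 1.5)
  # sex ratio estimated from balanced adult cohorts
  expect_lt(max(abs(fit$phenology$sex_ratio - 0.5)), 0.001)
})

test_that("model bundle validates completeness and sex ratio", {
  ph <- ref_phenology()
  expect_error(phenology_model(ph$dev_time[1:3], ph$dev_rate, ph$mortality,
                               ph$fecundity, ph$oviposition),
               "slots")
  expect_error(phenology_model(ph$dev_time, ph$dev_rate, ph$mortality,
                               ph$fecundity, ph$oviposition,
                               sex_ratio = 1.2), "\\[0, 1\\]")
  srt <- phenology_model(ph$dev_time, ph$dev_rate, ph$mortality,
                         ph$fecundity, ph$oviposition,
                         sex_ratio = c(`20` = 0.4, `30` = 0.6))
  expect_equal(sex_ratio_at(srt, 25), 0.5)
  expect_equal(sex_ratio_at(srt, 10), 0.4)   # constant beyond the ends
})
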