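test_that("logit CDF evaluates the cumulative completion probability", {
  egg <- egg_logit()
  # median by construction: CDF at exp(-a/b) is exactly one half
  expect_equal(eval_dev_time_cdf(egg, 15, exp(26.71 / 10.51)), 0.5)
  # probability vanishes as x -> 0+
  expect_lt(eval_dev_time_cdf(egg, 15, 1e-8), 1e-10)
  # hand-evaluated oracle: larva parameters at 25 C, x = 17.52 days
  larva <- dev_time_dist("larva", c(`25` = -93.81), 32.76)
  expect_equal(eval_dev_time_cdf(larva, 25, 17.52), 0.4982799,
               tolerance = 1e-6)
  # monotone nondecreasing in x
  xs <- seq(0.5, 40, by = 0.25)
  expect_true(all(diff(eval_dev_time_cdf(egg, 25, xs)) >= 0))
})

test_that("CDF evaluation rejects unknown temperatures and bad times", {
  egg <- egg_logit()
  expect_error(eval_dev_time_cdf(egg, 22, 5), "available")
  expect_error(eval_dev_time_cdf(egg, 15, 0), "positive")
  expect_error(median_dev_time(egg, 99), "available")
})

test_that("median development time is the unique root of CDF = 1/2", {
  egg <- egg_logit()
  for (tc in c(15, 25, 35)) {
    med <- median_dev_time(egg, tc)
    # independent bisection oracle on the CDF itself
    root <- uniroot(function(x) eval_dev_time_cdf(egg, tc, x) - 0.5,
                    c(1e-6, 1e3), tol = 1e-10)$root
    expect_equal(med, root, tolerance = 1e-6)
  }
  # reference medians reproduce the study's predicted mean times
  expect_equal(median_dev_time(egg, 15), 12.71, tolerance = 0.005)
  expect_equal(median_dev_time(egg, 25), 3.60, tolerance = 0.005)
})

test_that("fitting recovers the generating slope from synthetic cohorts", {
  ph <- ref_phenology()
  set.seed(401)
  coh <- generate_cohort(ph, c(15, 25), n = c(egg = 400, larva = 2,
                                              pupa = 2, adult = 2),
                         seed = 401)
  rec <- coh$records[coh$records$stage == "egg", ]
  fit <- fit_dev_time_distribution(rec, "egg")
  expect_s3_class(fit, "dev_time_dist")
  expect_lt(abs(fit$slope - 10.51) / 10.51, 0.10)
  expect_true(is.finite(fit$aic))
  expect_gt(fit$r2, 0.8)
})

test_that("identical distributions at two temperatures give equal intercepts", {
  set.seed(77)
  mk <- function(tc) {
    x <- pmax(ceiling(exp((qlogis(runif(300)) + 26.71) / 10.51)), 1)
    data.frame(stage = "egg", temperature_C = tc,
               individual_id = paste0(tc, "_", seq_along(x)),
               outcome = "completed", event_day = x)
  }
  fit <- fit_dev_time_distribution(rbind(mk(15), mk(20)), "egg")
  a <- fit$intercepts
  expect_lt(abs(a[["15"]] - a[["20"]]), 0.05 * abs(a[["15"]]))
})

test_that("a point-mass cohort is flagged degenerate with median at that day", {
  rec <- data.frame(stage = "egg", temperature_C = rep(c(15, 20), each = 50),
                    individual_id = paste0("i", 1:100),
                    outcome = "completed",
                    event_day = rep(c(7L, 4L), each = 50))
  fit <- fit_dev_time_distribution(rec, "egg")
  expect_true("degenerate" %in% fit$flags)
  expect_equal(median_dev_time(fit, 15), 7)
  expect_equal(median_dev_time(fit, 20), 4)
  expect_error(fit_dev_time_distribution(rec[0, ], "egg"), "empty")
})
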