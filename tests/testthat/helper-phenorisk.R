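# shared fixtures; the reference phenology refits the adult senescence
# curves at construction, so build it once per test run
.cache <- new.env(parent = emptyenv())

ref_phenology <- function() {
  if (is.null(.cache$ph)) .cache$ph <- slitura_phenology()
  .cache$ph
}

# published egg-stage logit parameters used across tests
egg_logit <- function() {
  dev_time_dist("egg",
                c(`15` = -26.71, `20` = -15.94, `25` = -13.46, `30` = -6.93,
                  `35` = -5.91, `38` = -9.38),
                10.51)
}

egg_sharpe <- function() {
  dev_rate_model("egg", p = 0.29, To = 297.65, dHa = 19159.01,
                 dHh = 78167.42, Th = 309.34)
}

# a fast-cycling synthetic phenology for simulator tests: short stages,
# moderate mortality, compact reproduction
toy_phenology <- function(H_scale = 1, fec_a = 3.5) {
  temps <- c(20, 25, 30)
  dt <- function(stage, meds, b)
    dev_time_dist(stage, stats::setNames(-b * log(meds), temps), b)
  dr <- function(stage, meds)
    fit_development_rate(stats::setNames(1 / meds, c(15, 20, 25, 30, 35)),
                         stage)
  # median days at the 5 anchor temperatures used for the rate curves
  eggm <- c(8, 5, 3, 2.2, 2); larm <- c(30, 14, 8, 6, 5.5)
  pupm <- c(16, 8, 5, 4, 3.8); femm <- c(20, 12, 8, 6, 5)
  dev_time <- list(
    egg = dt("egg", eggm[c(2, 3, 4)], 12),
    larva = dt("larva", larm[c(2, 3, 4)], 15),
    pupa = dt("pupa", pupm[c(2, 3, 4)], 14),
    female = dt("female", femm[c(2, 3, 4)], 8),
    male = dt("male", femm[c(2, 3, 4)] * 0.9, 8))
  dev_rate <- list(egg = dr("egg", eggm), larva = dr("larva", larm),
                   pupa = dr("pupa", pupm), female = dr("female", femm),
                   male = dr("male", femm * 0.9))
  mortality <- list(
    egg = mortality_model("egg", 25, 3, 0.02 * H_scale),
    larva = mortality_model("larva", 26, 4, 0.05 * H_scale),
    pupa = mortality_model("pupa", 26, 3, 0.02 * H_scale))
  phenology_model(dev_time, dev_rate, mortality,
                  fecundity_model("exp_quadratic", fec_a, 0.16, -0.0032),
                  oviposition_model(5.99, 10.32), sex_ratio = 0.5)
}

# quadratic parameter-response fixture through exact points
const_response <- function(value, parameter = "rm", range = c(10, 40)) {
  fit_parameter_response(
    data.frame(temperature = c(range[1], mean(range), range[2]),
               value = rep(value, 3)), parameter)
}
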