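# Shared fixtures: a fixed demonstration country and a generator of random
# valid parameter sets (drawn from the plausible multi-country ranges).

demo_params <- function(country_code = "ESP", ...) {
  args <- list(
    country_code = country_code,
    cabg_per_year = 8294,
    sswi_incidence = 3.2,
    dswi_incidence = 1.2,
    readmit_prob_given_swi = 0.3,
    extra_los_sswi = 4,
    extra_los_dswi = 20,
    icu_cost_per_day = 1500,
    gw_cost_per_day = 500,
    baseline_icu_los = 3,
    baseline_gw_los = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(country_parameters, args)
}

# draws one valid random parameter set using the caller's RNG stream
random_country_params <- function() {
  country_parameters(
    country_code = paste0(sample(LETTERS, 3, replace = TRUE), collapse = ""),
    cabg_per_year = sample(1000:50000, 1),
    sswi_incidence = stats::runif(1, 1, 8),
    dswi_incidence = stats::runif(1, 0.5, 3),
    readmit_prob_given_swi = stats::runif(1, 0, 1),
    extra_los_sswi = stats::runif(1, 1, 49),
    extra_los_dswi = stats::runif(1, 1, 66),
    icu_cost_per_day = stats::runif(1, 500, 10000),
    gw_cost_per_day = stats::runif(1, 200, 3000),
    baseline_icu_los = stats::runif(1, 2, 6),
    baseline_gw_los = stats::runif(1, 4, 12))
}

random_model <- function(config = pathway_config()) {
  p <- random_country_params()
  inc <- calibrate_incidence(p$country_code,
                             p$sswi_incidence + p$dswi_incidence)
  build_transition_model(p, inc, config)
}

# events stub for burden arithmetic tests
fake_events <- function(excess_icu = 0, excess_gw = 0, readmit_days = 0,
                        swi_events = 0, volume = 1000, readmissions = 0) {
  structure(list(
    country_code = "TST", volume = volume, swi_events = swi_events,
    sswi_events = swi_events, dswi_events = 0,
    inpatient_swi_events = swi_events, postdischarge_swi_events = 0,
    readmissions = readmissions, deaths = 0,
    excess_icu_days = excess_icu, excess_gw_days = excess_gw,
    readmit_days = readmit_days,
    inpatient_rate = if (volume > 0) swi_events / volume else 0,
    readmission_rate = if (volume > 0) readmissions / volume else 0,
    r_swi = if (volume > 0) (swi_events + readmissions) / volume else 0
  ), class = "swi_events")
}
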