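test_that("baseline dwell probabilities follow the geometric mean-stay rule", {
  p <- demo_params(baseline_gw_los = 5)
  inc0 <- calibrate_incidence("ESP", 0)
  m <- build_transition_model(p, inc0)
  # GW self-loop 0.8, exit 0.2 for a 5-day mean stay
  expect_equal(m$T[1, "GW", "GW"], 0.8)
  expect_equal(m$T[1, "GW", "HOME"], 0.2)
  expect_equal(m$p_gw, 0.2)
})

test_that("transition rows sum to one for every state and cycle", {
  withr::with_seed(21, {
    m <- random_model()
    for (t in c(1, 45, 90)) {
      expect_equal(rowSums(m$T[t, , ]), rep(1, 10), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  })
})

test_that("zero SWI hazard reduces to the baseline pathway", {
  p <- demo_params()
  inc0 <- calibrate_incidence("ESP", 0)
  m <- build_transition_model(p, inc0)
  ct <- run_cohort(m, volume = 1000)
  expect_equal(ct$sswi_events + ct$dswi_events, 0)
  expect_equal(ct$readmissions, 0)
  expect_equal(ct$deaths, 0)
  # truncated-geometric day counts reproduce the stated stays within 1%
  expect_equal(ct$icu_days, 1000 * p$baseline_icu_los, tolerance = 0.01)
  expect_equal(ct$gw_days, 1000 * p$baseline_gw_los, tolerance = 0.01)
})

test_that("cohort occupancy is conserved and volume scales linearly", {
  p <- demo_params()
  inc <- calibrate_incidence("ESP", 4.4)
  m <- build_transition_model(p, inc)
  ct1 <- run_cohort(m, volume = 500)
  expect_true(all(abs(rowSums(ct1$occupancy) - 1) < 1e-9))
  ct0 <- run_cohort(m, volume = 0)
  ct2 <- run_cohort(m, volume = 1000)
  for (f in c("icu_days", "gw_days", "readmit_days", "sswi_events",
              "dswi_events", "readmissions", "deaths")) {
    expect_equal(ct0[[f]], 0)
    expect_equal(ct2[[f]], 2 * ct1[[f]])
  }
})

test_that("known additional stays produce matching excess ward days", {
  # superficial-only model where nearly all onsets arise after discharge
  # (steep late curve, short baseline stays), every home onset readmits,
  # and every SWI adds a mean 10-day stay at ward intensity; onsets are
  # early enough that horizon truncation of the added stay is negligible
  p <- demo_params(sswi_incidence = 5, dswi_incidence = 0,
                   extra_los_sswi = 10, extra_los_dswi = 0,
                   readmit_prob_given_swi = 1,
                   baseline_icu_los = 2, baseline_gw_los = 4)
  curve <- hill_params(theta = 6, eta = 4, kappa = 15)
  res <- run_country(p, curve = curve)
  ev <- res$events
  extra_days <- ev$excess_gw_days + ev$readmit_days
  expect_equal(extra_days, 10 * ev$swi_events, tolerance = 0.01)
  # per 100 SWI cases that is 1000 ward days
  expect_equal(100 * extra_days / ev$swi_events, 1000, tolerance = 0.01)
})

test_that("vanishing extra stay and readmissions leave zero excess burden", {
  p <- demo_params(extra_los_sswi = 0, extra_los_dswi = 0,
                   readmit_prob_given_swi = 0)
  res <- run_country(p)
  expect_equal(res$events$excess_icu_days, 0, tolerance = 1e-9)
  expect_equal(res$events$excess_gw_days, 0, tolerance = 1e-9)
  expect_equal(res$events$readmit_days, 0)
  # the infections themselves still happen and are counted
  expect_gt(res$events$swi_events, 0)
})

test_that("raising the SWI hazard weakly raises events, days, readmissions", {
  p <- demo_params()
  prev <- NULL
  for (total in c(1, 3, 6, 10)) {
    p2 <- demo_params(sswi_incidence = total * 0.75,
                      dswi_incidence = total * 0.25)
    ev <- run_country(p2)$events
    if (!is.null(prev)) {
      expect_gte(ev$swi_events, prev$swi_events)
      expect_gte(ev$excess_gw_days + ev$readmit_days,
                 prev$excess_gw_days + prev$readmit_days)
      expect_gte(ev$readmissions, prev$readmissions)
    }
    prev <- ev
  }
})

test_that("invalid derived probabilities are rejected by name", {
  p <- demo_params(baseline_icu_los = 1.5)
  inc <- calibrate_incidence("ESP", 4.4)
  expect_error(build_transition_model(p, inc), "baseline_icu_los")
  p2 <- demo_params(extra_los_sswi = 0.5)
  expect_error(build_transition_model(p2, inc), "extra_los_sswi")
})

test_that("patient-level simulation is reproducible and respects edge cases", {
  p <- demo_params()
  inc <- calibrate_incidence("ESP", 4.4)
  m <- build_transition_model(p, inc)
  a <- simulate_patients(m, 500, seed = 7)
  b <- simulate_patients(m, 500, seed = 7)
  expect_identical(a, b)
  c <- simulate_patients(m, 500, seed = 8)
  expect_false(identical(a$totals, c$totals))
})

test_that("patient-level oracle matches the cohort engine (moderate n)", {
  p <- demo_params()
  inc <- calibrate_incidence("ESP", 4.4)
  m <- build_transition_model(p, inc)
  n <- 20000
  ct <- run_cohort(m, volume = n)
  sim <- simulate_patients(m, n, seed = 42)
  for (f in colnames(sim$per_patient)) {
    se_total <- stats::sd(sim$per_patient[, f]) * sqrt(n)
    expect_lt(abs(ct[[f]] - sim$totals[[f]]), 4 * se_total + 1e-9)
  }
})

test_that("event extraction reports rates whose sum is the hospital SWI rate", {
  res <- run_country(demo_params())
  ev <- res$events
  expect_equal(ev$r_swi, ev$inpatient_rate + ev$readmission_rate)
  expect_equal(ev$sswi_events + ev$dswi_events,
               ev$inpatient_swi_events + ev$postdischarge_swi_events,
               tolerance = 1e-9)
  # a 4% inpatient rate plus 1.6% readmissions gives a 5.6% hospital rate
  ev2 <- fake_events(swi_events = 40, readmissions = 16, volume = 1000)
  expect_equal(ev2$r_swi, 0.056)
  # mismatched horizons are refused
  short <- run_country(demo_params(), config = pathway_config(horizon = 60))
  expect_error(extract_events(res$trace, short$baseline, demo_params()),
               "horizon")
})
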