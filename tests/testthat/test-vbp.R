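spain_scenario <- function() {
  vbp_scenario(rr_with_intervention = 0.75, share_purchase = 30,
               n_interventions = 3, share_savings = 30, n_patients = 1200,
               cost_per_swi = 12008, swi_rate = 0.056)
}

test_that("CIPP matches the worked hospital example to the cent", {
  s <- spain_scenario()
  expect_equal(round(compute_cipp(s), 2), 16.81)
  # exact closed form
  expect_equal(compute_cipp(s), (1 - 0.75) * 12008 * 0.056 * 0.30 / 3)
})

test_that("VBP payment matches the worked hospital example to the cent", {
  s <- spain_scenario()
  expect_equal(round(compute_vbp(s, cipp = 16.81), 2), 14121.84)
})

test_that("CIPP degenerates and scales as its closed form dictates", {
  s <- spain_scenario()
  s1 <- s; s1$rr_with_intervention <- 1
  expect_equal(compute_cipp(s1), 0)
  s2 <- s; s2$n_interventions <- 6
  expect_equal(compute_cipp(s2), compute_cipp(s) / 2)
  # monotone increasing in cost, rate, purchase share and effect size
  bump <- function(field, value) { x <- s; x[[field]] <- value; compute_cipp(x) }
  expect_gt(bump("cost_per_swi", 13000), compute_cipp(s))
  expect_gt(bump("swi_rate", 0.06), compute_cipp(s))
  expect_gt(bump("share_purchase", 40), compute_cipp(s))
  expect_gt(bump("rr_with_intervention", 0.5), compute_cipp(s))
})

test_that("VBP vanishes at break-even and with a zero savings share", {
  s <- spain_scenario()
  breakeven <- (1 - s$rr_with_intervention) * s$cost_per_swi * s$swi_rate /
    s$n_interventions
  expect_equal(compute_vbp(s, cipp = breakeven), 0)
  s0 <- s; s0$share_savings <- 0
  expect_equal(compute_vbp(s0), 0)
  expect_warning(compute_vbp(s, cipp = 2 * breakeven), "break-even")
})

test_that("funded CIPP leaves the unallocated share of gross savings", {
  withr::with_seed(5, {
    for (i in 1:25) {
      s <- vbp_scenario(rr_with_intervention = stats::runif(1, 0, 1),
                        share_purchase = stats::runif(1, 0, 100),
                        n_interventions = sample(1:5, 1),
                        share_savings = stats::runif(1, 0, 100),
                        n_patients = sample(100:5000, 1),
                        cost_per_swi = stats::runif(1, 1000, 60000),
                        swi_rate = stats::runif(1, 0.005, 0.15))
      r <- run_vbp(s)
      # bracket identity: with cipp fully funded from the purchase share,
      # the shared pot is gross x (1 - S_PUR/100), always non-negative
      pot <- r$gross_savings * (1 - s$share_purchase / 100)
      expect_equal(r$vbp_payment,
                   pot / (100 * s$n_interventions) * s$share_savings,
                   tolerance = 1e-12)
      expect_gte(pot, -1e-9)
      # value conservation, exactly
      expect_equal(r$hospital_savings + s$n_interventions * r$vbp_payment +
                     r$purchase_cost, r$gross_savings, tolerance = 1e-12)
    }
  })
})

test_that("hospital savings follow gross - purchase - payouts", {
  s <- spain_scenario()
  # an ineffective intervention still costs its purchase price
  s1 <- s; s1$rr_with_intervention <- 1
  expect_equal(hospital_savings(s1, cipp = 5, vbp_payment = 0),
               -5 * s1$n_interventions * s1$n_patients)
  # with everything shared away (full purchase share, full savings share,
  # one intervention) the hospital keeps nothing
  s2 <- s; s2$share_purchase <- 100; s2$share_savings <- 100
  s2$n_interventions <- 1
  expect_equal(hospital_savings(s2), 0, tolerance = 1e-9)
})

test_that("hospital savings at point estimates sit near the published median", {
  # 1000-procedure hospital, scenario 1 constants, country-level cost per
  # SWI of 11 845 US$ and a 5.74% hospital SWI rate
  const <- scenario_constants(1)
  s <- vbp_scenario(rr_with_intervention = const$rr_with_intervention,
                    share_purchase = const$share_purchase,
                    n_interventions = const$n_interventions,
                    share_savings = const$share_savings,
                    n_patients = const$n_patients,
                    cost_per_swi = 11845, swi_rate = 0.0574)
  r <- run_vbp(s)
  # brute-force arithmetic oracle
  gross <- 0.0574 * 1000 * 11845 * 0.2
  cipp <- 0.2 * 11845 * 0.0574 * 0.5 / 2
  vbp <- (gross - cipp * 2 * 1000) / 200 * 15
  expect_equal(r$cipp, cipp)
  expect_equal(r$vbp_payment, vbp)
  expect_equal(r$hospital_savings, gross - cipp * 2000 - 2 * vbp)
  # the deterministic value lies within a few percent of the PSA median
  expect_equal(r$hospital_savings, 57165, tolerance = 0.05)
})

test_that("scenario constants and the scenario runner behave", {
  c1 <- scenario_constants(1)
  expect_equal(c1, list(share_purchase = 50, n_interventions = 2,
                        share_savings = 15, rr_with_intervention = 0.8,
                        n_patients = 1000))
  c2 <- scenario_constants(2)
  expect_equal(c2$share_purchase, 30)
  expect_equal(c2$share_savings, 25)
  expect_error(scenario_constants(3), "1 or 2")

  # degenerate single draw: median equals both range endpoints
  one <- data.frame(cost_per_swi = 12008, r_swi = 0.056)
  sr <- run_scenario(1, one)
  expect_equal(sr$summary$cipp[["median"]], sr$summary$cipp[["min"]])
  expect_equal(sr$summary$cipp[["median"]], sr$summary$cipp[["max"]])
  # hand-computed closed forms with scenario-1 constants on that draw
  cipp <- 0.2 * 12008 * 0.056 * 0.5 / 2
  expect_equal(sr$per_draw$cipp, cipp)
  gross <- 0.056 * 1000 * 12008 * 0.2
  expect_equal(sr$per_draw$vbp_payment, (gross - cipp * 2000) / 200 * 15)
})

test_that("scenario definitions are validated", {
  expect_error(vbp_scenario(1.2, 30, 3, 30, 1200, 12008, 0.056), "\\[0, 1\\]")
  expect_error(vbp_scenario(0.8, 130, 3, 30, 1200, 12008, 0.056), "percent")
  expect_error(vbp_scenario(0.8, 30, 0, 30, 1200, 12008, 0.056), ">= 1")
  expect_error(vbp_scenario(0.8, 30, 3, 30, 1200, 12008, 1.5), "fraction")
})
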