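test_that("study values merge by pass-through or range midpoint", {
  expect_equal(merge_study_values(10),
               list(value = 10, provenance = "observed"))
  expect_equal(merge_study_values(c(10, 20)),
               list(value = 15, provenance = "midpoint"))
  # midpoint spans the full reported range, not the first two studies
  expect_equal(merge_study_values(c(8, 20, 14)),
               list(value = (8 + 20) / 2, provenance = "midpoint"))
  expect_equal(merge_study_values(c(8, 20, 14), method = "mean")$value, 14)
  miss <- merge_study_values(numeric(0))
  expect_true(is.na(miss$value) && is.na(miss$provenance))
})

test_that("long observation tables collapse into a wide country table", {
  obs <- data.frame(
    country_code = c("AAA", "AAA", "AAA", "BBB"),
    field_name = c("gw_cost_per_day", "gw_cost_per_day", "extra_los_sswi",
                   "extra_los_sswi"),
    value = c(400, 600, 7, 3),
    source_id = c("s1", "s2", "s3", "s4"))
  w <- merge_observations(obs)
  expect_equal(w$gw_cost_per_day[w$country_code == "AAA"], 500)
  expect_equal(w$prov_gw_cost_per_day[w$country_code == "AAA"], "midpoint")
  expect_equal(w$extra_los_sswi, c(7, 3))
  expect_equal(w$prov_extra_los_sswi, c("observed", "observed"))
  expect_true(is.na(w$icu_cost_per_day[1]))
  expect_error(merge_observations(transform(obs, field_name = "bogus")),
               "unknown field")
})

make_table <- function(n_obs_by_country) {
  fields <- swi_country_fields()
  tab <- data.frame(country_code = names(n_obs_by_country))
  for (f in fields) tab[[f]] <- NA_real_
  for (i in seq_along(n_obs_by_country)) {
    k <- n_obs_by_country[[i]]
    if (k > 0) for (f in fields[seq_len(k)]) tab[[f]][i] <- i + 1
  }
  tab
}

test_that("inclusion requires at least five of the ten parameters", {
  tab <- make_table(list(FULL = 10, FOUR = 4, FIVE = 5))
  res <- filter_included_countries(tab)
  expect_setequal(res$included$country_code, c("FULL", "FIVE"))
  expect_equal(res$excluded$country_code, "FOUR")
  expect_equal(res$excluded$n_observed, 4)
  # idempotent
  res2 <- filter_included_countries(res$included)
  expect_identical(res2$included, res$included)
  expect_equal(nrow(res2$excluded), 0)
})

test_that("imputation fills with the cross-country median and type-7 IQR", {
  fields <- swi_country_fields()
  tab <- data.frame(country_code = sprintf("C%02d", 1:5))
  for (f in fields) tab[[f]] <- c(1, 2, 3, 4, 5)
  tab$gw_cost_per_day <- c(1, 2, 3, 4, NA)
  out <- impute_missing(tab)
  expect_equal(out$gw_cost_per_day[5], 2.5)
  unc <- attr(out, "uncertainty")
  expect_equal(unc$q1[unc$field == "gw_cost_per_day"], 1.75)
  expect_equal(unc$q3[unc$field == "gw_cost_per_day"], 3.25)
  expect_equal(out$prov_gw_cost_per_day[5], "imputed")
  # observed cells untouched
  expect_equal(out$gw_cost_per_day[1:4], c(1, 2, 3, 4))
  # degenerate one-country field
  tab2 <- tab
  tab2$icu_cost_per_day <- c(7, NA, NA, NA, NA)
  out2 <- impute_missing(tab2)
  expect_equal(out2$icu_cost_per_day, c(7, 7, 7, 7, 7))
  unc2 <- attr(out2, "uncertainty")
  expect_equal(unlist(unc2[unc2$field == "icu_cost_per_day", c("q1", "q3")],
                      use.names = FALSE), c(7, 7))
  # complete table passes through unchanged
  tab3 <- make_table(list(A = 10, B = 10))
  expect_equal(impute_missing(tab3)[names(tab3)], tab3)
  # a field observed nowhere is a hard error naming the field
  tab4 <- tab
  tab4$extra_los_dswi <- NA_real_
  expect_error(impute_missing(tab4), "extra_los_dswi")
})

test_that("imputed values stay inside the observed range", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      tab <- data.frame(country_code = sprintf("C%02d", 1:8))
      for (f in swi_country_fields()) {
        v <- stats::runif(8, 1, 100)
        v[sample(8, 2)] <- NA
        tab[[f]] <- v
      }
      # keep every field observed somewhere
      out <- impute_missing(tab)
      for (f in swi_country_fields()) {
        obs <- tab[[f]][!is.na(tab[[f]])]
        imp <- out[[f]][is.na(tab[[f]])]
        expect_true(all(imp >= min(obs) & imp <= max(obs)))
      }
    }
  })
})

test_that("currency conversion divides by the mid-2017 rate", {
  expect_equal(convert_currency(100, 1.0), 100)
  expect_equal(convert_currency(110, 1.1), 100)
  expect_equal(convert_currency(54180 * 112, 112), 54180)
  expect_error(convert_currency(100, 0), "> 0")
  expect_error(convert_currency(100, -2), "> 0")
})

test_that("country tables round-trip through CSV bit-exactly", {
  gen <- generate_country_table(synthetic_spec(n_countries = 6, seed = 9,
                                               missingness = 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_country_table(gen$table, path)
  back <- read_country_table(path)
  for (f in swi_country_fields()) {
    expect_identical(back[[f]], gen$table[[f]])
    expect_identical(back[[paste0("prov_", f)]],
                     gen$table[[paste0("prov_", f)]])
  }
  expect_identical(back$country_code, gen$table$country_code)
})

test_that("parameter validation enforces the type invariants", {
  expect_error(demo_params(sswi_incidence = 101), "\\[0, 100\\]")
  expect_error(demo_params(sswi_incidence = 60, dswi_incidence = 50),
               "sum to <= 100")
  expect_error(demo_params(readmit_prob_given_swi = 1.5), "\\[0, 1\\]")
  expect_error(demo_params(icu_cost_per_day = -1), ">= 0")
  expect_error(demo_params(cabg_per_year = 0), ">= 1")
  expect_error(demo_params(extra_los_dswi = NA_real_), "non-finite")
  # a converted population rate gives the expected count
  expect_equal(cabg_count_from_rate(61.4, 82e6), 61.4 * 820)
})
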