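# Synthetic country-table generator: emulates the structure and printed
# value ranges of the multi-country parameter extraction, so the whole
# pipeline is testable without the original country inputs.

#' Specification for the synthetic country-table generator
#'
#' Default ranges mirror the extremes reported for mature health-care
#' systems: CABG rates of 6.4--61.4 per 100 000 population, total SWI
#' incidence 2.8--10.4\% of procedures, deep-SWI incidence 0.8--3.4\%,
#' additional superficial-SWI stays of 2--49 days (deep 5--66 days), and
#' daily costs spanning roughly an order of magnitude between the cheapest
#' and most expensive systems. Values are drawn uniformly within their
#' range (log-uniformly for costs and population); missingness is applied
#' after generation so imputation can be scored against the ground truth.
#'
#' @param n_countries Number of countries (default 14).
#' @param seed Integer seed.
#' @param missingness Probability that any one model parameter is masked
#'   (default 0.1, matching roughly one missing cell in ten). Never applied
#'   to `cabg_per_year`.
#' @param ranges Optional named list overriding the default ranges; each
#'   element is `c(lo, hi)`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_countries = 14, seed = 1, missingness = 0.1,
                           ranges = list()) {
  stopifnot(n_countries >= 1, missingness >= 0, missingness < 1)
  defaults <- list(
    cabg_per_100k = c(6.4, 61.4),
    population = c(5e6, 3.3e8),          # log-uniform
    total_swi_incidence = c(2.8, 10.4),  # percent
    dswi_incidence = c(0.8, 3.4),        # percent
    readmit_prob_given_swi = c(0.1, 0.5),
    extra_los_sswi = c(2, 49),
    extra_los_dswi = c(5, 66),
    icu_cost_per_day = c(800, 10000),    # log-uniform
    gw_cost_per_day = c(250, 2500),      # log-uniform
    baseline_icu_los = c(2, 6),
    baseline_gw_los = c(5, 12)
  )
  for (nm in names(ranges)) {
    if (!nm %in% names(defaults)) stop("unknown range: ", nm)
    defaults[[nm]] <- ranges[[nm]]
  }
  for (nm in names(defaults)) {
    r <- defaults[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("range `", nm, "` must be ordered c(lo, hi)")
  }
  structure(list(n_countries = as.integer(n_countries),
                 seed = as.integer(seed), missingness = missingness,
                 ranges = defaults),
            class = "synthetic_spec")
}

#' Generate a synthetic country parameter table
#'
#' Draws one complete parameter set per country within the specified
#' ranges, derives the annual procedure count from the population-
#' normalised CABG rate, splits the total SWI incidence into superficial
#' and deep parts (the deep draw is capped at 80\% of the total so both
#' severities are represented), and finally masks cells at the configured
#' missingness rate. The pre-masking table is returned as ground truth for
#' imputation-recovery experiments.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (wide country table with `NA` holes and
#'   `prov_` columns) and `truth` (the complete pre-masking table).
#' @export
generate_country_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_countries
    rg <- spec$ranges
    runifr <- function(r) stats::runif(n, r[1], r[2])
    rlogunif <- function(r) exp(stats::runif(n, log(r[1]), log(r[2])))
    cabg_per_100k <- runifr(rg$cabg_per_100k)
    population <- rlogunif(rg$population)
    total <- runifr(rg$total_swi_incidence)
    dswi <- pmin(runifr(rg$dswi_incidence), 0.8 * total)
    truth <- data.frame(
      country_code = sprintf("C%02d", seq_len(n)),
      cabg_per_year = round(cabg_count_from_rate(cabg_per_100k, population)),
      cabg_per_100k = cabg_per_100k,
      sswi_incidence = total - dswi,
      dswi_incidence = dswi,
      readmit_prob_given_swi = runifr(rg$readmit_prob_given_swi),
      extra_los_sswi = runifr(rg$extra_los_sswi),
      extra_los_dswi = runifr(rg$extra_los_dswi),
      icu_cost_per_day = rlogunif(rg$icu_cost_per_day),
      gw_cost_per_day = rlogunif(rg$gw_cost_per_day),
      baseline_icu_los = runifr(rg$baseline_icu_los),
      baseline_gw_los = runifr(rg$baseline_gw_los),
      stringsAsFactors = FALSE)
    truth$cabg_per_year <- pmax(1, truth$cabg_per_year)
    tab <- truth
    maskable <- setdiff(swi_country_fields(), "cabg_per_year")
    for (f in swi_country_fields()) {
      tab[[paste0("prov_", f)]] <- "observed"
    }
    for (f in maskable) {
      mask <- stats::runif(n) < spec$missingness
      tab[[f]][mask] <- NA_real_
      tab[[paste0("prov_", f)]][mask] <- NA_character_
    }
    list(table = tab, truth = truth)
  })
}

#' Simulate 30-day SWI counts for calibration-recovery experiments
#'
#' Draws a binomial count of SWIs among `n_patients` followed to the
#' reference day, with success probability `true_factor` times the base
#' curve's cumulative incidence at that day (as a fraction).
#'
#' @param true_factor True country scale factor (>= 0).
#' @param n_patients Cohort size.
#' @param seed Integer seed.
#' @param curve Base [hill_params()] curve.
#' @param reference_day Follow-up day (default 30).
#' @return List with `events`, `n`, and the true `p`.
#' @export
generate_incidence_observations <- function(true_factor, n_patients, seed,
                                            curve = hill_params(),
                                            reference_day = 30) {
  p <- true_factor * hill_cumulative(reference_day, curve) / 100
  if (p < 0 || p >= 1) stop("true incidence fraction must lie in [0, 1)")
  events <- with_seed(seed, stats::rbinom(1, n_patients, p))
  list(events = events, n = n_patients, p = p)
}

#' Recover the calibration factor from observed 30-day counts
#'
#' @param events Observed SWI count.
#' @param n Cohort size.
#' @param curve Base [hill_params()] curve.
#' @param reference_day Follow-up day (default 30).
#' @return The estimated scale factor.
#' @export
recover_calibration_factor <- function(events, n, curve = hill_params(),
                                       reference_day = 30) {
  stopifnot(n >= 1, events >= 0, events <= n)
  calibration_factor(100 * events / n,
                     hill_cumulative(reference_day, curve))
}
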