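# Monetary burden of SWIs per country and cross-country aggregation.

#' Monetise the excess resource use attributable to SWIs
#'
#' Total burden is the sum of three components: excess ICU days at the ICU
#' daily cost, excess general-ward days at the GW daily cost, and
#' readmission days costed at the GW daily rate (an ICU fraction for
#' readmission stays is configurable).
#'
#' @param events An [extract_events()] summary.
#' @param params The matching [country_parameters()] object.
#' @param readmit_icu_fraction Fraction of readmission days costed at ICU
#'   intensity (default 0).
#' @return An object of class `burden_result` with fields `country_code`,
#'   `procedures`, `swi_events`, `total_cost`, `icu_days`, `gw_days`,
#'   `readmit_days`, `readmissions`, `cost_per_swi` (`NA` when there are
#'   no events, never 0), and `cost_per_cabg`.
#' @export
compute_country_burden <- function(events, params, readmit_icu_fraction = 0) {
  stopifnot(inherits(events, "swi_events"),
            inherits(params, "country_parameters"),
            readmit_icu_fraction >= 0, readmit_icu_fraction <= 1)
  readmit_rate <- readmit_icu_fraction * params$icu_cost_per_day +
    (1 - readmit_icu_fraction) * params$gw_cost_per_day
  total_cost <- events$excess_icu_days * params$icu_cost_per_day +
    events$excess_gw_days * params$gw_cost_per_day +
    events$readmit_days * readmit_rate
  structure(list(
    country_code = events$country_code,
    procedures = events$volume,
    swi_events = events$swi_events,
    total_cost = total_cost,
    icu_days = events$excess_icu_days,
    gw_days = events$excess_gw_days,
    readmit_days = events$readmit_days,
    readmissions = events$readmissions,
    r_swi = events$r_swi,
    cost_per_swi = if (events$swi_events > 0) {
      total_cost / events$swi_events
    } else NA_real_,
    cost_per_cabg = if (events$volume > 0) {
      total_cost / events$volume
    } else NA_real_
  ), class = "burden_result")
}

#' Stack burden results into a per-country table
#'
#' @param results A list of [compute_country_burden()] results, or a data
#'   frame already in table form.
#' @return Data frame with one row per country and the `burden_result`
#'   fields as columns.
#' @export
burden_table <- function(results) {
  if (is.data.frame(results)) return(results)
  stopifnot(length(results) >= 1)
  do.call(rbind, lapply(results, function(r) {
    data.frame(country_code = r$country_code, procedures = r$procedures,
               swi_events = r$swi_events, total_cost = r$total_cost,
               icu_days = r$icu_days, gw_days = r$gw_days,
               readmit_days = r$readmit_days, readmissions = r$readmissions,
               cost_per_swi = r$cost_per_swi, cost_per_cabg = r$cost_per_cabg,
               stringsAsFactors = FALSE)
  }))
}

#' Cross-country burden summary
#'
#' Aggregates per-country burden results: the grand total, each country's
#' share of it, and median / IQR / min / max of the per-SWI and per-CABG
#' costs. Quartiles use linear interpolation between order statistics
#' (type 7). Aggregation runs over unrounded values.
#'
#' @param results A list of `burden_result` objects or a data frame from
#'   [burden_table()] (columns `country_code`, `total_cost`, `procedures`,
#'   `cost_per_swi`, `cost_per_cabg`; day and readmission columns are
#'   totalled when present).
#' @return An object of class `cross_country_summary`: `total_cost`,
#'   `shares` (named, summing to 1), `cost_per_swi` and `cost_per_cabg`
#'   summaries (each median/q1/q3/min/max), and totals of days and
#'   readmissions where available.
#' @export
cross_country_summary <- function(results) {
  tab <- burden_table(results)
  stopifnot(nrow(tab) >= 1)
  total <- sum(tab$total_cost)
  shares <- stats::setNames(tab$total_cost / total, tab$country_code)
  five_num <- function(x) {
    x <- x[!is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x))
  }
  out <- list(
    total_cost = total,
    shares = shares,
    cost_per_swi = five_num(tab$cost_per_swi),
    cost_per_cabg = five_num(tab$cost_per_cabg)
  )
  for (col in c("icu_days", "gw_days", "readmit_days", "readmissions")) {
    if (col %in% names(tab)) out[[paste0("total_", col)]] <- sum(tab[[col]])
  }
  structure(out, class = "cross_country_summary")
}
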