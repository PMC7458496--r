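# Per-country parameter table: validation, study merging, inclusion filter,
# median/IQR imputation, currency conversion, and CSV round-tripping.

#' The ten canonical country-specific model parameters
#'
#' Every downstream stage is driven by these ten fields. A country enters
#' the analysis when at least five of them were identified in the
#' literature; the rest are imputed from the cross-country median.
#'
#' @return Character vector of the ten field names.
#' @export
swi_country_fields <- function() {
  c("cabg_per_year", "sswi_incidence", "dswi_incidence",
    "readmit_prob_given_swi", "extra_los_sswi", "extra_los_dswi",
    "icu_cost_per_day", "gw_cost_per_day", "baseline_icu_los",
    "baseline_gw_los")
}

#' Construct and validate one country's parameter set
#'
#' @param country_code Country identifier (conventionally ISO-3).
#' @param cabg_per_year Number of CABG procedures per year (>= 1).
#' @param sswi_incidence Superficial SWI incidence, percent of procedures.
#' @param dswi_incidence Deep SWI incidence, percent of procedures.
#' @param readmit_prob_given_swi Probability that an SWI arising after
#'   discharge leads to readmission, fraction in \[0, 1\].
#' @param extra_los_sswi Additional length of stay attributable to a
#'   superficial SWI, days.
#' @param extra_los_dswi Additional length of stay attributable to a deep
#'   SWI, days.
#' @param icu_cost_per_day Cost of one intensive-care day, 2017 US$.
#' @param gw_cost_per_day Cost of one general-ward day, 2017 US$.
#' @param baseline_icu_los Uncomplicated post-CABG ICU stay, days.
#' @param baseline_gw_los Uncomplicated post-CABG general-ward stay, days.
#' @param cabg_per_100k Optional population-normalised CABG rate
#'   (procedures per 100 000); informational, not used by the model.
#' @param provenance Named character vector mapping fields to one of
#'   `"observed"`, `"midpoint"`, `"imputed"`. Defaults to all `"observed"`.
#' @return An object of class `country_parameters` (a named list).
#' @export
country_parameters <- function(country_code, cabg_per_year, sswi_incidence,
                               dswi_incidence, readmit_prob_given_swi,
                               extra_los_sswi, extra_los_dswi,
                               icu_cost_per_day, gw_cost_per_day,
                               baseline_icu_los, baseline_gw_los,
                               cabg_per_100k = NA_real_,
                               provenance = NULL) {
  p <- list(country_code = as.character(country_code),
            cabg_per_year = cabg_per_year,
            cabg_per_100k = cabg_per_100k,
            sswi_incidence = sswi_incidence,
            dswi_incidence = dswi_incidence,
            readmit_prob_given_swi = readmit_prob_given_swi,
            extra_los_sswi = extra_los_sswi,
            extra_los_dswi = extra_los_dswi,
            icu_cost_per_day = icu_cost_per_day,
            gw_cost_per_day = gw_cost_per_day,
            baseline_icu_los = baseline_icu_los,
            baseline_gw_los = baseline_gw_los)
  if (is.null(provenance)) {
    provenance <- stats::setNames(rep("observed", length(swi_country_fields())),
                                  swi_country_fields())
  }
  p$provenance <- provenance
  validate_country_parameters(p)
  structure(p, class = "country_parameters")
}

validate_country_parameters <- function(p) {
  num <- swi_country_fields()
  vals <- unlist(p[num])
  if (any(!is.finite(vals))) {
    stop("missing or non-finite parameter(s): ",
         paste(num[!is.finite(vals)], collapse = ", "))
  }
  if (p$cabg_per_year < 1) stop("`cabg_per_year` must be >= 1")
  for (f in c("sswi_incidence", "dswi_incidence")) {
    if (p[[f]] < 0 || p[[f]] > 100) stop("`", f, "` must be in [0, 100] percent")
  }
  if (p$sswi_incidence + p$dswi_incidence > 100) {
    stop("superficial and deep SWI incidences must sum to <= 100 percent")
  }
  if (p$readmit_prob_given_swi < 0 || p$readmit_prob_given_swi > 1) {
    stop("`readmit_prob_given_swi` must be in [0, 1]")
  }
  for (f in c("extra_los_sswi", "extra_los_dswi", "icu_cost_per_day",
              "gw_cost_per_day", "baseline_icu_los", "baseline_gw_los")) {
    if (p[[f]] < 0) stop("`", f, "` must be >= 0")
  }
  invisible(p)
}

#' Convert a population-normalised CABG rate to an annual procedure count
#'
#' @param cabg_per_100k Procedures per 100 000 population.
#' @param population Country population.
#' @return Procedures per year.
#' @export
cabg_count_from_rate <- function(cabg_per_100k, population) {
  stopifnot(cabg_per_100k >= 0, population > 0)
  cabg_per_100k * population / 1e5
}

#' Merge multiple study values for one country and field
#'
#' When a single study reports a parameter its value passes through
#' unchanged; when two or more studies report it, the midpoint of the
#' reported range, `(min + max) / 2`, is used. The mean is available as an
#' alternative.
#'
#' @param values Numeric vector of study values for one (country, field)
#'   pair. An empty vector signals a missing value (handled downstream by
#'   imputation).
#' @param method `"midpoint"` (default) or `"mean"` for >= 2 studies.
#' @return List with `value` and `provenance` (`"observed"`, `"midpoint"`,
#'   or `NA` for a missing value).
#' @export
merge_study_values <- function(values, method = c("midpoint", "mean")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(list(value = NA_real_, provenance = NA_character_))
  }
  if (any(!is.finite(values))) stop("study values must be finite")
  if (length(values) == 1) {
    return(list(value = values, provenance = "observed"))
  }
  v <- switch(method,
              midpoint = (min(values) + max(values)) / 2,
              mean = mean(values))
  list(value = v, provenance = "midpoint")
}

#' Collapse a long table of study observations into a wide country table
#'
#' @param observations Data frame with columns `country_code`, `field_name`,
#'   `value`, and optionally `source_id`. `field_name` entries must be
#'   canonical fields (see [swi_country_fields()]) or `cabg_per_100k`.
#' @param method Passed to [merge_study_values()].
#' @return Wide data frame, one row per country, with `prov_<field>` columns.
#' @export
merge_observations <- function(observations, method = "midpoint") {
  req <- c("country_code", "field_name", "value")
  if (!all(req %in% names(observations))) {
    stop("observations need columns: ", paste(req, collapse = ", "))
  }
  allowed <- c(swi_country_fields(), "cabg_per_100k")
  bad <- setdiff(unique(observations$field_name), allowed)
  if (length(bad)) stop("unknown field(s): ", paste(bad, collapse = ", "))
  countries <- sort(unique(observations$country_code))
  fields <- swi_country_fields()
  out <- data.frame(country_code = countries, stringsAsFactors = FALSE)
  for (f in fields) {
    out[[f]] <- NA_real_
    out[[paste0("prov_", f)]] <- NA_character_
  }
  for (cc in countries) {
    for (f in fields) {
      vals <- observations$value[observations$country_code == cc &
                                   observations$field_name == f]
      m <- merge_study_values(vals, method = method)
      out[[f]][out$country_code == cc] <- m$value
      out[[paste0("prov_", f)]][out$country_code == cc] <- m$provenance
    }
  }
  out
}

#' Apply the five-of-ten data-availability inclusion filter
#'
#' Countries for which at least `min_observed` of the ten canonical
#' parameters are available are retained; the rest are reported in an
#' exclusion table. The operation is idempotent.
#'
#' @param table Wide country table (one row per country) with the canonical
#'   fields as columns; missing cells are `NA`.
#' @param min_observed Inclusion threshold (default 5 of 10).
#' @return List with `included` (the filtered table) and `excluded`
#'   (data frame of `country_code` and `n_observed`).
#' @export
filter_included_countries <- function(table, min_observed = 5) {
  fields <- swi_country_fields()
  missing_cols <- setdiff(fields, names(table))
  if (length(missing_cols)) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  n_obs <- rowSums(!is.na(table[fields]))
  keep <- n_obs >= min_observed
  list(
    included = table[keep, , drop = FALSE],
    excluded = data.frame(country_code = table$country_code[!keep],
                          n_observed = n_obs[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Fill missing parameters with cross-country medians
#'
#' Each missing cell is replaced by the median of the values observed in
#' the other countries; the cross-country interquartile range (IQR) of that
#' field is attached as the cell's uncertainty range for probabilistic
#' sensitivity analysis. Quartiles use linear interpolation between order
#' statistics (the type-7 convention). Observed cells are never altered.
#'
#' @param table Wide country table (post inclusion filter).
#' @return The completed table, with `prov_<field>` columns set to
#'   `"imputed"` where filling occurred, and an attribute `"uncertainty"`:
#'   a data frame of `field`, `q1`, `q3` for every field that had at least
#'   one missing cell.
#' @export
impute_missing <- function(table) {
  fields <- swi_country_fields()
  unc <- data.frame(field = character(), q1 = numeric(), q3 = numeric(),
                    stringsAsFactors = FALSE)
  for (f in fields) {
    prov_col <- paste0("prov_", f)
    if (!prov_col %in% names(table)) table[[prov_col]] <- "observed"
    miss <- is.na(table[[f]])
    if (!any(miss)) next
    obs <- table[[f]][!miss]
    if (length(obs) == 0) {
      stop("field `", f, "` is observed in no country; cannot impute")
    }
    med <- stats::median(obs)
    q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
    table[[f]][miss] <- med
    table[[prov_col]][miss] <- "imputed"
    unc <- rbind(unc, data.frame(field = f, q1 = q[1], q3 = q[2],
                                 stringsAsFactors = FALSE))
  }
  attr(table, "uncertainty") <- unc
  table
}

#' Convert a local-currency amount to 2017 US$
#'
#' @param amount Amount in local currency.
#' @param rate Market exchange rate, local currency units per US$ at
#'   mid-2017. Must be > 0.
#' @return Amount in 2017 US$ (`amount / rate`).
#' @export
convert_currency <- function(amount, rate) {
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("exchange rate must be > 0 (local units per US$)")
  }
  amount / rate
}

#' Extract one country's row of a wide table as a `country_parameters` object
#'
#' @param table Completed wide table (no `NA` in canonical fields).
#' @param country_code Which row to extract.
#' @return A [country_parameters()] object.
#' @export
country_from_table <- function(table, country_code) {
  row <- table[table$country_code == country_code, , drop = FALSE]
  if (nrow(row) != 1) stop("country `", country_code, "` not found (or duplicated)")
  fields <- swi_country_fields()
  prov <- vapply(fields, function(f) {
    pc <- paste0("prov_", f)
    if (pc %in% names(row)) row[[pc]] else "observed"
  }, character(1))
  args <- c(list(country_code = country_code), as.list(row[fields]),
            list(provenance = prov))
  if ("cabg_per_100k" %in% names(row)) args$cabg_per_100k <- row$cabg_per_100k
  do.call(country_parameters, args)
}

#' Write / read a country table preserving values and provenance
#'
#' Plain UTF-8 CSV with dot decimals; missing cells are written as empty
#' strings, never 0. The round trip is exact for values and provenance.
#'
#' @param table Wide country table.
#' @param path File path.
#' @return `write_country_table` returns `path` invisibly;
#'   `read_country_table` returns the table.
#' @export
write_country_table <- function(table, path) {
  out <- table
  for (f in names(out)) {
    if (is.double(out[[f]])) {
      # 17 significant digits make the numeric round trip exact
      chr <- sprintf("%.17g", out[[f]])
      chr[is.na(out[[f]])] <- NA_character_
      out[[f]] <- chr
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_country_table
#' @export
read_country_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(country_code = "character"))
  for (f in intersect(swi_country_fields(), names(tab))) {
    tab[[f]] <- as.numeric(tab[[f]])
    pc <- paste0("prov_", f)
    if (pc %in% names(tab)) {
      tab[[pc]] <- as.character(tab[[pc]])
      tab[[pc]][tab[[pc]] == ""] <- NA_character_
    }
  }
  tab
}
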