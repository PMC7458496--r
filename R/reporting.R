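# End-to-end runner: base-case burden table, PSA table, VBP scenario
# table, cross-country summary and box-plot statistics, with optional CSV/
# JSON emission carrying a provenance header.

.config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 4294967296)
}

.write_with_header <- function(df, path, seed, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# swiburden %s; seed=%d; config=%s",
                     as.character(utils::packageVersion("swiburden")),
                     seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Box-plot statistics from PSA draws
#'
#' One record per country: median, mean, first and third quartile (type-7
#' convention), standard deviation, min and max of the chosen metric.
#'
#' @param draws Data frame with a `country_code` column and the metric
#'   column; at least 2 draws per country.
#' @param metric Which column to summarise (default `"cost_per_cabg"`).
#' @return Data frame, one row per country.
#' @export
emit_boxplot_data <- function(draws, metric = "cost_per_cabg") {
  stopifnot(all(c("country_code", metric) %in% names(draws)))
  out <- do.call(rbind, lapply(split(draws, draws$country_code), function(d) {
    if (nrow(d) < 2) stop("need >= 2 draws per country")
    x <- d[[metric]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(country_code = d$country_code[1], median = q[2],
               mean = mean(x), q1 = q[1], q3 = q[3], sd = stats::sd(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the complete multi-country analysis
#'
#' Applies the inclusion filter and median/IQR imputation to the country
#' table, then per country: runs the deterministic base case, the PSA, and
#' both purchasing scenarios. Deterministic given the seed; rerunning with
#' the same inputs reproduces every table byte for byte.
#'
#' @param countries Wide country table (see [merge_observations()] /
#'   [generate_country_table()]); may contain `NA` holes.
#' @param seed Integer seed driving every random substream.
#' @param iterations PSA iterations per country (default 52).
#' @param pathway_cfg A [pathway_config()].
#' @param scenarios Scenario ids to run (default `c(1, 2)`).
#' @param out_dir Optional directory; when given, writes `table1.csv`
#'   (base-case burden), `table2.csv` (PSA median and range), `table3.csv`
#'   (VBP scenarios), `boxplot.csv` and `summary.json`, each CSV with a
#'   provenance header line.
#' @return List with `table1`, `table2`, `table3`, `summary`, `boxplot`,
#'   `draws` (all PSA draws, stacked) and `exclusions`.
#' @export
run_full_analysis <- function(countries, seed = 1, iterations = 52,
                              pathway_cfg = pathway_config(),
                              scenarios = c(1, 2), out_dir = NULL) {
  filt <- filter_included_countries(countries)
  completed <- impute_missing(filt$included)
  iqr <- attr(completed, "uncertainty")
  codes <- completed$country_code

  burdens <- list(); draw_list <- list(); t2 <- list(); t3 <- list()
  for (cc in codes) {
    p <- country_from_table(completed, cc)
    res <- run_country(p, config = pathway_cfg)
    burdens[[cc]] <- compute_country_burden(res$events, p)
    cfg <- psa_config(iterations = iterations, seed = seed, iqr = iqr)
    dr <- run_psa(p, cfg, pathway_cfg)
    dr$country_code <- cc
    draw_list[[cc]] <- dr
    s <- summarize_psa(dr[setdiff(names(dr), c("draw", "country_code"))])
    fmt <- function(m) {
      r <- s[s$metric == m, ]
      data.frame(median = r$median, lo = r$min, hi = r$max)
    }
    t2[[cc]] <- cbind(country_code = cc,
                      stats::setNames(fmt("total_cost"),
                                      c("cost_median", "cost_lo", "cost_hi")),
                      stats::setNames(fmt("icu_days"),
                                      c("icu_median", "icu_lo", "icu_hi")),
                      stats::setNames(fmt("gw_days"),
                                      c("gw_median", "gw_lo", "gw_hi")),
                      stats::setNames(fmt("readmissions"),
                                      c("readmit_median", "readmit_lo",
                                        "readmit_hi")))
    rows <- lapply(scenarios, function(sc) {
      sr <- run_scenario(sc, dr)
      data.frame(country_code = cc, scenario = sc,
                 cipp_median = sr$summary$cipp[["median"]],
                 cipp_lo = sr$summary$cipp[["min"]],
                 cipp_hi = sr$summary$cipp[["max"]],
                 vbp_median = sr$summary$vbp_payment[["median"]],
                 vbp_lo = sr$summary$vbp_payment[["min"]],
                 vbp_hi = sr$summary$vbp_payment[["max"]],
                 savings_median = sr$summary$hospital_savings[["median"]],
                 savings_lo = sr$summary$hospital_savings[["min"]],
                 savings_hi = sr$summary$hospital_savings[["max"]])
    })
    t3[[cc]] <- do.call(rbind, rows)
  }
  table1 <- burden_table(burdens)
  table2 <- do.call(rbind, t2); rownames(table2) <- NULL
  table3 <- do.call(rbind, t3); rownames(table3) <- NULL
  draws <- do.call(rbind, draw_list); rownames(draws) <- NULL
  summary <- cross_country_summary(burdens)
  boxplot <- emit_boxplot_data(draws)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    hash <- .config_hash(list(seed = seed, iterations = iterations,
                              pathway_cfg = unclass(pathway_cfg),
                              scenarios = scenarios))
    .write_with_header(table1, file.path(out_dir, "table1.csv"), seed, hash)
    .write_with_header(table2, file.path(out_dir, "table2.csv"), seed, hash)
    .write_with_header(table3, file.path(out_dir, "table3.csv"), seed, hash)
    .write_with_header(boxplot, file.path(out_dir, "boxplot.csv"), seed, hash)
    jsonlite::write_json(
      list(total_cost = summary$total_cost,
           shares = as.list(summary$shares),
           cost_per_swi = summary$cost_per_swi,
           cost_per_cabg = summary$cost_per_cabg,
           seed = seed, config = hash),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(table1 = table1, table2 = table2, table3 = table3, summary = summary,
       boxplot = boxplot, draws = draws, exclusions = filt$excluded)
}
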