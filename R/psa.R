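# Probabilistic sensitivity analysis: per-field parameter sampling with
# independent substreams, end-to-end re-runs, and order-statistic summaries.

# run expr with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic substream seed per (country, draw, field); adding a field
# must not perturb the other fields' draws, hence one seed per triple
.derive_seed <- function(base_seed, country_code, draw_index, field_index) {
  cc <- sum(utf8ToInt(country_code))
  s <- (as.numeric(base_seed) * 97 + cc * 131071 +
          draw_index * 8191 + field_index * 127) %% 2147483647
  as.integer(s)
}

#' Probabilistic sensitivity analysis configuration
#'
#' Costs and lengths of stay are drawn from gamma distributions and
#' probabilities/incidences from beta distributions, each with mean equal
#' to the point estimate. The default spread is a standard deviation of
#' 20\% of the mean; fields filled by imputation instead use their stored
#' cross-country IQR as the central 50\% interval (SD = IQR width / 1.349,
#' the normal-quartile conversion).
#'
#' @param iterations Number of PSA draws (default 52, >= 2).
#' @param seed Integer base seed for all substreams.
#' @param spread Default relative SD (SD / mean) for sampled fields.
#' @param sample_volume Should `cabg_per_year` be sampled too? Default
#'   `FALSE`: procedure volume is administrative, not uncertain.
#' @param iqr Optional uncertainty table from [impute_missing()] (attribute
#'   `"uncertainty"`): data frame with `field`, `q1`, `q3`.
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(iterations = 52, seed = 1, spread = 0.2,
                       sample_volume = FALSE, iqr = NULL) {
  stopifnot(iterations >= 2, spread >= 0)
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed), spread = spread,
                 sample_volume = sample_volume, iqr = iqr),
            class = "psa_config")
}

.rgamma_mean_sd <- function(mean, sd) {
  if (mean <= 0 || sd == 0) return(mean)
  shape <- (mean / sd)^2
  stats::rgamma(1, shape = shape, rate = shape / mean)
}

.rbeta_mean_sd <- function(mean, sd) {
  if (mean <= 0 || sd == 0) return(mean)
  if (mean >= 1) stop("beta mean must be < 1")
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("infeasible beta spread: variance must be < mean * (1 - mean)")
  }
  nu <- mean * (1 - mean) / v - 1
  stats::rbeta(1, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# field -> sampling family; beta fields are stored on a percent or
# probability scale, `scale` maps to the (0,1) support and back
.psa_families <- function() {
  list(
    cabg_per_year = list(family = "gamma", scale = 1),
    sswi_incidence = list(family = "beta", scale = 100),
    dswi_incidence = list(family = "beta", scale = 100),
    readmit_prob_given_swi = list(family = "beta", scale = 1),
    extra_los_sswi = list(family = "gamma", scale = 1, floor = 1),
    extra_los_dswi = list(family = "gamma", scale = 1, floor = 1),
    icu_cost_per_day = list(family = "gamma", scale = 1),
    gw_cost_per_day = list(family = "gamma", scale = 1),
    baseline_icu_los = list(family = "gamma", scale = 1, floor = 2),
    baseline_gw_los = list(family = "gamma", scale = 1, floor = 1)
  )
}

#' Draw one sampled parameter set for a PSA iteration
#'
#' Every (country, draw, field) triple has its own deterministic random
#' substream, so draws are reproducible and mutually independent. Length-
#' of-stay draws are floored at the model's validity minimum (1 day of
#' additional stay; baseline ICU stay of at least 2 days so the ventilated
#' first day fits); fields with a point estimate of 0 stay 0.
#'
#' @param params Base-case [country_parameters()].
#' @param cfg A [psa_config()].
#' @param draw_index Which draw (1-based).
#' @return A [country_parameters()] object with sampled values.
#' @export
sample_parameters <- function(params, cfg, draw_index) {
  stopifnot(inherits(params, "country_parameters"),
            inherits(cfg, "psa_config"), draw_index >= 1)
  fams <- .psa_families()
  fields <- swi_country_fields()
  out <- params
  for (i in seq_along(fields)) {
    f <- fields[i]
    if (f == "cabg_per_year" && !cfg$sample_volume) next
    spec <- fams[[f]]
    centre <- params[[f]]
    if (centre == 0) next
    sd_abs <- cfg$spread * centre
    from_iqr <- FALSE
    if (!is.null(cfg$iqr) && f %in% cfg$iqr$field &&
        identical(params$provenance[[f]], "imputed")) {
      row <- cfg$iqr[cfg$iqr$field == f, ][1, ]
      sd_abs <- (row$q3 - row$q1) / 1.349
      from_iqr <- TRUE
    }
    if (sd_abs == 0) next
    if (spec$family == "beta" && !from_iqr) {
      # the default relative spread is infeasible for probabilities near 1;
      # cap it at the beta-feasibility bound (user-supplied IQR spreads are
      # taken literally and error instead)
      m <- centre / spec$scale
      sd_abs <- min(sd_abs, 0.85 * sqrt(m * (1 - m)) * spec$scale)
    }
    seed_i <- .derive_seed(cfg$seed, params$country_code, draw_index, i)
    val <- with_seed(seed_i, {
      if (spec$family == "gamma") {
        .rgamma_mean_sd(centre, sd_abs)
      } else {
        spec$scale * .rbeta_mean_sd(centre / spec$scale, sd_abs / spec$scale)
      }
    })
    if (!is.null(spec$floor)) val <- max(spec$floor, val)
    out[[f]] <- val
  }
  # keep the severity split feasible after independent draws
  if (out$sswi_incidence + out$dswi_incidence > 100) {
    tot <- out$sswi_incidence + out$dswi_incidence
    out$sswi_incidence <- out$sswi_incidence * 100 / tot
    out$dswi_incidence <- out$dswi_incidence * 100 / tot
  }
  validate_country_parameters(out)
  out
}

#' Run the probabilistic sensitivity analysis for one country
#'
#' Each draw samples a full parameter set, recalibrates the incidence
#' curve, reruns the pathway model and its zero-hazard baseline, and
#' monetises the burden. Fully reproducible from the configuration seed.
#'
#' @param params Base-case [country_parameters()].
#' @param cfg A [psa_config()].
#' @param pathway_cfg A [pathway_config()].
#' @param curve Base [hill_params()] curve.
#' @return A data frame of class `psa_draws`, one row per draw, with
#'   columns `draw`, `total_cost`, `icu_days`, `gw_days`, `readmit_days`,
#'   `readmissions`, `swi_events`, `cost_per_swi`, `cost_per_cabg`,
#'   `r_swi`.
#' @export
run_psa <- function(params, cfg = psa_config(),
                    pathway_cfg = pathway_config(), curve = hill_params()) {
  rows <- lapply(seq_len(cfg$iterations), function(d) {
    p <- sample_parameters(params, cfg, d)
    res <- run_country(p, config = pathway_cfg, curve = curve)
    b <- compute_country_burden(res$events, p)
    data.frame(draw = d, total_cost = b$total_cost, icu_days = b$icu_days,
               gw_days = b$gw_days, readmit_days = b$readmit_days,
               readmissions = b$readmissions, swi_events = b$swi_events,
               cost_per_swi = b$cost_per_swi, cost_per_cabg = b$cost_per_cabg,
               r_swi = b$r_swi)
  })
  out <- do.call(rbind, rows)
  attr(out, "country_code") <- params$country_code
  class(out) <- c("psa_draws", class(out))
  out
}

#' Summarise PSA draws as median, range, IQR and SD
#'
#' @param draws A [run_psa()] data frame (or any data frame of numeric
#'   metric columns; a `draw` column is ignored).
#' @return Data frame with one row per metric: `median`, `min`, `max`,
#'   `q1`, `q3`, `sd`. Quartiles use the type-7 convention.
#' @export
summarize_psa <- function(draws) {
  stopifnot(nrow(draws) >= 2)
  metrics <- setdiff(names(draws), "draw")
  out <- do.call(rbind, lapply(metrics, function(m) {
    x <- draws[[m]]
    x <- x[!is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(metric = m, median = q[2], min = min(x), max = max(x),
               q1 = q[1], q3 = q[3], sd = stats::sd(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
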