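# Daily-cycle Markov cohort model of the CABG care pathway with SWI,
# readmission and death risks, plus a patient-level Monte-Carlo oracle.
#
# Internal state space (10 states). SWI care is tracked separately by the
# ward the patient was infected in, so that on recovery the patient resumes
# the interrupted baseline stay (geometric dwells are memoryless, so the
# resumed stay has the correct remaining expectation):
#   1 ICU_VENT  first ICU day(s), mechanically ventilated
#   2 ICU       intensive care, off ventilator
#   3 GW        general ward
#   4 HOME      discharged
#   5 S_ICU     superficial-SWI care, infected in ICU (returns to ICU)
#   6 D_ICU     deep-SWI care, infected in ICU (returns to ICU)
#   7 S_GW      superficial-SWI care, infected on the GW (returns to GW)
#   8 D_GW      deep-SWI care, infected on the GW (returns to GW)
#   9 READMIT   inpatient care for a post-discharge SWI
#  10 DEAD      absorbing
# The exported occupancy trace aggregates 5+7 -> SSWI_CARE and 6+8 ->
# DSWI_CARE, giving the 8 reported pathway states.

.states_internal <- c("ICU_VENT", "ICU", "GW", "HOME", "S_ICU", "D_ICU",
                      "S_GW", "D_GW", "READMIT", "DEAD")
.states_public <- c("ICU_VENT", "ICU", "GW", "HOME", "SSWI_CARE",
                    "DSWI_CARE", "READMIT", "DEAD")

#' Pathway model configuration
#'
#' @param horizon Model horizon in daily cycles (default 90).
#' @param vent_days Mean ventilated ICU days at the start of the stay
#'   (default 1); counted inside `baseline_icu_los`.
#' @param dswi_icu_fraction Fraction of deep-SWI care days accrued at ICU
#'   cost intensity (default 0.2); the rest accrue at general-ward
#'   intensity. Superficial-SWI and readmission care days accrue entirely
#'   at general-ward intensity.
#' @param dswi_case_fatality Probability that a deep SWI is fatal
#'   (default 0.15, the midpoint of reported 7--35\% in-hospital mortality).
#'   Converted internally to a per-cycle death probability competing with
#'   recovery. Superficial SWIs carry no excess mortality.
#' @return An object of class `pathway_config`.
#' @export
pathway_config <- function(horizon = 90, vent_days = 1,
                           dswi_icu_fraction = 0.2,
                           dswi_case_fatality = 0.15) {
  stopifnot(horizon >= 1, vent_days >= 1,
            dswi_icu_fraction >= 0, dswi_icu_fraction <= 1,
            dswi_case_fatality >= 0, dswi_case_fatality < 1)
  structure(list(horizon = as.integer(horizon), vent_days = vent_days,
                 dswi_icu_fraction = dswi_icu_fraction,
                 dswi_case_fatality = dswi_case_fatality),
            class = "pathway_config")
}

# Per-cycle death probability m such that, competing with a geometric
# recovery of rate p, the eventual case fatality is `cf`:
# P(death) = m / (m + (1 - m) p) = cf  =>  m = r p / (1 + r p), r = cf/(1-cf)
.fatality_to_cycle_prob <- function(cf, p_exit) {
  if (cf <= 0 || p_exit <= 0) return(0)
  r <- cf / (1 - cf)
  r * p_exit / (1 + r * p_exit)
}

.check_prob <- function(p, name) {
  if (!is.finite(p) || p < 0 || p > 1) {
    stop("derived per-cycle probability for `", name, "` is ", format(p),
         ", outside [0, 1]; check the input parameter")
  }
  p
}

#' Build the daily-cycle transition model for one country
#'
#' Baseline dwell times are geometric with the stated mean stay (exit
#' probability `1/mean`), so the expected uncomplicated pathway reproduces
#' `baseline_icu_los` and `baseline_gw_los`. Calibrated daily SWI hazards
#' are overlaid on every alive at-risk state; an SWI arising at home leads
#' to readmission with probability `readmit_prob_given_swi`. SWI care
#' dwells for the country's additional length of stay (readmission stay
#' included), after which the patient resumes the interrupted pathway.
#'
#' @param params A [country_parameters()] object (post-imputation).
#' @param inc A [calibrate_incidence()] object for the same country.
#' @param config A [pathway_config()].
#' @return An object of class `transition_model` containing the per-day
#'   transition array `T` (`horizon x 10 x 10`, rows summing to 1), the
#'   daily hazard vector, severity shares, and all derived per-cycle
#'   probabilities.
#' @export
build_transition_model <- function(params, inc, config = pathway_config()) {
  stopifnot(inherits(params, "country_parameters"),
            inherits(inc, "calibrated_incidence"),
            inherits(config, "pathway_config"))
  H <- config$horizon

  total <- params$sswi_incidence + params$dswi_incidence
  wd <- if (total > 0) params$dswi_incidence / total else 0
  ws <- 1 - wd

  ftab <- cumulative_fraction(0:H, inc)
  h <- (ftab[-1] - ftab[-(H + 1)]) / (1 - ftab[-(H + 1)])
  if (any(h < 0 | h >= 1)) stop("daily SWI hazard outside [0, 1)")

  p_vent <- .check_prob(1 / config$vent_days, "vent_days")
  icu_rest <- params$baseline_icu_los - config$vent_days
  if (icu_rest < 1) {
    stop("`baseline_icu_los` must exceed `vent_days` by at least 1 day")
  }
  p_icu <- .check_prob(1 / icu_rest, "baseline_icu_los")
  p_gw <- .check_prob(1 / params$baseline_gw_los, "baseline_gw_los")

  # SWI care dwells; an additional LOS of exactly 0 bypasses the care state
  # (the event is still counted) rather than spending a spurious day in it.
  care_dwell <- function(los, name) {
    if (los == 0) return(list(enabled = FALSE, p = 0))
    list(enabled = TRUE, p = .check_prob(1 / los, name))
  }
  sw <- care_dwell(params$extra_los_sswi, "extra_los_sswi")
  dw <- care_dwell(params$extra_los_dswi, "extra_los_dswi")
  readmit_los <- ws * params$extra_los_sswi + wd * params$extra_los_dswi
  rm_ <- care_dwell(readmit_los, "readmission stay (severity-weighted extra LOS)")

  m_d <- .fatality_to_cycle_prob(config$dswi_case_fatality, dw$p)
  # readmitted cohort is a severity mixture; expected fatality wd * cf
  m_r <- .fatality_to_cycle_prob(wd * config$dswi_case_fatality, rm_$p)

  r_re <- params$readmit_prob_given_swi

  Tarr <- array(0, dim = c(H, 10, 10),
                dimnames = list(NULL, .states_internal, .states_internal))
  for (t in seq_len(H)) {
    ht <- h[t]
    hs <- if (sw$enabled) ws * ht else 0
    hd <- if (dw$enabled) wd * ht else 0
    stayflow <- 1 - hs - hd  # share that continues the baseline flow
    M <- matrix(0, 10, 10)
    # ICU_VENT: infection diverts to ICU-origin care, else wean to ICU
    M[1, 5] <- hs; M[1, 6] <- hd
    M[1, 2] <- stayflow * p_vent; M[1, 1] <- stayflow * (1 - p_vent)
    # ICU
    M[2, 5] <- hs; M[2, 6] <- hd
    M[2, 3] <- stayflow * p_icu; M[2, 2] <- stayflow * (1 - p_icu)
    # GW
    M[3, 7] <- hs; M[3, 8] <- hd
    M[3, 4] <- stayflow * p_gw; M[3, 3] <- stayflow * (1 - p_gw)
    # HOME: onset h; readmitted fraction moves to READMIT, the rest are
    # treated as outpatients and remain home (events counted separately)
    p_home_readmit <- if (rm_$enabled) ht * r_re else 0
    M[4, 9] <- p_home_readmit; M[4, 4] <- 1 - p_home_readmit
    # SSWI care (no excess mortality), return to ward of origin
    M[5, 2] <- sw$p; M[5, 5] <- 1 - sw$p
    M[7, 3] <- sw$p; M[7, 7] <- 1 - sw$p
    # DSWI care: death competes with recovery
    M[6, 10] <- m_d; M[6, 2] <- (1 - m_d) * dw$p
    M[6, 6] <- 1 - m_d - (1 - m_d) * dw$p
    M[8, 10] <- m_d; M[8, 3] <- (1 - m_d) * dw$p
    M[8, 8] <- 1 - m_d - (1 - m_d) * dw$p
    # READMIT: severity-mixture care at GW intensity, discharge home
    M[9, 10] <- m_r; M[9, 4] <- (1 - m_r) * rm_$p
    M[9, 9] <- 1 - m_r - (1 - m_r) * rm_$p
    # DEAD absorbing
    M[10, 10] <- 1
    if (max(abs(rowSums(M) - 1)) > 1e-12) {
      stop("internal error: transition rows do not sum to 1 on day ", t)
    }
    Tarr[t, , ] <- M
  }

  structure(list(
    states = .states_public, states_internal = .states_internal,
    T = Tarr, horizon = H, h = h, ws = ws, wd = wd,
    p_vent = p_vent, p_icu = p_icu, p_gw = p_gw,
    p_sswi = sw$p, sswi_enabled = sw$enabled,
    p_dswi = dw$p, dswi_enabled = dw$enabled,
    p_readmit_exit = rm_$p, readmit_enabled = rm_$enabled,
    m_dswi = m_d, m_readmit = m_r,
    readmit_prob = r_re, dswi_icu_fraction = config$dswi_icu_fraction,
    params = params, config = config
  ), class = "transition_model")
}

#' Run the deterministic cohort model
#'
#' Propagates state-occupancy fractions forward over the horizon, starting
#' with the whole cohort in ventilated ICU on day 0, and accumulates care
#' days (a state occupied at the start of a cycle contributes one day),
#' SWI events by severity and setting, readmissions and deaths. All
#' accumulators are scaled by `volume`.
#'
#' @param model A [build_transition_model()] object.
#' @param volume Number of procedures the cohort represents (>= 0).
#' @return An object of class `cohort_trace` with the `horizon + 1` by 8
#'   `occupancy` matrix (fractions; rows sum to 1) and named accumulators:
#'   `icu_days`, `gw_days`, `readmit_days`, `sswi_events`, `dswi_events`,
#'   `inpatient_swi_events`, `postdischarge_swi_events`, `readmissions`,
#'   `deaths`.
#' @export
run_cohort <- function(model, volume = 1) {
  stopifnot(inherits(model, "transition_model"), volume >= 0)
  H <- model$horizon
  occ <- matrix(0, H + 1, 10, dimnames = list(NULL, model$states_internal))
  occ[1, 1] <- 1
  icu_days <- gw_days <- readmit_days <- 0
  sswi <- dswi <- inpat <- postd <- readm <- 0
  fr <- model$dswi_icu_fraction
  for (t in seq_len(H)) {
    prev <- unname(occ[t, ])
    # day counting: state at the start of cycle t contributes one day
    icu_days <- icu_days + prev[1] + prev[2] + fr * (prev[6] + prev[8])
    gw_days <- gw_days + prev[3] + prev[5] + prev[7] +
      (1 - fr) * (prev[6] + prev[8])
    readmit_days <- readmit_days + prev[9]
    # event counting from hazard exposure (includes outpatient home onsets)
    at_risk_ip <- prev[1] + prev[2] + prev[3]
    onset_ip <- model$h[t] * at_risk_ip
    onset_home <- model$h[t] * prev[4]
    sswi <- sswi + model$ws * (onset_ip + onset_home)
    dswi <- dswi + model$wd * (onset_ip + onset_home)
    inpat <- inpat + onset_ip
    postd <- postd + onset_home
    readm <- readm + model$readmit_prob * onset_home
    nxt <- as.vector(prev %*% model$T[t, , ])
    if (abs(sum(nxt) - 1) > 1e-9) {
      stop("cohort mass not conserved at cycle ", t)
    }
    occ[t + 1, ] <- nxt
  }
  pub <- cbind(occ[, 1:4, drop = FALSE],
               SSWI_CARE = occ[, 5] + occ[, 7],
               DSWI_CARE = occ[, 6] + occ[, 8],
               occ[, 9:10, drop = FALSE])
  colnames(pub) <- .states_public
  structure(list(
    occupancy = pub, occupancy_internal = occ,
    horizon = H, volume = volume,
    icu_days = volume * icu_days, gw_days = volume * gw_days,
    readmit_days = volume * readmit_days,
    sswi_events = volume * sswi, dswi_events = volume * dswi,
    inpatient_swi_events = volume * inpat,
    postdischarge_swi_events = volume * postd,
    readmissions = volume * readm,
    deaths = volume * unname(occ[H + 1, 10])
  ), class = "cohort_trace")
}

#' Patient-level Monte-Carlo oracle for the cohort engine
#'
#' Samples `n` individual trajectories from the same per-day transition
#' probabilities as [run_cohort()], via an independent event-by-event code
#' path. Accumulator means converge to the cohort values; the returned
#' per-patient matrices permit standard-error comparisons.
#'
#' @param model A [build_transition_model()] object.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `totals` (named sums over patients, comparable to a
#'   `volume = n` cohort run) and `per_patient` (an `n` by 9 matrix of
#'   per-patient accumulators).
#' @export
simulate_patients <- function(model, n, seed) {
  stopifnot(inherits(model, "transition_model"), n >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  H <- model$horizon
  fr <- model$dswi_icu_fraction
  s <- rep(1L, n)  # everyone starts ventilated in ICU
  acc <- matrix(0, n, 9, dimnames = list(NULL, c(
    "icu_days", "gw_days", "readmit_days", "sswi_events", "dswi_events",
    "inpatient_swi_events", "postdischarge_swi_events", "readmissions",
    "deaths")))
  for (t in seq_len(H)) {
    # day accrual for the state occupied at the start of the cycle
    in_icu <- s == 1L | s == 2L
    in_dcare <- s == 6L | s == 8L
    acc[in_icu, "icu_days"] <- acc[in_icu, "icu_days"] + 1
    acc[in_dcare, "icu_days"] <- acc[in_dcare, "icu_days"] + fr
    in_gw <- s == 3L | s == 5L | s == 7L
    acc[in_gw, "gw_days"] <- acc[in_gw, "gw_days"] + 1
    acc[in_dcare, "gw_days"] <- acc[in_dcare, "gw_days"] + (1 - fr)
    acc[s == 9L, "readmit_days"] <- acc[s == 9L, "readmit_days"] + 1

    ht <- model$h[t]
    u <- stats::runif(n); usev <- stats::runif(n); uex <- stats::runif(n)
    ns <- s

    # at-risk inpatient states: onset, then severity, else baseline flow;
    # onsets whose care state is bypassed (extra LOS 0) continue the flow
    for (st in c(1L, 2L, 3L)) {
      idx <- which(s == st)
      if (!length(idx)) next
      onset <- u[idx] < ht
      oi <- idx[onset]
      bypass <- integer(0)
      if (length(oi)) {
        deep <- usev[oi] < model$wd
        acc[oi[deep], "dswi_events"] <- acc[oi[deep], "dswi_events"] + 1
        acc[oi[!deep], "sswi_events"] <- acc[oi[!deep], "sswi_events"] + 1
        acc[oi, "inpatient_swi_events"] <- acc[oi, "inpatient_swi_events"] + 1
        care_s <- if (st == 3L) 7L else 5L
        care_d <- if (st == 3L) 8L else 6L
        if (model$dswi_enabled) ns[oi[deep]] <- care_d else
          bypass <- c(bypass, oi[deep])
        if (model$sswi_enabled) ns[oi[!deep]] <- care_s else
          bypass <- c(bypass, oi[!deep])
      }
      mv <- c(idx[!onset], bypass)
      if (length(mv)) {
        p_exit <- switch(st, model$p_vent, model$p_icu, model$p_gw)
        ex <- uex[mv] < p_exit
        ns[mv[ex]] <- st + 1L
      }
    }
    # HOME: onset, readmission decision
    idx <- which(s == 4L)
    if (length(idx)) {
      oi <- idx[u[idx] < ht]
      if (length(oi)) {
        deep <- usev[oi] < model$wd
        acc[oi[deep], "dswi_events"] <- acc[oi[deep], "dswi_events"] + 1
        acc[oi[!deep], "sswi_events"] <- acc[oi[!deep], "sswi_events"] + 1
        acc[oi, "postdischarge_swi_events"] <-
          acc[oi, "postdischarge_swi_events"] + 1
        re <- stats::runif(length(oi)) < model$readmit_prob
        acc[oi[re], "readmissions"] <- acc[oi[re], "readmissions"] + 1
        if (model$readmit_enabled) ns[oi[re]] <- 9L
      }
    }
    # care states: death (deep / readmit mixture) competing with recovery
    care_spec <- list(
      list(st = 5L, m = 0, p = model$p_sswi, back = 2L),
      list(st = 7L, m = 0, p = model$p_sswi, back = 3L),
      list(st = 6L, m = model$m_dswi, p = model$p_dswi, back = 2L),
      list(st = 8L, m = model$m_dswi, p = model$p_dswi, back = 3L),
      list(st = 9L, m = model$m_readmit, p = model$p_readmit_exit, back = 4L))
    for (cs in care_spec) {
      idx <- which(s == cs$st)
      if (!length(idx)) next
      die <- u[idx] < cs$m
      ns[idx[die]] <- 10L
      rest <- idx[!die]
      rec <- uex[rest] < cs$p
      ns[rest[rec]] <- cs$back
    }
    s <- ns
  }
  acc[, "deaths"] <- as.numeric(s == 10L)
  list(totals = colSums(acc), per_patient = acc)
}

#' Summarise SWI events and excess resource use against a baseline run
#'
#' Compares an SWI-bearing cohort trace with a matching zero-hazard
#' baseline trace of the same country and horizon. Excess days are the
#' difference of the two runs; readmission days occur only under SWI risk.
#' The hospital SWI rate `r_swi` is the inpatient event rate plus the
#' readmission rate, per procedure.
#'
#' @param trace A [run_cohort()] trace with SWI hazards active.
#' @param baseline A matching trace run with zero SWI hazard.
#' @param params The [country_parameters()] behind both runs.
#' @return An object of class `swi_events`: totals (`swi_events`,
#'   `sswi_events`, `dswi_events`, `readmissions`, `deaths`), excess days
#'   (`excess_icu_days`, `excess_gw_days`, `readmit_days`), and rates per
#'   procedure (`inpatient_rate`, `readmission_rate`, `r_swi`).
#' @export
extract_events <- function(trace, baseline, params) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(baseline, "cohort_trace"))
  if (trace$horizon != baseline$horizon) {
    stop("trace and baseline horizons differ")
  }
  if (trace$volume != baseline$volume) {
    stop("trace and baseline volumes differ")
  }
  vol <- trace$volume
  inpatient_rate <- if (vol > 0) trace$inpatient_swi_events / vol else 0
  readmission_rate <- if (vol > 0) trace$readmissions / vol else 0
  structure(list(
    country_code = params$country_code,
    volume = vol,
    swi_events = trace$sswi_events + trace$dswi_events,
    sswi_events = trace$sswi_events,
    dswi_events = trace$dswi_events,
    inpatient_swi_events = trace$inpatient_swi_events,
    postdischarge_swi_events = trace$postdischarge_swi_events,
    readmissions = trace$readmissions,
    deaths = trace$deaths,
    excess_icu_days = trace$icu_days - baseline$icu_days,
    excess_gw_days = trace$gw_days - baseline$gw_days,
    readmit_days = trace$readmit_days,
    inpatient_rate = inpatient_rate,
    readmission_rate = readmission_rate,
    r_swi = inpatient_rate + readmission_rate
  ), class = "swi_events")
}

#' Run the full pathway for one country: calibrate, simulate, difference
#'
#' Convenience wrapper: calibrates the incidence curve to the country's
#' total SWI incidence, builds the transition model, runs the SWI and
#' zero-hazard baseline cohorts at the country's procedure volume, and
#' extracts the event summary.
#'
#' @param params A [country_parameters()] object.
#' @param config A [pathway_config()].
#' @param curve Base [hill_params()] incidence curve.
#' @param reference_day Calibration day (default 30).
#' @return List with `events` ([extract_events()] output), `trace`,
#'   `baseline`, and `incidence` (the calibrated curve).
#' @export
run_country <- function(params, config = pathway_config(),
                        curve = hill_params(), reference_day = 30) {
  total <- params$sswi_incidence + params$dswi_incidence
  inc <- calibrate_incidence(params$country_code, total, curve, reference_day)
  model <- build_transition_model(params, inc, config)
  trace <- run_cohort(model, volume = params$cabg_per_year)
  inc0 <- calibrate_incidence(params$country_code, 0, curve, reference_day)
  model0 <- build_transition_model(params, inc0, config)
  baseline <- run_cohort(model0, volume = params$cabg_per_year)
  list(events = extract_events(trace, baseline, params),
       trace = trace, baseline = baseline, incidence = inc)
}
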