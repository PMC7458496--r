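# Value-based purchasing calculator: affordable cost of intervention per
# patient (CIPP), contingent per-intervention VBP payment, and hospital
# savings, plus the two standard purchasing scenarios.

#' Define a value-based purchasing scenario
#'
#' A hospital allocates a share of its expected SWI cost burden to
#' purchasing preventive interventions, and additionally commits a share of
#' realised savings as a contingent payment (the VBP) that is paid only if
#' an intervention meets its effectiveness target.
#'
#' @param rr_with_intervention Relative risk of SWI events with the
#'   intervention in place, in \[0, 1\] (e.g. 0.8 for a 20\% reduction).
#' @param share_purchase Share of the expected SWI cost allocated to
#'   purchasing, percent (0--100).
#' @param n_interventions Number of interventions the funds are split
#'   across (>= 1).
#' @param share_savings Share of realised savings committed as the
#'   contingent payment, percent (0--100).
#' @param n_patients Annual CABG volume of the hospital (>= 1).
#' @param cost_per_swi Expected cost of one SWI, US$.
#' @param swi_rate Hospital SWI rate (inpatient events plus readmissions),
#'   fraction per procedure.
#' @return An object of class `vbp_scenario`.
#' @export
vbp_scenario <- function(rr_with_intervention, share_purchase,
                         n_interventions, share_savings, n_patients,
                         cost_per_swi, swi_rate) {
  s <- list(rr_with_intervention = rr_with_intervention,
            share_purchase = share_purchase,
            n_interventions = n_interventions,
            share_savings = share_savings,
            n_patients = n_patients,
            cost_per_swi = cost_per_swi,
            swi_rate = swi_rate)
  if (rr_with_intervention < 0 || rr_with_intervention > 1) {
    stop("`rr_with_intervention` must be in [0, 1]")
  }
  for (f in c("share_purchase", "share_savings")) {
    if (s[[f]] < 0 || s[[f]] > 100) stop("`", f, "` must be in [0, 100] percent")
  }
  if (n_interventions < 1) stop("`n_interventions` must be >= 1")
  if (n_patients < 1) stop("`n_patients` must be >= 1")
  if (cost_per_swi < 0) stop("`cost_per_swi` must be >= 0")
  if (swi_rate < 0 || swi_rate > 1) stop("`swi_rate` must be a fraction in [0, 1]")
  structure(s, class = "vbp_scenario")
}

#' Affordable cost of intervention per patient (CIPP)
#'
#' \deqn{CIPP = \frac{(1 - RR)\, C^{SWI} r^{SWI}\, (S_{PUR}/100)}{N_{INT}}}
#' the expected per-patient SWI cost averted by the intervention, scaled by
#' the purchasing share and split across the interventions considered.
#'
#' @param s A [vbp_scenario()].
#' @return CIPP in US$ per patient.
#' @export
compute_cipp <- function(s) {
  stopifnot(inherits(s, "vbp_scenario"))
  (1 - s$rr_with_intervention) * s$cost_per_swi * s$swi_rate *
    (s$share_purchase / 100) / s$n_interventions
}

#' Contingent per-intervention VBP payment
#'
#' \deqn{VBP = \frac{r^{SWI} N^{PT} C^{SWI} (1 - RR) - CIPP\, N_{INT} N^{PT}}
#'   {100\, N_{INT}} \, S_{SAV}}
#' the savings remaining after the purchase cost, shared at `share_savings`
#' percent and split per intervention. Paid only if the intervention meets
#' its target; negative values (price above break-even) are reported with a
#' warning, not clamped.
#'
#' @param s A [vbp_scenario()].
#' @param cipp Cost of intervention per patient; defaults to
#'   [compute_cipp()] of the same scenario.
#' @return VBP payment in US$ per intervention.
#' @export
compute_vbp <- function(s, cipp = compute_cipp(s)) {
  stopifnot(inherits(s, "vbp_scenario"))
  bracket <- s$swi_rate * s$n_patients * s$cost_per_swi *
    (1 - s$rr_with_intervention) - cipp * s$n_interventions * s$n_patients
  v <- bracket / (100 * s$n_interventions) * s$share_savings
  if (v < 0) {
    warning("negative VBP payment: intervention priced above break-even")
  }
  v
}

#' Annual hospital savings under a VBP agreement
#'
#' Gross savings from the averted SWIs, minus the purchase cost
#' (`CIPP x n_interventions x n_patients`), minus the contingent payouts
#' (`n_interventions x vbp_payment`). Value is conserved: savings plus
#' payouts plus purchase cost equals gross savings exactly.
#'
#' @param s A [vbp_scenario()].
#' @param cipp Cost of intervention per patient.
#' @param vbp_payment Per-intervention VBP payment.
#' @return Hospital savings in US$ per year.
#' @export
hospital_savings <- function(s, cipp = compute_cipp(s),
                             vbp_payment = compute_vbp(s, cipp)) {
  stopifnot(inherits(s, "vbp_scenario"))
  gross <- s$swi_rate * s$n_patients * s$cost_per_swi *
    (1 - s$rr_with_intervention)
  purchase <- cipp * s$n_interventions * s$n_patients
  gross - purchase - s$n_interventions * vbp_payment
}

#' Run all VBP components for one scenario
#'
#' @param s A [vbp_scenario()].
#' @return An object of class `vbp_result`: `cipp`, `vbp_payment`,
#'   `gross_savings`, `purchase_cost`, `hospital_savings`.
#' @export
run_vbp <- function(s) {
  cipp <- compute_cipp(s)
  vbp <- compute_vbp(s, cipp)
  gross <- s$swi_rate * s$n_patients * s$cost_per_swi *
    (1 - s$rr_with_intervention)
  purchase <- cipp * s$n_interventions * s$n_patients
  structure(list(cipp = cipp, vbp_payment = vbp, gross_savings = gross,
                 purchase_cost = purchase,
                 hospital_savings = gross - purchase - s$n_interventions * vbp),
            class = "vbp_result")
}

#' Constants of the two standard purchasing scenarios
#'
#' Scenario 1: 50\% of the cost burden funds two interventions, with a 15\%
#' savings share on success. Scenario 2: 30\% of the burden funds two
#' interventions, with a 25\% savings share. Both target a 20\% reduction
#' in the SWI rate (relative risk 0.8) at a hospital performing 1000 CABG
#' procedures per year.
#'
#' @param scenario_id 1 or 2.
#' @return List with `share_purchase`, `n_interventions`, `share_savings`,
#'   `rr_with_intervention`, `n_patients`.
#' @export
scenario_constants <- function(scenario_id) {
  if (!scenario_id %in% c(1, 2)) stop("`scenario_id` must be 1 or 2")
  if (scenario_id == 1) {
    list(share_purchase = 50, n_interventions = 2, share_savings = 15,
         rr_with_intervention = 0.8, n_patients = 1000)
  } else {
    list(share_purchase = 30, n_interventions = 2, share_savings = 25,
         rr_with_intervention = 0.8, n_patients = 1000)
  }
}

#' Run a purchasing scenario over PSA draws
#'
#' Applies the scenario constants to every draw's cost per SWI and SWI
#' rate, computing CIPP, VBP payment and hospital savings per draw, and
#' summarises each as median and range.
#'
#' @param scenario_id 1 or 2 (see [scenario_constants()]), or a list of
#'   custom constants in the same shape.
#' @param draws Data frame with columns `cost_per_swi` and `r_swi`, one row
#'   per PSA draw (see [run_psa()]).
#' @return List with `per_draw` (data frame of cipp, vbp_payment,
#'   hospital_savings per draw) and `summary` (median, min, max for each).
#' @export
run_scenario <- function(scenario_id, draws) {
  const <- if (is.list(scenario_id) && !is.null(scenario_id$share_purchase)) {
    scenario_id
  } else {
    scenario_constants(scenario_id)
  }
  stopifnot(all(c("cost_per_swi", "r_swi") %in% names(draws)), nrow(draws) >= 1)
  per_draw <- do.call(rbind, lapply(seq_len(nrow(draws)), function(i) {
    s <- vbp_scenario(
      rr_with_intervention = const$rr_with_intervention,
      share_purchase = const$share_purchase,
      n_interventions = const$n_interventions,
      share_savings = const$share_savings,
      n_patients = const$n_patients,
      cost_per_swi = draws$cost_per_swi[i],
      swi_rate = draws$r_swi[i])
    r <- run_vbp(s)
    data.frame(cipp = r$cipp, vbp_payment = r$vbp_payment,
               hospital_savings = r$hospital_savings)
  }))
  summ <- lapply(per_draw, function(x) {
    c(median = stats::median(x), min = min(x), max = max(x))
  })
  list(per_draw = per_draw, summary = summ)
}
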