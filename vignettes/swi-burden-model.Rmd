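---
title: "Modelling the burden of sternal-wound infections after CABG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the burden of sternal-wound infections after CABG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swiburden)
```

## The problem

Sternal-wound infections (SWIs) after coronary artery bypass graft (CABG)
surgery are rare but expensive: they prolong intensive-care (ICU) and
general-ward (GW) stays, trigger readmissions, and — in their deep form
(DSWI, the mediastinitis spectrum) — carry substantial mortality. Hospitals
weighing preventive interventions need two numbers per setting: what an SWI
costs, and what they can therefore afford to pay for prevention.
`swiburden` estimates both. It propagates a cohort of CABG patients through
a daily-cycle Markov model of the care pathway, monetises the excess
resource use in 2017 US$, quantifies parameter uncertainty by probabilistic
sensitivity analysis (PSA), and converts the burden into value-based
purchasing (VBP) prices for risk-sharing contracts.

## Cumulative incidence: Hill curve and country calibration

Cumulative SWI incidence over days since surgery follows a saturating Hill
dose-response curve

$$F(t) = \alpha + \frac{\theta\, t^{\eta}}{\kappa^{\eta} + t^{\eta}},$$

in percent of patients, with defaults $\alpha = 2.96\times 10^{-30}$,
$\theta = 6.93$, $\eta = 1.08$, $\kappa = 23.73$ days. The offset is
effectively zero; the asymptote is $\alpha + \theta \approx 6.93\%$ and the
half-maximum sits near day 24. The curve shape is taken as common across
settings; each country rescales it multiplicatively so that the curve
reproduces that country's observed total SWI incidence at a reference day
(30 by default, the day at which national incidences are typically
reported):

```{r}
hill_cumulative(30)                 # base curve at day 30, percent
calibration_factor(2.4, 4.8)        # observed 2.4% where curve gives 4.8%
inc <- calibrate_incidence("NLD", 10.4)
inc$scale_factor
```

The calibrated cumulative fraction is converted to daily conditional
probabilities for the Markov model by
$h(t) = \{F(t) - F(t\!-\!1)\}/\{1 - F(t\!-\!1)\}$; the product identity
$1 - \prod_{s \le t}(1 - h(s)) = \{F(t)-F(0)\}/\{1-F(0)\}$ holds to
machine precision and is enforced in the tests. The severity split is a
time-constant proportion: deep SWIs are `dswi_incidence / total` of every
day's hazard (no severity-specific timing is available to justify more).

## The care-pathway model

Patients enter at surgery into ventilated ICU, are weaned (1 day by
default), recover in ICU, move to the general ward, and go home. At all
times alive and not already infected they face the daily SWI hazard. The
reported state space is `ICU_VENT, ICU, GW, HOME, SSWI_CARE, DSWI_CARE,
READMIT, DEAD`.

Dwell times are geometric with mean equal to the stated length of stay
(exit probability $1/\text{mean}$), so a 5-day ward stay gives a 0.8
self-loop — the convention that makes expected stays match the input LOS
exactly. An SWI diverts the patient to a care state that dwells for the
country's *additional* LOS (superficial or deep), after which the patient
**resumes the interrupted stay**. Internally the care states are split by
ward of infection so that resumption returns to the right place; because
geometric dwells are memoryless, the resumed stay has exactly the correct
remaining expectation, and the excess over a zero-hazard baseline run
equals the additional LOS per event (up to horizon truncation — see
below). The exported occupancy trace aggregates the internal split back to
the eight states above.

An SWI arising at home leads to readmission with the country's readmission
probability; the readmission stay is the severity-mixture mean of the two
additional-LOS values (readmission LOS is treated as *included* in the
additional LOS, not added to it), accrued at general-ward intensity.
Post-discharge SWIs that do not readmit are counted as events but accrue
no inpatient burden — superficial infections managed with outpatient wound
care. Deep-SWI care days are split 20% ICU / 80% GW by default; deep-SWI
care carries a per-cycle death probability calibrated so that the eventual
case fatality, competing with geometric recovery, equals 15% — the midpoint
of the widely cited 7–35% range; superficial SWIs and all other states
carry no excess mortality by default.

```{r}
p <- country_parameters("ESP", cabg_per_year = 8294,
                        sswi_incidence = 3.2, dswi_incidence = 1.2,
                        readmit_prob_given_swi = 0.3,
                        extra_los_sswi = 4, extra_los_dswi = 20,
                        icu_cost_per_day = 1500, gw_cost_per_day = 500,
                        baseline_icu_los = 3, baseline_gw_los = 7)
res <- run_country(p)
unlist(res$events[c("swi_events", "readmissions", "excess_gw_days", "r_swi")])
```

Every country run is differenced against a zero-hazard baseline of the
same cohort, which is what makes the burden *attributable*: excess ICU and
GW days, readmission days, events by severity and setting, and deaths.

### The patient-level oracle

`simulate_patients()` samples individual trajectories from the same
transition probabilities through an independent event-by-event code path.
It exists to validate the cohort engine: accumulator totals agree within
Monte-Carlo error (the tests require 4 standard errors at $n = 50\,000$),
and it would expose any structural disagreement between the written
transition matrix and the intended event logic.

## Costing and aggregation

The burden of one country is
`excess_icu_days × icu_cost + excess_gw_days × gw_cost +
readmit_days × gw_cost` (an ICU share for readmission stays is
configurable), with cost per SWI and cost per CABG as the defining ratios;
cost per SWI is reported as missing, never zero, when there are no events.
Cross-country aggregation sums totals and reports median/IQR/min/max of
the ratios. All quartiles in the package use linear interpolation between
order statistics (R's type 7) — the convention is pinned because no source
states one — and aggregation always runs on unrounded values.

## Input handling

A country enters the analysis when at least 5 of the 10 canonical
parameters (procedure volume, the two incidences, readmission probability,
the two additional LOS, the two daily costs, the two baseline stays) were
identified. Where several studies report one field, the midpoint of the
reported range, $(\min + \max)/2$, is used — the most literal reading of a
"midpoint" over multiple studies, with the mean available as an option.
Remaining gaps are filled with the cross-country median, and the field's
cross-country IQR is attached as that cell's uncertainty range for the
PSA. Monetary inputs are converted to 2017 US$ by dividing by a
user-supplied mid-2017 market exchange rate; no rates are bundled.

## Probabilistic sensitivity analysis

The PSA reruns calibration, pathway and costing end-to-end per draw
(52 iterations by default — kept as a configurable default, not a
constant). Costs and lengths of stay draw from gamma distributions,
probabilities and incidences from beta distributions, each with mean equal
to the point estimate; the default spread is SD = 20% of the mean, a
conventional choice in the absence of reported uncertainty. Imputed fields
instead use their stored IQR as the central 50% interval
(SD = IQR/1.349). Each (country, draw, field) triple has its own derived
random substream, so adding a field never perturbs the other fields'
draws and results are bit-reproducible from the base seed. Numerical
guards: LOS draws are floored at the model's validity minimum (1 day; a
2-day baseline ICU stay so the ventilated first day fits), probability
draws near 1 cap the default spread at the beta-feasibility bound, and
procedure volume is not sampled by default.

## Value-based purchasing

With $RR$ the relative risk of SWI under the intervention, $C^{SWI}$ the
cost per SWI, $r^{SWI}$ the hospital SWI rate (inpatient events plus
readmissions), $S_{PUR}$ the percent of the expected burden allocated to
purchasing, $N_{INT}$ the number of interventions, $N^{PT}$ the annual
volume and $S_{SAV}$ the percent of savings shared on success:

$$CIPP = \frac{(1-RR)\, C^{SWI} r^{SWI} \, (S_{PUR}/100)}{N_{INT}}, \qquad
VBP = \frac{r^{SWI} N^{PT} C^{SWI} (1-RR) - CIPP\, N_{INT} N^{PT}}
{100\, N_{INT}}\, S_{SAV}.$$

These reconstructions are validated to the cent against the published
worked example (CIPP US\$16.81, VBP US\$14 121.84 for a 1200-procedure
hospital with $r^{SWI}=0.056$, $C^{SWI}=12\,008$, $RR=0.75$, three
interventions, both shares 30%). Value is conserved exactly: hospital
savings + payouts + purchase cost = gross savings; a price above
break-even yields a negative contingent payment, which is reported with a
warning, never clamped. Two standard scenarios are built in (both: two
interventions, $RR=0.8$, 1000 procedures/yr): scenario 1 with
$S_{PUR}=50$, $S_{SAV}=15$; scenario 2 with $S_{PUR}=30$, $S_{SAV}=25$.

```{r}
s <- vbp_scenario(rr_with_intervention = 0.75, share_purchase = 30,
                  n_interventions = 3, share_savings = 30,
                  n_patients = 1200, cost_per_swi = 12008, swi_rate = 0.056)
unlist(run_vbp(s))
```

## The synthetic country generator

No per-country input set is bundled, so `generate_country_table()` draws
complete, reproducible tables whose ranges mirror the published extremes
for mature health-care systems: CABG rates 6.4–61.4 per 100 000, total SWI
incidence 2.8–10.4%, deep-SWI incidence 0.8–3.4% (capped at 80% of the
total so both severities occur), additional superficial stays 2–49 days
(deep 5–66), daily costs spanning roughly an order of magnitude
(ICU 800–10 000, GW 250–2500 US$, log-uniform as is natural for costs;
other fields uniform — the least-assuming emulation when only extremes are
known). Missingness (10% per field by default, matching roughly one hole
in ten in the real extraction) is applied after generation, and the
pre-masking table is returned so imputation can be scored. The generator
deliberately does **not** emulate inter-parameter correlations across
countries (unknown), so passing tests demonstrate engine correctness and
plausibility of magnitudes, not distributional fidelity to any real
country set.

## Numerical choices and problem sizes

- Cycle length 1 day; horizon 90 days. $\kappa = 23.73$ puts the curve's
  half-maximum near day 24, so 90 days captures the large majority of the
  asymptote. Long deep-SWI stays (up to 66 days) are truncated by the
  horizon; extend `pathway_config(horizon = )` for such settings.
- Conservation is asserted at every cycle (occupancy row sums within
  1e-9); derived per-cycle probabilities outside [0, 1] are errors naming
  the offending parameter, not silent clamps.
- Returning SWI survivors to their ward of origin slightly *inflates* the
  in-hospital time relative to baseline (the interrupted stay restarts
  memorylessly, adding roughly the stay length times the daily hazard —
  well under 1% at observed hazards); this is the price of keeping excess
  days equal to the stated additional LOS, and is reported as part of the
  attributable burden.
- Patients back home after a resolved SWI remain exposed to the (small)
  residual hazard; the cohort engine counts events, not distinct patients.
- Test and validation sizes: the Monte-Carlo oracle runs at
  $n = 50\,000$ patients, conservation checks over 100 random models,
  calibration recovery over 200 binomial replicates of $10^5$ patients,
  VBP conservation over 1000 random scenarios — sizes at which the
  binomial standard errors make the assertions sharp.

## Known limitations

Patient-level risk factors (obesity, diabetes) are not modelled beyond
what country-level incidence encodes; the care pathway is assumed
identical across settings; readmission care is costed at ward rates by
default; the 90-day horizon truncates the longest deep-SWI stays; and the
bundled reference burden table is used only for aggregation-identity
checks — the package does not claim to reproduce those per-country rows
from first principles, because the underlying country inputs are not
publicly deposited.
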