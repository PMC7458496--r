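# Cumulative SWI incidence: Hill dose-response curve, country calibration,
# and conversion to per-cycle hazards for the Markov pathway.

#' Hill-curve parameters for cumulative SWI incidence
#'
#' The cumulative incidence of sternal-wound infection (SWI) over days since
#' surgery is modelled with a saturating Hill dose-response curve
#' \deqn{F(t) = \alpha + \frac{\theta t^\eta}{\kappa^\eta + t^\eta}}
#' where the output is the percentage of patients with an SWI by day \eqn{t}.
#' The defaults are the curve fitted to pooled post-CABG surveillance data:
#' the asymptote \eqn{\alpha + \theta} is about 6.93\% and the half-maximum
#' is reached near day 24.
#'
#' @param alpha Curve offset at day 0, in percent. Effectively zero by
#'   default (`2.96e-30`).
#' @param theta Asymptotic amplitude, in percent of patients.
#' @param eta Dimensionless shape (steepness) parameter.
#' @param kappa Day at which half of `theta` is reached.
#' @return An object of class `hill_params`.
#' @examples
#' p <- hill_params()
#' hill_cumulative(23.73, p) # half-maximum: alpha + theta/2 = 3.465
#' @export
hill_params <- function(alpha = 2.96e-30, theta = 6.93, eta = 1.08,
                        kappa = 23.73) {
  stopifnot(is.numeric(alpha), is.numeric(theta), is.numeric(eta),
            is.numeric(kappa))
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (theta <= 0) stop("`theta` must be > 0")
  if (eta <= 0) stop("`eta` must be > 0")
  if (kappa <= 0) stop("`kappa` must be > 0")
  structure(list(alpha = alpha, theta = theta, eta = eta, kappa = kappa),
            class = "hill_params")
}

#' Cumulative SWI incidence at a given day
#'
#' Evaluates the Hill curve at `t` days post-surgery. The result is a
#' percentage of patients (0-100 scale), monotone non-decreasing in `t` and
#' bounded above by `alpha + theta`.
#'
#' @param t Days post-surgery, numeric vector, all >= 0.
#' @param params A [hill_params()] object.
#' @return Cumulative SWI incidence in percent, same length as `t`.
#' @export
hill_cumulative <- function(t, params = hill_params()) {
  if (!inherits(params, "hill_params")) stop("`params` must be hill_params")
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("days post-surgery `t` must be finite and >= 0")
  }
  tp <- t^params$eta
  params$alpha + params$theta * tp / (params$kappa^params$eta + tp)
}

#' Country calibration factor for the incidence curve
#'
#' The base curve is assumed common across countries but is rescaled by a
#' multiplicative factor so that it reproduces each country's observed total
#' SWI incidence at the reference day. A country observing 2.4\% where the
#' curve gives 4.8\% gets a factor of 0.5.
#'
#' @param country_incidence_at_ref Observed cumulative SWI incidence at the
#'   reference day, percent, >= 0.
#' @param curve_value_at_ref Base-curve cumulative incidence at the same day,
#'   percent, > 0.
#' @return The dimensionless scale factor (country / curve).
#' @export
calibration_factor <- function(country_incidence_at_ref, curve_value_at_ref) {
  if (!is.finite(curve_value_at_ref) || curve_value_at_ref <= 0) {
    stop("curve value at the reference day must be > 0")
  }
  if (!is.finite(country_incidence_at_ref) || country_incidence_at_ref < 0) {
    stop("country incidence must be finite and >= 0")
  }
  country_incidence_at_ref / curve_value_at_ref
}

#' Calibrate the incidence curve to a country's observed incidence
#'
#' @param country_code Country identifier (free text, conventionally ISO-3).
#' @param total_swi_incidence Observed total (superficial + deep) SWI
#'   incidence at `reference_day`, percent of CABG procedures.
#' @param curve Base [hill_params()] curve.
#' @param reference_day Day at which the observed incidence applies
#'   (default 30).
#' @return An object of class `calibrated_incidence` with fields `curve`,
#'   `scale_factor`, `reference_day`, `country_code`.
#' @export
calibrate_incidence <- function(country_code, total_swi_incidence,
                                curve = hill_params(), reference_day = 30) {
  ref_value <- hill_cumulative(reference_day, curve)
  sf <- calibration_factor(total_swi_incidence, ref_value)
  out <- structure(
    list(curve = curve, scale_factor = sf, reference_day = reference_day,
         country_code = country_code),
    class = "calibrated_incidence")
  # invariant: scaled curve reproduces the observed incidence at the ref day
  stopifnot(abs(sf * ref_value - total_swi_incidence) < 1e-9)
  out
}

#' Scaled cumulative SWI incidence as a fraction
#'
#' Evaluates the calibrated curve and converts from percent to a fraction
#' in \[0, 1) suitable for hazard computation.
#'
#' @param t Days post-surgery, numeric vector.
#' @param inc A [calibrate_incidence()] object.
#' @return Cumulative SWI fraction, same length as `t`.
#' @export
cumulative_fraction <- function(t, inc) {
  if (!inherits(inc, "calibrated_incidence")) {
    stop("`inc` must be a calibrated_incidence object")
  }
  f <- inc$scale_factor * hill_cumulative(t, inc$curve) / 100
  if (any(f >= 1)) stop("scaled cumulative incidence reaches 1; invalid model")
  f
}

#' Per-cycle SWI hazard from the calibrated cumulative curve
#'
#' Converts the cumulative incidence curve into daily conditional
#' probabilities for the Markov model:
#' \deqn{h(t) = \frac{F(t) - F(t-1)}{1 - F(t-1)}}
#' Reconstructing the cumulative curve from these hazards by the product
#' identity \eqn{1 - \prod_{s \le t} (1 - h(s)) = (F(t) - F(0)) / (1 - F(0))}
#' recovers the input curve exactly (the offset `F(0)` is ~1e-32 by default).
#'
#' @param t Day index (>= 1), integer vector.
#' @param inc A [calibrate_incidence()] object.
#' @return Per-cycle SWI probability in \[0, 1), same length as `t`.
#' @export
interval_hazard <- function(t, inc) {
  if (any(t < 1)) stop("`t` must be >= 1 (hazard over the interval (t-1, t])")
  f1 <- cumulative_fraction(t, inc)
  f0 <- cumulative_fraction(t - 1, inc)
  if (any(f0 >= 1)) stop("cumulative incidence at t-1 must be < 1")
  (f1 - f0) / (1 - f0)
}

#' Split a total SWI incidence into superficial and deep components
#'
#' The severity split is applied as a time-constant proportional split:
#' deep SWIs (DSWIs) are `dswi_share` of all events, superficial SWIs the
#' rest, and the two parts sum exactly to the total. Countries reporting
#' only a total incidence (no severity breakdown) must supply an assumed
#' share explicitly.
#'
#' @param total_swi Total SWI incidence (any unit; the split preserves it).
#' @param dswi_share Fraction of SWIs that are deep, in \[0, 1\]. `NA` is an
#'   error: an assumed share must be stated.
#' @return Named numeric vector `c(sswi = ..., dswi = ...)`.
#' @export
split_severity <- function(total_swi, dswi_share) {
  if (is.na(dswi_share)) {
    stop("severity split unknown: supply an assumed `dswi_share` explicitly")
  }
  if (dswi_share < 0 || dswi_share > 1) stop("`dswi_share` must be in [0, 1]")
  dswi <- total_swi * dswi_share
  c(sswi = total_swi - dswi, dswi = dswi)
}
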