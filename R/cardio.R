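#' Ventricular activation waveform
#'
#' Normalized double-Hill activation of the time-varying elastance
#' chambers: a product of a rising Hill term (exponent `n1`, half point
#' at `0.6 * sys_frac` of the cycle) and a falling Hill term (exponent
#' `n2`, half point at `sys_frac` of the cycle), rescaled so the maximum
#' over the cycle is exactly 1. The waveform is 0 at the start of the
#' cycle (end-diastole), peaks once, and is periodic with period
#' `60/hr`.
#'
#' @param t_in_cycle time since cycle start, s (recycled mod the
#'   period).
#' @param hr heart rate, bpm.
#' @param shape list with `sys_frac`, `n1`, `n2`.
#' @return activation level in `[0, 1]`, vectorized over `t_in_cycle`.
#' @export
activation <- function(t_in_cycle, hr,
                       shape = list(sys_frac = 0.27, n1 = 1.9, n2 = 35)) {
  if (hr <= 0) stop("hr must be > 0 (got ", hr, ")", call. = FALSE)
  period <- 60 / hr
  x <- (t_in_cycle %% period) / period
  .activation_raw(x, shape) / .activation_norm(shape)
}

.activation_raw <- function(x, shape) {
  a1 <- 0.6 * shape$sys_frac
  a2 <- shape$sys_frac
  h1 <- (x / a1)^shape$n1
  h1 <- h1 / (1 + h1)
  h2 <- 1 / (1 + (x / a2)^shape$n2)
  h1 * h2
}

# peak of the raw double-Hill product over one cycle (memoised on shape)
.activation_norm <- local({
  cache <- list()
  function(shape) {
    key <- paste(shape$sys_frac, shape$n1, shape$n2)
    if (is.null(cache[[key]])) {
      opt <- optimize(function(x) .activation_raw(x, shape),
                      c(1e-6, 1), maximum = TRUE, tol = 1e-12)
      cache[[key]] <<- opt$objective
    }
    cache[[key]]
  }
})

#' EDPVR stiffness coefficient from the V30 anchor
#'
#' The end-diastolic pressure-volume relation is
#' `P_ed(V) = s * (exp(k * (V - v0)) - 1)`. Diastolic stiffness is
#' specified only through V30, the volume at which end-diastolic
#' pressure reaches 30 mmHg, so `k` is solved from
#' `P_ed(v30) = 30`: `k = log(1 + 30/s) / (v30 - v0)`.
#'
#' @param s EDPVR pressure scale, mmHg.
#' @param v0 unstressed volume, mL.
#' @param v30 volume at which end-diastolic pressure is 30 mmHg, mL.
#' @param p_anchor anchor pressure, mmHg (30 by definition of V30).
#' @return exponential coefficient `k`, 1/mL.
#' @export
edpvr_k <- function(s, v0, v30, p_anchor = 30) {
  stopifnot(s > 0, v30 > v0)
  log1p(p_anchor / s) / (v30 - v0)
}

#' Instantaneous chamber pressure
#'
#' Time-varying elastance chamber: at full activation the pressure
#' follows the linear ESPVR `e_max * (V - v0)`; at zero activation it
#' follows the exponential EDPVR anchored at V30 (see [edpvr_k()]);
#' in between the two limbs are blended linearly by the activation
#' level. Pressure is clamped at a floor (default -20 mmHg) so runaway
#' negative pressures cannot destabilize the solver before the collapse
#' dynamics engage.
#'
#' @param v chamber volume, mL (vectorized).
#' @param t_in_cycle time since cycle start, s.
#' @param params list with `ees`, `v0`, `s`, `v30`, `hr` and optionally
#'   `shape` (activation shape, see [activation()]).
#' @param floor pressure floor, mmHg.
#' @return pressure, mmHg.
#' @export
chamber_pressure <- function(v, t_in_cycle, params, floor = -20) {
  act <- activation(t_in_cycle, params$hr,
                    params$shape %||% list(sys_frac = 0.27, n1 = 1.9,
                                           n2 = 35))
  k <- edpvr_k(params$s, params$v0, params$v30)
  pes <- params$ees * (v - params$v0)
  ped <- params$s * expm1(k * (v - params$v0))
  pmax(act * pes + (1 - act) * ped, floor)
}

#' Valve flow (diode-resistance law)
#'
#' @param p_up upstream pressure, mmHg.
#' @param p_down downstream pressure, mmHg.
#' @param r valve resistance, mmHg s/mL.
#' @return forward flow in mL/s; 0 when the valve is closed
#'   (`p_up <= p_down`).
#' @export
valve_flow <- function(p_up, p_down, r) {
  pmax(0, p_up - p_down) / r
}

# All compartment pressures of the closed loop at a given state.
# volumes: named vector with v_lv, v_la, v_rv, v_ra, v_sa, v_sv, v_pa,
# v_pv (absolute volumes, mL).
.circulation_pressures <- function(volumes, t_in_cycle, profile,
                                   floor = -20) {
  act_shape <- profile$activation
  lv <- list(ees = profile$ees_lv, v0 = profile$v0_lv, s = profile$s_lv,
             v30 = profile$v30, hr = profile$hr, shape = act_shape)
  rv <- list(ees = profile$rv_params$ees, v0 = profile$rv_params$v0,
             s = profile$rv_params$s, v30 = profile$rv_params$v30,
             hr = profile$hr, shape = act_shape)
  a <- profile$atrial_params
  sy <- profile$systemic; pu <- profile$pulmonary
  c(p_lv = chamber_pressure(volumes[["v_lv"]], t_in_cycle, lv, floor),
    p_rv = chamber_pressure(volumes[["v_rv"]], t_in_cycle, rv, floor),
    p_la = a$e_la * (volumes[["v_la"]] - a$v0_la),
    p_ra = a$e_ra * (volumes[["v_ra"]] - a$v0_ra),
    p_sa = (volumes[["v_sa"]] - sy$v0_arterial) / sy$compliance,
    p_sv = (volumes[["v_sv"]] - sy$v0_venous) / sy$venous_compliance,
    p_pa = (volumes[["v_pa"]] - pu$v0_arterial) / pu$compliance,
    p_pv = (volumes[["v_pv"]] - pu$v0_venous) / pu$venous_compliance)
}

#' Closed-loop volume derivatives
#'
#' Reference implementation of the circulation right-hand side used by
#' the compiled solver: returns the volume derivatives of all eight
#' compartments for a given state, with the pump appearing as an LV
#' apex withdrawal and an aortic return term. The derivatives of a
#' closed loop always sum to zero (volume conservation).
#'
#' @param volumes named vector `v_lv, v_la, v_rv, v_ra, v_sa, v_sv,
#'   v_pa, v_pv` of absolute compartment volumes, mL.
#' @param t_in_cycle time since cycle start, s.
#' @param profile a [patient_profile()].
#' @param q_pump pump flow withdrawn from the LV apex and returned to
#'   the systemic arteries, mL/s.
#' @return list with `dv` (named derivative vector, mL/s), `pressures`
#'   and `flows`.
#' @export
circulation_derivatives <- function(volumes, t_in_cycle, profile,
                                    q_pump = 0) {
  if (any(!is.finite(volumes)))
    stop("numerical error: non-finite state", call. = FALSE)
  p <- .circulation_pressures(volumes, t_in_cycle, profile)
  va <- profile$valves
  sy <- profile$systemic; pu <- profile$pulmonary
  q_mv <- valve_flow(p[["p_la"]], p[["p_lv"]], va$r_mv)
  q_av <- valve_flow(p[["p_lv"]], p[["p_sa"]], va$r_av)
  q_tv <- valve_flow(p[["p_ra"]], p[["p_rv"]], va$r_tv)
  q_pvv <- valve_flow(p[["p_rv"]], p[["p_pa"]], va$r_pv)
  q_sys <- (p[["p_sa"]] - p[["p_sv"]]) / sy$resistance
  q_vs <- (p[["p_sv"]] - p[["p_ra"]]) / sy$venous_resistance
  q_pul <- (p[["p_pa"]] - p[["p_pv"]]) / pu$resistance
  q_vp <- (p[["p_pv"]] - p[["p_la"]]) / pu$venous_resistance
  dv <- c(v_lv = q_mv - q_av - q_pump,
          v_la = q_vp - q_mv,
          v_rv = q_tv - q_pvv,
          v_ra = q_vs - q_tv,
          v_sa = q_av + q_pump - q_sys,
          v_sv = q_sys - q_vs,
          v_pa = q_pvv - q_pul,
          v_pv = q_pul - q_vp)
  list(dv = dv, pressures = p,
       flows = c(q_mv = q_mv, q_av = q_av, q_tv = q_tv, q_pvv = q_pvv,
                 q_sys = q_sys, q_vs = q_vs, q_pul = q_pul, q_vp = q_vp,
                 q_pump = q_pump))
}
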