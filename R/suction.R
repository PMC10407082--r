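#' Target collapse fraction of the apex tube
#'
#' Sigmoid in left ventricular pressure centred at the collapse
#' threshold (0 mmHg): fully open well above the threshold, fully
#' collapsed well below it, exactly one half at the threshold for an
#' open tube. Buckling hysteresis shifts the effective threshold up by
#' up to `hysteresis_pressure` while the tube is engaging
#' (`collapse_fraction` between 0.3 and 0.5), so a buckled tube reopens
#' only at a higher pressure than the one that collapsed it.
#'
#' @param p_lv left ventricular pressure, mmHg.
#' @param params a [suction_params()].
#' @param collapse_fraction current collapse fraction (sets the
#'   hysteresis state; 0 = fully open tube).
#' @return target collapse fraction in `[0, 1]`.
#' @export
collapse_target <- function(p_lv, params = suction_params(),
                            collapse_fraction = 0) {
  engage <- pmin(pmax((collapse_fraction - 0.3) / 0.2, 0), 1)
  thr_eff <- params$collapse_threshold_pressure +
    (params$hysteresis_pressure %||% 0) * engage
  1 / (1 + exp(params$collapse_steepness * (p_lv - thr_eff)))
}

#' One step of the collapse dynamics
#'
#' The collapse fraction relaxes first-order toward
#' [collapse_target()] with a fast engage and a slower release time
#' constant; the inflow resistance follows collapsing-tube hydraulics
#' (see [inflow_resistance()]).
#'
#' @param p_lv left ventricular pressure, mmHg.
#' @param state list with `collapse_fraction` and `r_inflow`.
#' @param params a [suction_params()].
#' @param dt step, s (<= 1 ms).
#' @return updated state list.
#' @export
collapse_dynamics <- function(p_lv, state, params = suction_params(),
                              dt = 1e-3) {
  if (dt > 1e-3) stop("dt must be <= 1 ms", call. = FALSE)
  target <- if (isTRUE(params$enabled))
    collapse_target(p_lv, params, state$collapse_fraction) else 0
  tau <- if (target > state$collapse_fraction)
    params$recovery_time_constant else params$release_time_constant
  cf <- state$collapse_fraction +
    (target - state$collapse_fraction) / tau * dt
  cf <- min(max(cf, 0), 1)
  list(collapse_fraction = cf, r_inflow = inflow_resistance(cf, params))
}

#' Inflow resistance of a partially collapsed tube
#'
#' Resistance of the collapsing lumen, anchored at `r_open` for a fully
#' open tube and `r_collapsed` for a fully collapsed one:
#' `r = r_open + cf^gamma * (r_collapsed - r_open)`. The exponent
#' `gamma` (`collapse_exponent`) sets how late in the collapse the
#' throttling engages: 1 is a linear interpolation, larger values keep
#' the lumen nearly unobstructed until the collapse is deep — which is
#' why marginal suction events barely disturb the pump while deep ones
#' throttle it.
#'
#' @param collapse_fraction collapse fraction in `[0, 1]`.
#' @param params a [suction_params()].
#' @return inflow resistance, mmHg s/mL.
#' @export
inflow_resistance <- function(collapse_fraction, params = suction_params()) {
  params$r_open + collapse_fraction^(params$collapse_exponent %||% 1) *
    (params$r_collapsed - params$r_open)
}

#' Pressure at the inflow cannula inlet
#'
#' `p_apex = p_lv - r_inflow * q_pump`. With the tube open and moderate
#' pump flow the apex pressure tracks LV pressure; during a collapse
#' with continued pump draw it develops the characteristic end-systolic
#' negative spike.
#'
#' @param p_lv left ventricular pressure, mmHg.
#' @param q_pump pump flow, mL/s.
#' @param r_inflow current inflow resistance, mmHg s/mL.
#' @return apex pressure, mmHg.
#' @export
apex_pressure <- function(p_lv, q_pump, r_inflow) {
  p_lv - r_inflow * q_pump
}

#' Ground-truth suction flag for one beat
#'
#' A beat is a true suction beat when the collapse fraction exceeded the
#' ground-truth threshold (default one half, the midpoint of the
#' open/collapsed continuum) at any sample of the beat window —
#' equivalently, when LV pressure crossed below the 0 mmHg threshold
#' firmly enough for the tube to engage. This flag is the reference
#' label for sensitivity and specificity.
#'
#' @param collapse_fraction collapse-fraction samples over exactly one
#'   cardiac cycle.
#' @param threshold flag threshold on the collapse fraction.
#' @return logical flag.
#' @export
suction_ground_truth <- function(collapse_fraction, threshold = 0.5) {
  if (length(collapse_fraction) == 0)
    stop("empty beat window", call. = FALSE)
  any(collapse_fraction > threshold)
}
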