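#' Construct a patient profile
#'
#' A patient profile is the complete cardiac and vascular parameter set
#' realizing one heart-failure phenotype in the closed-loop model. The
#' left ventricle is described by its end-systolic elastance `ees_lv`
#' (slope of the ESPVR), unstressed volume `v0_lv`, and a diastolic
#' stiffness anchored through `v30`, the volume at which end-diastolic
#' pressure equals 30 mmHg. The end-diastolic pressure-volume relation is
#' `P = s * (exp(k * (V - v0)) - 1)` with `k` solved from the V30 anchor
#' (see [edpvr_k()]).
#'
#' @param name profile label, e.g. `"DCM"`.
#' @param hr heart rate in beats per minute.
#' @param ees_lv LV end-systolic elastance, mmHg/mL.
#' @param v0_lv LV unstressed volume, mL.
#' @param v30 LV volume at which end-diastolic pressure is 30 mmHg, mL.
#' @param s_lv LV end-diastolic pressure scale, mmHg.
#' @param rv_params list with `ees`, `v0`, `s`, `v30` for the right
#'   ventricle (same meaning as the LV fields).
#' @param atrial_params list with constant atrial elastances `e_la`,
#'   `e_ra` (mmHg/mL) and unstressed volumes `v0_la`, `v0_ra` (mL).
#' @param systemic list with arterial `resistance` (mmHg s/mL),
#'   `compliance` (mL/mmHg), `v0_arterial`, venous `venous_compliance`,
#'   `venous_resistance`, `v0_venous`.
#' @param pulmonary analogous list for the pulmonary bed.
#' @param valves list of valve resistances `r_mv`, `r_av`, `r_tv`,
#'   `r_pv` in mmHg s/mL.
#' @param activation list with systolic fraction `sys_frac` of the cycle
#'   and double-Hill shape exponents `n1`, `n2`.
#' @param total_blood_volume total circulating volume, mL.
#' @param target_hemodynamics named list of calibration targets (`co`
#'   in L/min, `sap_sys`/`sap_dia`/`sap_mean`, `pap_*`, `pcwp` in mmHg,
#'   `edv`, `esv` in mL). Used only for calibration checks, never by the
#'   solver.
#' @return an object of class `patient_profile`.
#' @seealso [builtin_profile()] for the shipped DCM and RCM phenotypes.
#' @export
patient_profile <- function(name, hr, ees_lv, v0_lv, v30, s_lv,
                            rv_params, atrial_params, systemic, pulmonary,
                            valves = list(r_mv = 0.005, r_av = 0.008,
                                          r_tv = 0.005, r_pv = 0.006),
                            activation = list(sys_frac = 0.27,
                                              n1 = 1.9, n2 = 35),
                            total_blood_volume,
                            target_hemodynamics = NULL) {
  prof <- structure(
    list(name = name, hr = hr, ees_lv = ees_lv, v0_lv = v0_lv, v30 = v30,
         s_lv = s_lv, rv_params = rv_params, atrial_params = atrial_params,
         systemic = systemic, pulmonary = pulmonary, valves = valves,
         activation = activation, total_blood_volume = total_blood_volume,
         target_hemodynamics = target_hemodynamics),
    class = "patient_profile")
  validate_profile(prof)
  prof
}

#' Validate a patient profile
#'
#' Checks the structural invariants of a [patient_profile()]: positive
#' heart rate, elastances and volumes, `v30 > v0_lv`, and (when targets
#' are present) `edv > esv >= 0`.
#'
#' @param profile a `patient_profile`.
#' @return the profile, invisibly; stops with a descriptive error
#'   otherwise.
#' @export
validate_profile <- function(profile) {
  need <- function(ok, what, val) {
    if (!isTRUE(ok))
      stop("invalid patient profile: ", what,
           if (!missing(val)) paste0(" (got ", val, ")"), call. = FALSE)
  }
  for (f in c("name", "hr", "ees_lv", "v0_lv", "v30", "s_lv", "rv_params",
              "atrial_params", "systemic", "pulmonary",
              "total_blood_volume"))
    need(!is.null(profile[[f]]), paste0("missing required field '", f, "'"))
  need(profile$hr > 0, "hr must be > 0", profile$hr)
  need(profile$ees_lv > 0, "ees_lv must be > 0", profile$ees_lv)
  need(profile$s_lv > 0, "s_lv must be > 0", profile$s_lv)
  need(profile$v30 > profile$v0_lv, "v30 must exceed v0_lv",
       paste(profile$v30, "<=", profile$v0_lv))
  need(profile$total_blood_volume > 0, "total_blood_volume must be > 0",
       profile$total_blood_volume)
  th <- profile$target_hemodynamics
  if (!is.null(th) && !is.null(th$edv) && !is.null(th$esv)) {
    need(th$edv > th$esv, "target edv must exceed esv",
         paste(th$edv, "<=", th$esv))
    need(th$esv >= 0, "target esv must be >= 0", th$esv)
  }
  invisible(profile)
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile> ", x$name, "\n", sep = "")
  cat(sprintf("  HR %g bpm | Ees %g mmHg/mL | V0 %g mL | V30 %g mL\n",
              x$hr, x$ees_lv, x$v0_lv, x$v30))
  cat(sprintf("  total blood volume %g mL\n", x$total_blood_volume))
  th <- x$target_hemodynamics
  if (!is.null(th))
    cat(sprintf("  targets: CO %g L/min, PCWP %g mmHg, EDV %g mL, ESV %g mL\n",
                th$co, th$pcwp, th$edv, th$esv))
  invisible(x)
}

#' Pump parameter set
#'
#' Parameters of the HVAD-like continuous-flow pump: the quadratic
#' head-flow-speed hydraulic characteristic
#' `dP = a0*w^2 + a1*w*q + a2*q^2` (w in rpm, q in L/min, dP in mmHg),
#' impeller/motor dynamics, the constant-speed PI controller, and the
#' on-device flow estimator. The shipped hydraulic coefficients are a
#' quadratic fit to published HVAD pressure-flow curves; inertia and
#' controller gains are tuned so intra-beat speed excursions match the
#' reported non-suction (about +/-50 rpm) and suction (about +100 rpm)
#' signatures.
#'
#' @param speed_setpoint constant-speed setpoint, rpm (1,800-4,000).
#' @param hq_coeffs numeric length-3 `c(a0, a1, a2)` of the head curve.
#' @param impeller_inertia impeller + entrained fluid inertia, kg m^2.
#' @param torque_constant motor torque constant, N m/A.
#' @param friction_coeff viscous friction torque coefficient, N m s/rad.
#' @param torque_coeffs hydraulic torque coefficients `c(c0, c1)` in
#'   `T = (c0 + c1 * q_lpm) * omega`.
#' @param controller_gains `c(kp, ki)` of the PI speed controller
#'   (A/(rad/s) and A/(rad/s)/s).
#' @param i_max motor current limit, A.
#' @param inertance blood inertance of the cannulae, mmHg s^2/mL.
#' @param r_outflow outflow-graft resistance, mmHg s/mL.
#' @param estimator_coeffs static flow-estimator map coefficients
#'   `c(kt, drag, slope)`: `q_est = (kt*I - drag*w) / (slope*w)` with `w`
#'   in rad/s and `q_est` in L/min. Defaults to the values implied by the
#'   motor model, which makes the estimator exact in torque equilibrium.
#' @param sample_rate_pump pump telemetry sample rate, Hz (fixed at 50).
#' @param flow_filter_hz fast corner of the estimated-flow dynamics, Hz
#'   (shape-preserving anti-alias stage).
#' @param flow_mean_filter_hz slow corner of the estimated-flow
#'   dynamics, Hz (mean-tracking stage).
#' @param flow_pulsatility_gain dimensionless gain applied to the
#'   pulsatile component of the estimated flow. The device firmware
#'   reports a heavily averaged flow whose within-beat pulsatility is
#'   strongly attenuated but keeps the waveform shape; beat means are
#'   unaffected (the slow component has unit gain).
#' @param speed_filter_hz anti-alias corner for speed/current/power.
#' @return an object of class `pump_params`.
#' @export
pump_params <- function(speed_setpoint = 2800,
                        hq_coeffs = c(a0 = 1.38e-5, a1 = -1.07e-3,
                                      a2 = -0.60),
                        impeller_inertia = 3.2e-5,
                        torque_constant = 0.02,
                        friction_coeff = 1.0e-5,
                        torque_coeffs = c(c0 = 1.1e-5, c1 = 1.0e-5),
                        controller_gains = c(kp = 0.035, ki = 0.08),
                        i_max = 3,
                        inertance = 2e-3,
                        r_outflow = 0.12,
                        estimator_coeffs = NULL,
                        sample_rate_pump = 50,
                        flow_filter_hz = 3.5,
                        flow_mean_filter_hz = 0.2,
                        flow_pulsatility_gain = 0.075,
                        speed_filter_hz = 15) {
  if (speed_setpoint < 1800 || speed_setpoint > 4000)
    stop("speed_setpoint must lie within [1800, 4000] rpm (got ",
         speed_setpoint, ")", call. = FALSE)
  if (sample_rate_pump != 50)
    stop("sample_rate_pump is fixed at 50 Hz (got ", sample_rate_pump,
         ")", call. = FALSE)
  if (length(hq_coeffs) != 3)
    stop("hq_coeffs must have three coefficients", call. = FALSE)
  if (is.null(estimator_coeffs))
    estimator_coeffs <- c(kt = unname(torque_constant),
                          drag = unname(friction_coeff + torque_coeffs[[1]]),
                          slope = unname(torque_coeffs[[2]]))
  structure(list(speed_setpoint = speed_setpoint,
                 hq_coeffs = hq_coeffs,
                 impeller_inertia = impeller_inertia,
                 torque_constant = torque_constant,
                 friction_coeff = friction_coeff,
                 torque_coeffs = torque_coeffs,
                 controller_gains = controller_gains,
                 i_max = i_max, inertance = inertance,
                 r_outflow = r_outflow,
                 estimator_coeffs = estimator_coeffs,
                 sample_rate_pump = sample_rate_pump,
                 flow_filter_hz = flow_filter_hz,
                 flow_mean_filter_hz = flow_mean_filter_hz,
                 flow_pulsatility_gain = flow_pulsatility_gain,
                 speed_filter_hz = speed_filter_hz),
            class = "pump_params")
}

#' Suction (collapsible apex) parameter set
#'
#' The collapsible-apex module restricts pump inflow when left
#' ventricular pressure drops below the collapse threshold (0 mmHg). The
#' target collapse fraction is a sigmoid in LV pressure centred at the
#' threshold; the state relaxes toward it with a fast engage and a
#' slightly slower release time constant, and the inflow resistance
#' interpolates linearly between `r_open` and `r_collapsed`.
#'
#' @param collapse_threshold_pressure LV pressure at which the tube is
#'   half collapsed, mmHg (0 by definition of the suction trigger).
#' @param collapse_steepness sigmoid slope, 1/mmHg.
#' @param hysteresis_pressure buckling hysteresis, mmHg: once the tube
#'   is engaging, the effective collapse threshold rises by up to this
#'   amount, so a collapsed tube reopens only at a higher LV pressure
#'   than the one that closed it. This snap-through bistability (a
#'   property of buckled elastic tubes) produces the per-beat
#'   collapse/reopen limit cycle of intermittent suction instead of a
#'   smooth Starling-resistor equilibrium.
#' @param r_open baseline inflow-cannula resistance, mmHg s/mL.
#' @param collapse_exponent exponent of the collapse-fraction to
#'   resistance map (see [inflow_resistance()]).
#' @param r_collapsed fully collapsed inflow resistance, mmHg s/mL.
#' @param recovery_time_constant engage time constant, s.
#' @param release_time_constant release time constant, s.
#' @param ground_truth_fraction collapse fraction above which a beat is
#'   flagged as a true suction beat.
#' @param enabled logical; `FALSE` freezes the tube fully open.
#' @return an object of class `suction_params`.
#' @export
suction_params <- function(collapse_threshold_pressure = 0,
                           collapse_steepness = 6,
                           hysteresis_pressure = 1.2,
                           r_open = 0.035,
                           r_collapsed = 3.5,
                           collapse_exponent = 1,
                           recovery_time_constant = 0.04,
                           release_time_constant = 0.5,
                           ground_truth_fraction = 0.5,
                           enabled = TRUE) {
  if (!(r_collapsed > r_open && r_open > 0))
    stop("suction parameters require r_collapsed > r_open > 0 (got ",
         r_collapsed, " <= ", r_open, ")", call. = FALSE)
  if (collapse_steepness <= 0)
    stop("collapse_steepness must be > 0 (got ", collapse_steepness, ")",
         call. = FALSE)
  structure(list(collapse_threshold_pressure = collapse_threshold_pressure,
                 collapse_steepness = collapse_steepness,
                 hysteresis_pressure = hysteresis_pressure,
                 r_open = r_open, r_collapsed = r_collapsed,
                 collapse_exponent = collapse_exponent,
                 recovery_time_constant = recovery_time_constant,
                 release_time_constant = release_time_constant,
                 ground_truth_fraction = ground_truth_fraction,
                 enabled = enabled),
            class = "suction_params")
}

#' Experiment configuration
#'
#' Bundles a patient profile, pump and suction parameters, and the
#' protocol settings for the hypovolemia-ramp / speed-sweep experiments.
#'
#' @param profile a [patient_profile()].
#' @param pump a [pump_params()].
#' @param suction a [suction_params()].
#' @param speed_list pump speeds for the sweep, rpm.
#' @param hypovolemia_step fractional blood-volume decrement per ramp
#'   stage (fraction of the baseline total blood volume).
#' @param stop_criterion_flow_peak the ramp stops once suction is
#'   triggered and a beat's 50-Hz estimated-flow peak falls below this
#'   value, L/min.
#' @param n_beats_per_stage beats recorded per ramp stage.
#' @param settle_beats beats simulated (not recorded) after each volume
#'   step before recording resumes.
#' @param solver list with solver step `dt` in seconds (max 1 ms).
#' @param noise list with `enabled`, `sd_flow` (L/min), `sd_speed` (rpm)
#'   and `seed`; additive zero-mean telemetry noise, off by default.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(profile = builtin_profile("DCM"),
                              pump = pump_params(),
                              suction = suction_params(),
                              speed_list = seq(2500, 3200, by = 100),
                              hypovolemia_step = 0.02,
                              stop_criterion_flow_peak = 2,
                              n_beats_per_stage = 25,
                              settle_beats = 5,
                              solver = list(dt = 2.5e-4),
                              noise = list(enabled = FALSE, sd_flow = 0,
                                           sd_speed = 0, seed = NULL)) {
  validate_profile(profile)
  if (stop_criterion_flow_peak <= 0)
    stop("stop_criterion_flow_peak must be > 0 (got ",
         stop_criterion_flow_peak, ")", call. = FALSE)
  if (hypovolemia_step <= 0 || hypovolemia_step >= 0.5)
    stop("hypovolemia_step must be a small positive fraction (got ",
         hypovolemia_step, ")", call. = FALSE)
  if (n_beats_per_stage < 1)
    stop("n_beats_per_stage must be >= 1", call. = FALSE)
  structure(list(profile = profile, pump = pump, suction = suction,
                 speed_list = speed_list,
                 hypovolemia_step = hypovolemia_step,
                 stop_criterion_flow_peak = stop_criterion_flow_peak,
                 n_beats_per_stage = n_beats_per_stage,
                 settle_beats = settle_beats,
                 solver = solver, noise = noise),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat("  profile:", x$profile$name, "| pump setpoint:",
      x$pump$speed_setpoint, "rpm\n")
  cat("  speed sweep:", paste(range(x$speed_list), collapse = "-"),
      "rpm | hypovolemia step:", x$hypovolemia_step * 100, "%/stage\n")
  cat("  stop criterion: estimated-flow peak <",
      x$stop_criterion_flow_peak, "L/min\n")
  invisible(x)
}

#' Built-in heart-failure profiles
#'
#' Returns one of the two calibrated phenotype archetypes: a severe
#' dilated cardiomyopathy (`"DCM"`: large, compliant, weakly contracting
#' LV, Ees 0.4 mmHg/mL, V30 210 mL) or a restrictive cardiomyopathy
#' (`"RCM"`: small, stiff, strongly contracting LV, Ees 3.3 mmHg/mL,
#' V30 95 mL), both at heart rate 78 bpm and supported at 2,800 rpm.
#' The vascular and right-heart parameters not fixed by the phenotype
#' definition are calibration results: they were fitted once so that the
#' closed-loop simulation reproduces the baseline target hemodynamics
#' stored in `target_hemodynamics`.
#'
#' @param name `"DCM"` or `"RCM"`.
#' @return a [patient_profile()].
#' @examples
#' builtin_profile("DCM")
#' @export
builtin_profile <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% c("DCM", "RCM")))
    stop("unknown profile '", paste(name, collapse = ","),
         "'; valid names are: DCM, RCM", call. = FALSE)
  if (name == "DCM") .profile_dcm() else .profile_rcm()
}

# Calibrated DCM parameter set (targets: CO 4.7 L/min, SAP 87/81 (84),
# PAP 37/16 (24), PCWP 12 mmHg, EDV 183 mL, ESV 154 mL at 2,800 rpm).
.profile_dcm <- function() {
  patient_profile(
    name = "DCM", hr = 78,
    ees_lv = 0.4, v0_lv = 60, v30 = 210, s_lv = 0.117,
    rv_params = list(ees = 0.75, v0 = 10, s = 0.08, v30 = 180),
    atrial_params = list(e_la = 0.25, v0_la = 20, e_ra = 0.20, v0_ra = 20),
    systemic = list(resistance = 1.00, compliance = 1.3, v0_arterial = 500,
                    venous_compliance = 70, venous_resistance = 0.025,
                    v0_venous = 2800),
    pulmonary = list(resistance = 0.153, compliance = 3.0, v0_arterial = 80,
                     venous_compliance = 12, venous_resistance = 0.012,
                     v0_venous = 300),
    total_blood_volume = 4700,
    target_hemodynamics = list(co = 4.7, sap_sys = 87, sap_dia = 81,
                               sap_mean = 84, pap_sys = 37, pap_dia = 16,
                               pap_mean = 24, pcwp = 12, edv = 183,
                               esv = 154))
}

# Calibrated RCM parameter set (targets: CO 5.0 L/min, SAP 102/83 (92),
# PAP 37/10 (20), PCWP 7 mmHg, EDV 67 mL, ESV 13 mL at 2,800 rpm).
.profile_rcm <- function() {
  patient_profile(
    name = "RCM", hr = 78,
    ees_lv = 3.3, v0_lv = -13, v30 = 95, s_lv = 0.256,
    rv_params = list(ees = 0.80, v0 = 10, s = 0.08, v30 = 180),
    atrial_params = list(e_la = 0.35, v0_la = 15, e_ra = 0.25, v0_ra = 15),
    systemic = list(resistance = 1.12, compliance = 1.1, v0_arterial = 500,
                    venous_compliance = 70, venous_resistance = 0.025,
                    v0_venous = 2800),
    pulmonary = list(resistance = 0.156, compliance = 2.6, v0_arterial = 80,
                     venous_compliance = 12, venous_resistance = 0.012,
                     v0_venous = 300),
    total_blood_volume = 4500,
    target_hemodynamics = list(co = 5.0, sap_sys = 102, sap_dia = 83,
                               sap_mean = 92, pap_sys = 37, pap_dia = 10,
                               pap_mean = 20, pcwp = 7, edv = 67,
                               esv = 13))
}

#' Load an experiment configuration from YAML or JSON
#'
#' Reads a structured config file, fills defaults for omitted optional
#' sections (pump, suction, protocol settings) and validates all
#' invariants. Units are the package-internal system throughout: mmHg,
#' mL, s, rpm.
#'
#' The file may contain the top-level keys `profile` (either a string
#' naming a built-in profile or a full parameter mapping), `pump`,
#' `suction`, and the protocol fields of [experiment_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an [experiment_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  config_from_list(raw)
}

#' Build an experiment configuration from a plain list
#'
#' Workhorse behind [load_config()]; useful when the configuration comes
#' from somewhere other than a file.
#'
#' @param raw a named list as produced by parsing a config file.
#' @return an [experiment_config()].
#' @export
config_from_list <- function(raw) {
  if (is.null(raw$profile))
    stop("configuration error: missing required field 'profile'",
         call. = FALSE)
  prof <- if (is.character(raw$profile)) {
    builtin_profile(raw$profile)
  } else {
    p <- raw$profile
    for (f in c("name", "hr", "ees_lv", "v0_lv", "v30", "s_lv"))
      if (is.null(p[[f]]) && is.null(p$base))
        stop("configuration error: missing required field 'profile$", f,
             "'", call. = FALSE)
    # a mapping may set `base: DCM|RCM` and override individual fields
    base <- if (!is.null(p$base)) builtin_profile(p$base)
    else builtin_profile("DCM")
    merged <- modifyList(unclass(base), p[setdiff(names(p), "base")])
    args <- merged[intersect(names(formals(patient_profile)),
                             names(merged))]
    do.call(patient_profile, args)
  }
  pump <- do.call(pump_params, as.list(raw$pump %||% list()))
  suction <- do.call(suction_params, as.list(raw$suction %||% list()))
  extra <- raw[setdiff(names(raw), c("profile", "pump", "suction"))]
  do.call(experiment_config,
          c(list(profile = prof, pump = pump, suction = suction), extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save an experiment configuration to YAML or JSON
#'
#' Field-for-field inverse of [load_config()]: `load_config(save_config(x, f))`
#' reproduces `x`.
#'
#' @param config an [experiment_config()].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  as_plain <- function(x) {
    if (is.list(x)) lapply(unclass(x), as_plain) else x
  }
  out <- as_plain(config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(out, path)
  invisible(path)
}
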