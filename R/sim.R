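# --- coupling layer between the R parameter objects and the compiled
# --- fixed-step RK4 solver (src/simulate.cpp)

# Order must match enum Par in src/simulate.cpp.
.cpp_param_vector <- function(profile, pump, suction, speed_rpm,
                              dt = 2.5e-4) {
  a <- profile$atrial_params; sy <- profile$systemic
  pu <- profile$pulmonary; va <- profile$valves
  sh <- profile$activation
  rv <- profile$rv_params
  c(hr = profile$hr,
    ees_lv = profile$ees_lv, v0_lv = profile$v0_lv, s_lv = profile$s_lv,
    k_lv = edpvr_k(profile$s_lv, profile$v0_lv, profile$v30),
    ees_rv = rv$ees, v0_rv = rv$v0, s_rv = rv$s,
    k_rv = edpvr_k(rv$s, rv$v0, rv$v30),
    e_la = a$e_la, v0_la = a$v0_la, e_ra = a$e_ra, v0_ra = a$v0_ra,
    sys_frac = sh$sys_frac, n1 = sh$n1, n2 = sh$n2,
    act_norm = .activation_norm(sh),
    r_mv = va$r_mv, r_av = va$r_av, r_tv = va$r_tv, r_pv = va$r_pv,
    c_sa = sy$compliance, v0_sa = sy$v0_arterial, r_sys = sy$resistance,
    c_sv = sy$venous_compliance, v0_sv = sy$v0_venous,
    r_vs = sy$venous_resistance,
    c_pa = pu$compliance, v0_pa = pu$v0_arterial, r_pul = pu$resistance,
    c_pv = pu$venous_compliance, v0_pv = pu$v0_venous,
    r_vp = pu$venous_resistance,
    speed_rpm = speed_rpm,
    hq_a0 = pump$hq_coeffs[[1]], hq_a1 = pump$hq_coeffs[[2]],
    hq_a2 = pump$hq_coeffs[[3]],
    l_pump = pump$inertance, r_out = pump$r_outflow,
    j_imp = pump$impeller_inertia, kt = pump$torque_constant,
    b_f = pump$friction_coeff,
    tc0 = pump$torque_coeffs[[1]], tc1 = pump$torque_coeffs[[2]],
    kp = pump$controller_gains[[1]], ki = pump$controller_gains[[2]],
    i_max = pump$i_max,
    steep = suction$collapse_steepness,
    p_thr = suction$collapse_threshold_pressure,
    hyst = suction$hysteresis_pressure %||% 0,
    r_open = suction$r_open,
    r_coll = suction$r_collapsed,
    r_exp = suction$collapse_exponent %||% 1,
    tau_eng = suction$recovery_time_constant,
    tau_rel = suction$release_time_constant,
    suction_on = as.numeric(isTRUE(suction$enabled)),
    p_floor = -20, dt_solver = dt)
}

# Standard initial conditions: volumes distributed from plausible
# starting pressures, then the systemic venous reservoir absorbs the
# residual so the sum equals total blood volume exactly.
.init_state <- function(profile, pump, speed_rpm) {
  th <- profile$target_hemodynamics %||%
    list(sap_mean = 85, pap_mean = 20, pcwp = 10, edv = 150)
  sy <- profile$systemic; pu <- profile$pulmonary
  a <- profile$atrial_params
  v_lv <- th$edv
  v_la <- a$v0_la + th$pcwp / a$e_la
  v_rv <- profile$rv_params$v0 + 70
  v_ra <- a$v0_ra + 4 / a$e_ra
  v_sa <- sy$v0_arterial + th$sap_mean * sy$compliance
  v_pa <- pu$v0_arterial + th$pap_mean * pu$compliance
  v_pv <- pu$v0_venous + (th$pcwp + 2) * pu$venous_compliance
  v_sv <- profile$total_blood_volume -
    (v_lv + v_la + v_rv + v_ra + v_sa + v_pa + v_pv)
  if (v_sv <= sy$v0_venous * 0.2)
    stop("initial state infeasible: venous volume would be depleted",
         call. = FALSE)
  # operating-point flow guess from the head curve against a nominal
  # 75 mmHg gradient (keeps the initial transient benign at low speeds)
  head0 <- pump$hq_coeffs[[1]] * speed_rpm^2
  q0 <- min(max((head0 - 75) / 9, 1.5), 8) / 0.06
  w0 <- speed_rpm * pi / 30
  tc <- pump$torque_coeffs
  i0 <- ((tc[[1]] + tc[[2]] * q0 * 0.06) * w0 +
           pump$friction_coeff * w0) / pump$torque_constant
  c(v_lv, v_la, v_rv, v_ra, v_sa, v_sv, v_pa, v_pv, q0, w0, i0, 0)
}

.run_segment <- function(state, pv, duration, t0) {
  dur <- round(duration * 1000) / 1000
  .simulate_core(state, pv, dur, t0)
}

# butterworth low-pass, causal (device-like); initialized at the first
# sample value so records do not start with a step transient; falls
# back to the raw series if the corner is at/above Nyquist
.lowpass <- function(x, fc, fs) {
  if (fc >= fs / 2) return(x)
  bf <- signal::butter(2, fc / (fs / 2), type = "low")
  x0 <- x[1]
  x0 + as.numeric(signal::filter(bf, x - x0))
}

# Build a signal_record from a raw 1-kHz solver matrix. The leading
# `drop_s` seconds serve as settling and filter warm-up and are
# discarded after the causal pump-channel filters have run over them.
.make_signal_record <- function(mat, meta, pump, noise = NULL,
                                drop_s = 0) {
  fs <- 1000
  om <- .lowpass(mat[, "omega_rpm"], pump$speed_filter_hz, fs)
  cu <- .lowpass(mat[, "current"], pump$speed_filter_hz, fs)
  po <- .lowpass(mat[, "power"], pump$speed_filter_hz, fs)
  # estimated flow as the device reports it: a slow mean-tracking
  # component plus a strongly attenuated (shape-preserving) pulsatile
  # component
  qf <- .lowpass(mat[, "q_est_raw"], pump$flow_filter_hz, fs)
  qs_slow <- .lowpass(mat[, "q_est_raw"], pump$flow_mean_filter_hz, fs)
  qe <- qs_slow + pump$flow_pulsatility_gain * (qf - qs_slow)
  keep <- mat[, "t"] >= mat[1, "t"] + drop_s - 1e-9
  mat <- mat[keep, , drop = FALSE]
  om <- om[keep]; cu <- cu[keep]; po <- po[keep]; qe <- qe[keep]
  qd <- .lowpass(mat[, "q_pump"] * 0.06, pump$speed_filter_hz, fs)
  idx50 <- seq(1, nrow(mat), by = 20)
  pump_df <- data.frame(t = mat[idx50, "t"], omega_rpm = om[idx50],
                        current = cu[idx50], power = po[idx50],
                        q_est = qe[idx50], q_dyn = qd[idx50])
  if (!is.null(noise) && isTRUE(noise$enabled)) {
    if (!is.null(noise$seed)) {
      seed <- (noise$seed + round(meta$stage %||% 0)) %% .Machine$integer.max
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    n <- nrow(pump_df)
    pump_df$omega_rpm <- pump_df$omega_rpm +
      rnorm(n, 0, noise$sd_speed %||% 0)
    pump_df$q_est <- pump_df$q_est + rnorm(n, 0, noise$sd_flow %||% 0)
  }
  hemo <- data.frame(t = mat[, "t"], p_lv = mat[, "p_lv"],
                     p_ao = mat[, "p_sa"], p_la = mat[, "p_la"],
                     p_pa = mat[, "p_pa"], p_apex = mat[, "p_apex"],
                     v_lv = mat[, "v_lv"], v_total = mat[, "v_total"],
                     q_sys = mat[, "q_sys"], q_pump = mat[, "q_pump"],
                     q_av = mat[, "q_av"],
                     collapse_fraction = mat[, "collapse_fraction"])
  rec <- structure(list(hemo = hemo, pump = pump_df, meta = meta),
                   class = "signal_record")
  rec$beats <- .cycle_truth(rec)
  rec
}

# Per-cycle ground truth on the heart-period grid (absolute time
# multiples of 60/hr) plus the 50-Hz estimated-flow peak per cycle.
.cycle_truth <- function(record) {
  T <- 60 / record$meta$hr
  t <- record$hemo$t
  k0 <- ceiling(t[1] / T - 1e-9)
  k1 <- floor((t[length(t)] + 1e-3) / T + 1e-9) - 1
  if (k1 < k0) return(data.frame(t_start = numeric(0),
                                 t_end = numeric(0), suction = logical(0),
                                 flow_peak = numeric(0)))
  out <- lapply(k0:k1, function(k) {
    i <- t >= k * T - 1e-9 & t < (k + 1) * T - 1e-9
    j <- record$pump$t >= k * T - 1e-9 & record$pump$t < (k + 1) * T - 1e-9
    data.frame(t_start = k * T, t_end = (k + 1) * T,
               suction = suction_ground_truth(
                 record$hemo$collapse_fraction[i]),
               flow_peak = if (any(j)) max(record$pump$q_est[j]) else NA_real_,
               flow_peak_dyn = if (any(j)) max(record$pump$q_dyn[j])
               else NA_real_,
               min_p_lv = min(record$hemo$p_lv[i]))
  })
  do.call(rbind, out)
}

#' @export
print.signal_record <- function(x, ...) {
  cat("<signal_record> profile", x$meta$profile, "| speed",
      x$meta$speed_rpm, "rpm | stage", x$meta$stage %||% 0, "\n")
  cat(sprintf("  %.1f s of hemodynamics at 1 kHz, pump telemetry at 50 Hz\n",
              nrow(x$hemo) / 1000))
  if (!is.null(x$beats))
    cat(sprintf("  %d whole beats, %d with suction\n", nrow(x$beats),
                sum(x$beats$suction)))
  invisible(x)
}

# Integrate beat by beat until the periodic-steady-state criterion
# holds: relative change of beat CO and EDV below `tol` across three
# consecutive beats.
.settle <- function(state, pv, hr, t0, max_beats = 200, tol = 0.005) {
  T <- round(60 / hr * 1000) / 1000
  co <- edv <- rep(NA_real_, max_beats)
  t <- t0
  for (b in seq_len(max_beats)) {
    seg <- .run_segment(state, pv, T, t)
    state <- seg$state
    t <- seg$t_end
    co[b] <- mean(seg$signals[, "q_sys"])
    edv[b] <- max(seg$signals[, "v_lv"])
    if (b >= 3) {
      rel <- function(x) max(abs(diff(x))) / max(abs(x[3]), 1e-9)
      if (rel(co[(b - 2):b]) < tol && rel(edv[(b - 2):b]) < tol)
        return(list(state = state, t = t, beats = b))
    }
  }
  stop("no periodic steady state within ", max_beats,
       " beats; last beat CO trend (mL/s): ",
       paste(round(tail(co[!is.na(co)], 5), 2), collapse = ", "),
       call. = FALSE)
}

#' Steady-state run of the coupled system
#'
#' Integrates the coupled cardiovascular-pump-suction system from
#' standard initial conditions until the periodic-steady-state
#' criterion holds (beat CO and EDV changing by less than 0.5% over
#' three consecutive beats), then records `duration` seconds and
#' summarizes the hemodynamics over whole beats.
#'
#' @param config an [experiment_config()].
#' @param duration recorded duration, s.
#' @param speed pump speed, rpm; defaults to the pump's setpoint.
#' @return list of class `steady_run` with elements `record` (a
#'   `signal_record`) and `summary` (a `hemodynamic_summary`).
#' @examples
#' \donttest{
#' run <- run_steady(experiment_config(builtin_profile("DCM")), duration = 6)
#' run$summary
#' }
#' @export
run_steady <- function(config, duration = 10, speed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  speed <- speed %||% config$pump$speed_setpoint
  pv <- .cpp_param_vector(config$profile, config$pump, config$suction,
                          speed, config$solver$dt %||% 2.5e-4)
  state <- .init_state(config$profile, config$pump, speed)
  st <- .settle(state, pv, config$profile$hr, 0)
  warm <- 4  # filter warm-up, discarded
  seg <- .run_segment(st$state, pv, warm + duration, st$t)
  meta <- list(profile = config$profile$name, speed_rpm = speed,
               stage = 0, volume_fraction = 1, hr = config$profile$hr,
               fs_hemo = 1000, fs_pump = 50,
               tbv = config$profile$total_blood_volume)
  rec <- .make_signal_record(seg$signals, meta, config$pump,
                             config$noise, drop_s = warm)
  structure(list(record = rec, summary = summarize_hemodynamics(rec),
                 state = seg$state, t_end = seg$t_end,
                 settle_beats = st$beats),
            class = "steady_run")
}

#' @export
print.steady_run <- function(x, ...) {
  print(x$record); print(x$summary); invisible(x)
}

#' Hemodynamic summary over whole beats
#'
#' Beat-aligned summary of a `signal_record`: cardiac output (beat-mean
#' systemic flow), systolic/diastolic/mean systemic and pulmonary
#' arterial pressures, wedge pressure surrogate (beat-mean left atrial
#' pressure), end-diastolic and end-systolic LV volumes, beat-mean pump
#' flow and the peak of the 50-Hz estimated flow.
#'
#' @param record a `signal_record`.
#' @return object of class `hemodynamic_summary`.
#' @export
summarize_hemodynamics <- function(record) {
  T <- 60 / record$meta$hr
  t <- record$hemo$t
  k0 <- ceiling(t[1] / T - 1e-9); k1 <- floor((t[length(t)] + 1e-3) / T) - 1
  if (k1 < k0) stop("record shorter than one whole beat", call. = FALSE)
  per_beat <- function(x, f) {
    vapply(k0:k1, function(k) f(x[t >= k * T - 1e-9 & t < (k + 1) * T - 1e-9]),
           numeric(1))
  }
  h <- record$hemo
  in_window <- t >= k0 * T - 1e-9 & t < (k1 + 1) * T - 1e-9
  s <- list(
    co = mean(h$q_sys[in_window]) * 0.06,
    sap_sys = mean(per_beat(h$p_ao, max)),
    sap_dia = mean(per_beat(h$p_ao, min)),
    sap_mean = mean(h$p_ao[in_window]),
    pap_sys = mean(per_beat(h$p_pa, max)),
    pap_dia = mean(per_beat(h$p_pa, min)),
    pap_mean = mean(h$p_pa[in_window]),
    pcwp = mean(h$p_la[in_window]),
    edv = mean(per_beat(h$v_lv, max)),
    esv = mean(per_beat(h$v_lv, min)),
    pump_flow_mean = mean(h$q_pump[in_window]) * 0.06,
    pump_flow_peak = if (nrow(record$pump)) max(record$pump$q_est) else NA,
    n_beats = k1 - k0 + 1)
  stopifnot(s$sap_sys >= s$sap_mean - 1e-6, s$sap_mean >= s$sap_dia - 1e-6,
            s$edv >= s$esv)
  structure(s, class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<hemodynamic_summary> (%d beats)\n",
           "  CO %.2f L/min | SAP %.0f/%.0f (%.0f) mmHg | ",
           "PAP %.0f/%.0f (%.0f) mmHg\n",
           "  PCWP %.1f mmHg | EDV %.0f mL | ESV %.0f mL | ",
           "pump flow %.2f L/min (peak %.2f)\n"),
    x$n_beats, x$co, x$sap_sys, x$sap_dia, x$sap_mean, x$pap_sys,
    x$pap_dia, x$pap_mean, x$pcwp, x$edv, x$esv, x$pump_flow_mean,
    x$pump_flow_peak))
  invisible(x)
}

# withdraw `dv` mL from the venous reservoirs, proportionally to their
# current volumes (hypovolemia emulation)
.withdraw_volume <- function(state, dv) {
  v_sv <- state[6]; v_pv <- state[8]
  tot <- v_sv + v_pv
  if (dv >= 0.8 * tot)
    stop("protocol error: venous reservoirs too depleted to withdraw ",
         round(dv), " mL", call. = FALSE)
  state[6] <- v_sv - dv * v_sv / tot
  state[8] <- v_pv - dv * v_pv / tot
  state
}

#' Hypovolemia ramp at a fixed pump speed
#'
#' Starting from the baseline steady state, the total circulating blood
#' volume is reduced stepwise (default 2% of baseline per stage, with a
#' settling window after each step and at least 15 recorded beats per
#' stage) until suction is triggered and a beat's 50-Hz estimated-flow
#' peak falls below the stop criterion (default 2 L/min). Near suction
#' onset (once the beat minimum of LV pressure falls below
#' `refine_below` mmHg) the decrement is refined to an eighth of the
#' nominal step, so the transition from intermittent to continuous
#' suction is resolved into several stages instead of being skipped in
#' one step. The flow-peak stop rule is evaluated on the dynamic pump
#' flow (true flow, anti-alias filtered to the 50-Hz grid) rather than
#' the firmware-averaged estimate, whose suppressed pulsatility would
#' systematically bias the peak low. All stage records are returned
#' with their volume labels.
#'
#' @param config an [experiment_config()].
#' @param speed pump speed for the ramp, rpm.
#' @param max_volume_loss abort fraction: if the criterion is not
#'   reached after losing this fraction of blood volume, a protocol
#'   error is raised.
#' @param final_hold_beats extra beats recorded at the terminal volume
#'   after the stop criterion fires (the suction condition is held so
#'   enough suction beats are captured for the beat dataset); 0
#'   disables the hold.
#' @param refine_below LV-pressure threshold (mmHg) below which the
#'   volume decrement switches to the refined step.
#' @return list of `signal_record`s (stage 0 = baseline), with
#'   attribute `stages` (a data.frame summary per stage).
#' @export
hypovolemia_ramp <- function(config, speed = NULL, max_volume_loss = 0.5,
                             final_hold_beats = 70, refine_below = 2) {
  stopifnot(inherits(config, "experiment_config"))
  speed <- speed %||% config$pump$speed_setpoint
  pv <- .cpp_param_vector(config$profile, config$pump, config$suction,
                          speed, config$solver$dt %||% 2.5e-4)
  tbv0 <- config$profile$total_blood_volume
  T <- round(60 / config$profile$hr * 1000) / 1000
  state <- .init_state(config$profile, config$pump, speed)
  st <- .settle(state, pv, config$profile$hr, 0)
  state <- st$state; t <- st$t
  settle_s <- config$settle_beats * T
  rec_s <- config$n_beats_per_stage * T
  removed <- 0
  records <- list()
  stage <- 0
  step_w <- 1  # fraction of the nominal volume step this stage covers
  repeat {
    seg <- .run_segment(state, pv, settle_s + rec_s, t)
    state <- seg$state; t <- seg$t_end
    meta <- list(profile = config$profile$name, speed_rpm = speed,
                 stage = stage, volume_fraction = 1 - removed / tbv0,
                 hr = config$profile$hr, fs_hemo = 1000, fs_pump = 50,
                 tbv = tbv0 - removed, step_weight = step_w)
    rec <- .make_signal_record(seg$signals, meta, config$pump,
                               config$noise, drop_s = settle_s)
    records[[stage + 1]] <- rec
    hit <- any(rec$beats$suction) &&
      min(rec$beats$flow_peak_dyn, na.rm = TRUE) <
        config$stop_criterion_flow_peak
    if (hit) {
      if (final_hold_beats > 0) {
        seg <- .run_segment(state, pv, settle_s + final_hold_beats * T, t)
        meta$stage <- stage + 0.5
        records[[length(records) + 1]] <-
          .make_signal_record(seg$signals, meta, config$pump,
                              config$noise, drop_s = settle_s)
      }
      break
    }
    if (removed / tbv0 >= max_volume_loss)
      stop("protocol error: stop criterion not reached after ",
           round(100 * max_volume_loss), "% volume loss at ", speed,
           " rpm", call. = FALSE)
    refine <- min(rec$beats$min_p_lv) < refine_below
    dv <- config$hypovolemia_step * tbv0 / (if (refine) 4 else 1)
    state <- .withdraw_volume(state, dv)
    removed <- removed + dv
    stage <- stage + 1
  }
  stages <- do.call(rbind, lapply(records, function(r)
    data.frame(stage = r$meta$stage,
               volume_fraction = r$meta$volume_fraction,
               n_beats = nrow(r$beats),
               n_suction = sum(r$beats$suction),
               min_p_lv = min(r$hemo$p_lv),
               flow_peak_min = min(r$beats$flow_peak_dyn, na.rm = TRUE))))
  attr(records, "stages") <- stages
  records
}

# deterministic per-speed allocation of a total beat quota
.quota_split <- function(total, n_speeds) {
  base <- total %/% n_speeds
  extra <- total - base * n_speeds
  base + c(rep(1, extra), rep(0, n_speeds - extra))
}

# evenly-spaced subsample of k elements from 1..n (chronological)
.even_subsample <- function(n, k) {
  if (k >= n) return(seq_len(n))
  unique(round(seq(1, n, length.out = k)))
}

# subsample k indices evenly spaced in cumulative weight
.weighted_subsample <- function(w, k) {
  if (k >= length(w)) return(seq_along(w))
  cw <- cumsum(w)
  targets <- seq(cw[1], cw[length(cw)], length.out = k)
  unique(vapply(targets, function(tg) which.min(abs(cw - tg)), integer(1)))
}

#' Full suction protocol: speed sweep with hypovolemia ramps
#'
#' Runs the hypovolemia ramp for each profile at each pump speed of the
#' sweep, segments the 50-Hz telemetry of every stage into beats with
#' the beat detector, attaches the simulator's per-beat ground-truth
#' suction flag, and assembles a labeled beat dataset. Per profile and
#' speed, beat quotas (evenly subsampled over the ramp chronology) keep
#' the totals at the configured counts — by default about 183 suction /
#' 19 non-suction beats for the DCM and 168 / 21 for the RCM.
#'
#' @param config an [experiment_config()]; its profile slot is ignored
#'   in favour of `profiles`.
#' @param profiles character vector of built-in profile names (or a
#'   list of [patient_profile()]s).
#' @param quotas named list per profile with elements
#'   `c(suction = , non_suction = )`.
#' @param keep_records `"none"`, or `"example"` to retain a baseline and
#'   a deep-suction `signal_record` per profile for morphology checks.
#' @return object of class `beat_dataset`: list with `beats` (one row
#'   per beat: profile, speed, stage, timing, ground truth), `segments`
#'   (per-beat 50-Hz pump channels) and optionally `examples`.
#' @export
full_protocol <- function(config = experiment_config(),
                          profiles = c("DCM", "RCM"),
                          quotas = list(
                            DCM = c(suction = 183, non_suction = 19),
                            RCM = c(suction = 168, non_suction = 21)),
                          keep_records = "example") {
  beats_all <- list(); segs_all <- list(); examples <- list()
  for (pr in profiles) {
    prof <- if (inherits(pr, "patient_profile")) pr else builtin_profile(pr)
    cfg <- config
    cfg$profile <- prof
    speeds <- cfg$speed_list
    qa <- quotas[[prof$name]] %||% c(suction = Inf, non_suction = Inf)
    prof_beats <- NULL; prof_segs <- list()
    for (si in seq_along(speeds)) {
      ramp <- hypovolemia_ramp(cfg, speeds[si])
      cand <- .ramp_beats(ramp, cfg)
      if (nrow(cand$beats)) {
        prof_beats <- rbind(prof_beats, cand$beats)
        prof_segs <- c(prof_segs, cand$segments)
      }
      if (keep_records == "example" && si == 1) {
        if (is.null(examples[[paste0(prof$name, "_baseline")]]))
          examples[[paste0(prof$name, "_baseline")]] <- ramp[[1]]
        examples[[paste0(prof$name, "_suction")]] <-
          ramp[[length(ramp)]]
      }
    }
    # per-profile quotas over the pooled (speed, stage) chronology.
    # Suction beats are subsampled evenly by beat (all severities and
    # speeds contribute); non-suction reference beats are subsampled
    # uniformly per unit of removed blood volume, as a continuous
    # hardware ramp would record them — the refined stages near the
    # suction transition carry proportionally less weight
    for (cls in c(TRUE, FALSE)) {
      pool <- which(prof_beats$suction == cls)
      want <- if (cls) qa[["suction"]] else qa[["non_suction"]]
      takei <- if (cls) pool[.even_subsample(length(pool), want)]
      else pool[.weighted_subsample(prof_beats$step_weight[pool], want)]
      beats_all[[length(beats_all) + 1]] <- prof_beats[takei, ]
      segs_all <- c(segs_all, prof_segs[takei])
    }
  }
  beats <- do.call(rbind, beats_all)
  rownames(beats) <- NULL
  structure(list(beats = beats, segments = segs_all,
                 examples = if (length(examples)) examples),
            class = "beat_dataset")
}

# Detect beats on each stage's 50-Hz telemetry, label each detected
# beat with the simulator ground truth, return per-beat metadata and
# pump-channel segments.
.ramp_beats <- function(ramp, config) {
  beats <- list(); segs <- list()
  for (rec in ramp) {
    bt <- tryCatch(detect_beats(rec$pump$q_est, fs = rec$meta$fs_pump),
                   warning = function(w) NULL)
    if (is.null(bt) || nrow(bt) == 0) next
    for (bi in seq_len(nrow(bt))) {
      i0 <- bt$start[bi]; i1 <- bt$end[bi]
      tw <- rec$pump$t[c(i0, i1 - 1)]
      hsel <- rec$hemo$t >= tw[1] - 1e-9 & rec$hemo$t <= tw[2] + 0.02
      truth <- suction_ground_truth(
        rec$hemo$collapse_fraction[hsel],
        threshold = config$suction$ground_truth_fraction)
      seg <- rec$pump[i0:(i1 - 1),
                      c("t", "omega_rpm", "current", "power", "q_est")]
      beats[[length(beats) + 1]] <- data.frame(
        profile = rec$meta$profile, speed_rpm = rec$meta$speed_rpm,
        stage = rec$meta$stage,
        volume_fraction = rec$meta$volume_fraction,
        step_weight = rec$meta$step_weight %||% 1,
        t_start = tw[1], duration = bt$duration[bi],
        min_p_lv = min(rec$hemo$p_lv[hsel]), suction = truth)
      segs[[length(beats)]] <- seg
    }
  }
  list(beats = if (length(beats)) do.call(rbind, beats) else
    data.frame(suction = logical(0)), segments = segs)
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat("<beat_dataset>", nrow(x$beats), "beats\n")
  if (nrow(x$beats)) {
    tab <- table(x$beats$profile, ifelse(x$beats$suction, "suction",
                                         "non-suction"))
    print(tab)
  }
  invisible(x)
}
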