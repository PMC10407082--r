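#' Synthetic labeled pump telemetry
#'
#' Generates idealized 50-Hz pump telemetry with known beat timing and
#' suction labels, independent of the physiological simulator. Each
#' cycle starts at the beginning of diastole. Non-suction beats carry a
#' smooth systolic flow pulse (and the matching biphasic speed
#' excursion); suction beats carry a weak systolic pulse plus an
#' end-systolic negative flow spike and a positive speed spike. Useful
#' as a ground-truthed fixture for the detection pipeline.
#'
#' @param hr heart rate, bpm.
#' @param duration record length, s.
#' @param suction logical: generate suction-type beats.
#' @param base_flow diastolic flow level, L/min.
#' @param pulse_amp systolic pulse amplitude, L/min.
#' @param spike_depth suction spike depth, L/min.
#' @param speed_setpoint nominal speed, rpm.
#' @param noise_sd additive white-noise SD on the flow channel, L/min.
#' @param fs sample rate, Hz.
#' @param seed optional RNG seed for the noise.
#' @return list with `telemetry` (data.frame in the
#'   [read_telemetry()] schema), `onsets` (true diastole-start times,
#'   s) and `suction` (the label).
#' @export
synthetic_telemetry <- function(hr = 78, duration = 60, suction = FALSE,
                                base_flow = 4, pulse_amp = 3,
                                spike_depth = 2.5, speed_setpoint = 2800,
                                noise_sd = 0, fs = 50, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  T <- 60 / hr
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  ph <- (t %% T) / T  # 0 = beginning of diastole
  # systole occupies the last 35% of the cycle in this convention
  sys_on <- 0.65
  in_sys <- ph >= sys_on
  pulse_shape <- ifelse(in_sys, sin(pi * (ph - sys_on) / (1 - sys_on))^2, 0)
  amp <- if (suction) 0.25 * pulse_amp else pulse_amp
  q <- base_flow + amp * pulse_shape
  w <- rep(speed_setpoint, length(t))
  w <- w - (if (suction) 20 else 80) * pulse_shape +
    (if (suction) 0 else 50) * ifelse(in_sys,
                                      sin(2 * pi * (ph - sys_on) /
                                            (1 - sys_on)) * -1, 0)
  if (suction) {
    # end-systolic collapse: negative flow spike, positive speed spike
    spike_c <- 0.97
    spike <- exp(-((ph - spike_c) / 0.015)^2)
    q <- q - spike_depth * spike
    w <- w + 100 * spike
  }
  if (noise_sd > 0) q <- q + rnorm(length(q), 0, noise_sd)
  current <- 0.9 + 0.05 * (q - base_flow)
  power <- current * speed_setpoint * pi / 30 * 0.02
  list(telemetry = data.frame(time_s = t, speed_rpm = w,
                              current_A = current, power_W = power,
                              flow_est_lpm = q),
       onsets = seq(0, duration - T, by = T),
       suction = suction)
}
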