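#' Pump differential pressure (head) from the quadratic characteristic
#'
#' `dP = a0 * w^2 + a1 * w * q + a2 * q^2` with speed `w` in rpm, flow
#' `q` in L/min and head in mmHg. With the shipped HVAD-like
#' coefficients the head is monotone decreasing in flow over the
#' operating range at fixed speed.
#'
#' @param q pump flow, L/min.
#' @param omega impeller speed, rpm.
#' @param coeffs numeric `c(a0, a1, a2)`.
#' @return head pressure, mmHg.
#' @export
head_pressure <- function(q, omega, coeffs = pump_params()$hq_coeffs) {
  stopifnot(all(omega >= 0))
  coeffs[[1]] * omega^2 + coeffs[[2]] * omega * q + coeffs[[3]] * q^2
}

#' One step of the PI speed controller
#'
#' Proportional-integral control of impeller speed with an anti-windup
#' clamp: the integral state freezes whenever the commanded current is
#' saturated in the direction of the error. Output current is limited
#' to `[0, i_max]`.
#'
#' @param omega measured impeller speed, rpm.
#' @param setpoint speed setpoint, rpm.
#' @param integral current integral state, A.
#' @param gains `c(kp, ki)` in A/(rad/s) and A/(rad/s)/s.
#' @param dt step, s.
#' @param i_max current limit, A.
#' @return list with `current` (A) and updated `integral`.
#' @export
controller_step <- function(omega, setpoint, integral,
                            gains = pump_params()$controller_gains,
                            dt = 1e-3, i_max = 3) {
  stopifnot(all(gains > 0))
  err <- (setpoint - omega) * pi / 30  # rpm -> rad/s
  cmd <- gains[[1]] * err + integral
  current <- min(max(cmd, 0), i_max)
  windup <- (cmd >= i_max && err > 0) || (cmd <= 0 && err < 0)
  if (!windup) integral <- integral + gains[[2]] * err * dt
  list(current = current, integral = integral)
}

#' One explicit step of the impeller/motor dynamics
#'
#' `J * domega/dt = kt * I - T_hydraulic - b * omega` with the hydraulic
#' load torque `T = (c0 + c1 * q) * omega` (q in L/min, omega in rad/s,
#' clamped at zero for reverse flow). The controller supplies the motor
#' current. Used as a single-step reference for the compiled solver and
#' for open-loop experiments.
#'
#' @param state list with `omega` (rpm), `integral` (A).
#' @param q_lpm pump flow, L/min (sets the hydraulic load torque).
#' @param dt step, s (must be <= 1 ms).
#' @param params a [pump_params()].
#' @return updated state list with `omega`, `integral`, `current`,
#'   `power` (W).
#' @export
step_motor <- function(state, q_lpm, dt, params = pump_params()) {
  if (dt > 1e-3) stop("dt must be <= 1 ms", call. = FALSE)
  w <- state$omega * pi / 30
  ctrl <- controller_step(state$omega, params$speed_setpoint,
                          state$integral, params$controller_gains, dt,
                          params$i_max)
  tc <- params$torque_coeffs
  t_hyd <- max(0, (tc[[1]] + tc[[2]] * q_lpm) * w)
  dw <- (params$torque_constant * ctrl$current - t_hyd -
           params$friction_coeff * w) / params$impeller_inertia
  w_new <- w + dw * dt
  if (w_new <= 0) stop("pump stall: impeller speed reached zero",
                       call. = FALSE)
  list(omega = w_new * 30 / pi, integral = ctrl$integral,
       current = ctrl$current,
       power = params$torque_constant * ctrl$current * w)
}

#' On-device flow estimator
#'
#' Static map from motor current and impeller speed to estimated pump
#' flow: `q_est = (kt * I - drag * w) / (slope * w)` with `w` in rad/s.
#' With the default coefficients (derived from the motor model) the
#' estimate is exact whenever the impeller is in torque equilibrium, so
#' beat-mean estimated flow tracks beat-mean true flow closely in
#' non-suction steady states; fast transients (impeller acceleration)
#' distort it, as on the physical device.
#'
#' @param i_motor motor current, A.
#' @param omega impeller speed, rpm.
#' @param coeffs `c(kt, drag, slope)`; see [pump_params()].
#' @return estimated flow, L/min.
#' @export
estimate_flow <- function(i_motor, omega,
                          coeffs = pump_params()$estimator_coeffs) {
  stopifnot(all(omega > 0))
  w <- omega * pi / 30
  (coeffs[[1]] * i_motor - coeffs[[2]] * w) / (coeffs[[3]] * w)
}
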