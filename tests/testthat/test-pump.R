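test_that("head curve is anchored and monotone decreasing in flow", {
  expect_equal(head_pressure(0, 0), 0)
  q <- seq(0, 8, by = 0.1)
  h <- head_pressure(q, 2800)
  expect_true(all(diff(h) < 0))
  # closed-loop consistency: head at the DCM operating point matches
  # the arterial-minus-ventricular gradient plus cannula losses
  run <- cached_steady("DCM")
  h <- run$record$hemo
  q_op <- mean(h$q_pump)            # mL/s
  grad <- mean(h$p_ao - h$p_lv)
  pp <- pump_params(); sp <- suction_params()
  losses <- (pp$r_outflow + sp$r_open) * q_op
  expect_equal(head_pressure(q_op * 0.06, 2800), grad + losses,
               tolerance = 0.04)
})

test_that("PI controller has correct sign, integral growth and anti-windup", {
  g <- c(kp = 0.05, ki = 0.5)
  at_set <- controller_step(2800, 2800, integral = 0.9, gains = g)
  expect_equal(at_set$current, 0.9)        # baseline current
  below <- controller_step(2700, 2800, integral = 0.9, gains = g)
  expect_gt(below$current, at_set$current) # speed low -> more current
  # integral grows as ki * e * dt per step
  e_rad <- (2800 - 2700) * pi / 30
  expect_equal(below$integral - 0.9, 0.5 * e_rad * 1e-3)
  # anti-windup: integral frozen while saturated in the error direction
  sat <- controller_step(1800, 4000, integral = 10, gains = g, i_max = 3)
  expect_equal(sat$current, 3)
  expect_equal(sat$integral, 10)
  expect_error(controller_step(2800, 2800, 0, gains = c(-1, 1)), "gains")
})

test_that("motor step holds equilibrium and recovers from load steps", {
  pp <- pump_params()
  w0 <- pp$speed_setpoint
  tc <- pp$torque_coeffs
  q0 <- 4.7
  i0 <- ((tc[[1]] + tc[[2]] * q0) * (w0 * pi / 30) +
           pp$friction_coeff * (w0 * pi / 30)) / pp$torque_constant
  st <- list(omega = w0, integral = i0)
  st1 <- step_motor(st, q0, dt = 1e-3, pp)
  expect_equal(st1$omega, w0, tolerance = 1e-3)    # equilibrium holds
  expect_gte(st1$power, 0)
  # load-torque step: speed dips, controller recovers toward setpoint
  st <- list(omega = w0, integral = i0)
  for (i in 1:400) st <- step_motor(st, q0 + 3, dt = 1e-3, pp)
  dip <- st$omega
  expect_lt(dip, w0)
  for (i in 1:4000) st <- step_motor(st, q0 + 3, dt = 1e-3, pp)
  expect_lt(abs(st$omega - w0), abs(dip - w0))
  expect_error(step_motor(list(omega = w0, integral = 0), 1, dt = 0.1, pp),
               "dt")
})

test_that("flow estimator is exact in torque equilibrium and tracks beat means", {
  pp <- pump_params()
  w <- 2800; q <- 5.2
  tc <- pp$torque_coeffs
  i_eq <- ((tc[[1]] + tc[[2]] * q) * (w * pi / 30) +
             pp$friction_coeff * (w * pi / 30)) / pp$torque_constant
  expect_equal(estimate_flow(i_eq, w), q, tolerance = 1e-10)
  expect_error(estimate_flow(1, 0), "omega")
  # calibration property on a non-suction steady state: beat-mean
  # estimated flow within 10% of beat-mean true pump flow
  run <- cached_steady("DCM")
  q_true <- mean(run$record$hemo$q_pump) * 0.06
  q_est <- mean(run$record$pump$q_est)
  expect_lt(abs(q_est - q_true) / q_true, 0.10)
})

test_that("speed regulation and intra-beat excursions match the device", {
  run <- cached_steady("DCM")
  om <- run$record$pump$omega_rpm
  expect_lt(abs(mean(om) - 2800), 5)  # beat-mean drift under 5 rpm
  # biphasic intra-beat excursion on the order of +/-50 rpm
  expect_gt(max(om) - min(om), 50)
  expect_lt(max(om) - min(om), 200)
  expect_true(all(run$record$pump$power >= 0))
})
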