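test_that("activation is zero at cycle start, unit-peak, periodic", {
  hr <- 78
  t <- seq(0, 60 / hr, length.out = 2000)
  a <- activation(t, hr)
  expect_equal(a[1], 0)
  expect_equal(max(a), 1, tolerance = 1e-5)
  expect_equal(sum(diff(sign(diff(a))) < 0), 1)  # single peak
  t0 <- c(0.1, 0.37, 0.62)
  expect_equal(activation(t0, hr), activation(t0 + 60 / hr, hr))
  expect_error(activation(0.1, hr = 0), "hr")
})

test_that("EDPVR coefficient reproduces the V30 anchor exactly", {
  for (p in c("DCM", "RCM")) {
    prof <- builtin_profile(p)
    k <- edpvr_k(prof$s_lv, prof$v0_lv, prof$v30)
    expect_equal(prof$s_lv * expm1(k * (prof$v30 - prof$v0_lv)), 30)
  }
})

test_that("chamber pressure follows EDPVR at rest and ESPVR at peak", {
  dcm <- builtin_profile("DCM")
  pars <- list(ees = dcm$ees_lv, v0 = dcm$v0_lv, s = dcm$s_lv,
               v30 = dcm$v30, hr = dcm$hr, shape = dcm$activation)
  # end-diastole (activation 0): P(V30) = 30 mmHg, P(V0) = 0
  expect_equal(chamber_pressure(dcm$v30, 0, pars), 30)
  expect_equal(chamber_pressure(dcm$v0_lv, 0, pars), 0)
  # peak activation: linear ESPVR with slope Ees
  tpk <- optimize(function(t) activation(t, dcm$hr, dcm$activation),
                  c(0, 60 / dcm$hr), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(chamber_pressure(dcm$v0_lv + 10, tpk, pars),
               dcm$ees_lv * 10, tolerance = 1e-4)
  # floor engages for strongly negative pressures
  expect_equal(chamber_pressure(dcm$v0_lv - 500, tpk, pars), -20)
})

test_that("valve flow is a diode-resistance law", {
  expect_equal(valve_flow(10, 20, 0.01), 0)
  expect_equal(valve_flow(15, 15, 0.01), 0)
  expect_equal(valve_flow(20, 10, 0.01), 1000)
})

test_that("closed-loop volume derivatives conserve volume", {
  dcm <- builtin_profile("DCM")
  set.seed(42)
  for (i in 1:20) {
    vols <- c(v_lv = runif(1, 60, 200), v_la = runif(1, 20, 90),
              v_rv = runif(1, 20, 160), v_ra = runif(1, 20, 70),
              v_sa = runif(1, 550, 650), v_sv = runif(1, 2900, 3400),
              v_pa = runif(1, 90, 180), v_pv = runif(1, 320, 480))
    d <- circulation_derivatives(vols, runif(1, 0, 0.7), dcm,
                                 q_pump = runif(1, 0, 100))
    expect_equal(sum(d$dv), 0, tolerance = 1e-10)
  }
  expect_error(circulation_derivatives(
    c(v_lv = NaN, v_la = 50, v_rv = 80, v_ra = 40, v_sa = 600,
      v_sv = 3000, v_pa = 120, v_pv = 380), 0, dcm), "non-finite")
})

test_that("a pressure-equilibrated state with no pump flow is stationary", {
  dcm <- builtin_profile("DCM")
  p_eq <- 5  # mmHg everywhere, diastolic instant
  t_dia <- 0.95 * 60 / dcm$hr  # activation ~ 0
  k_lv <- edpvr_k(dcm$s_lv, dcm$v0_lv, dcm$v30)
  k_rv <- edpvr_k(dcm$rv_params$s, dcm$rv_params$v0, dcm$rv_params$v30)
  vols <- c(
    v_lv = dcm$v0_lv + log1p(p_eq / dcm$s_lv) / k_lv,
    v_la = dcm$atrial_params$v0_la + p_eq / dcm$atrial_params$e_la,
    v_rv = dcm$rv_params$v0 + log1p(p_eq / dcm$rv_params$s) / k_rv,
    v_ra = dcm$atrial_params$v0_ra + p_eq / dcm$atrial_params$e_ra,
    v_sa = dcm$systemic$v0_arterial + p_eq * dcm$systemic$compliance,
    v_sv = dcm$systemic$v0_venous + p_eq * dcm$systemic$venous_compliance,
    v_pa = dcm$pulmonary$v0_arterial + p_eq * dcm$pulmonary$compliance,
    v_pv = dcm$pulmonary$v0_venous + p_eq * dcm$pulmonary$venous_compliance)
  d <- circulation_derivatives(vols, t_dia, dcm, q_pump = 0)
  expect_true(all(abs(d$dv) < 1e-3))
})
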