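test_that("steady runs conserve blood volume to solver precision", {
  for (p in c("DCM", "RCM")) {
    run <- cached_steady(p)
    drift <- max(abs(run$record$hemo$v_total - run$record$meta$tbv))
    expect_lt(drift, 0.1)
  }
})

test_that("summary invariants hold: pressure ordering and volume ordering", {
  for (p in c("DCM", "RCM")) {
    s <- cached_steady(p)$summary
    expect_gte(s$sap_sys, s$sap_mean); expect_gte(s$sap_mean, s$sap_dia)
    expect_gte(s$pap_sys, s$pap_mean); expect_gte(s$pap_mean, s$pap_dia)
    expect_gt(s$edv, s$esv); expect_gte(s$esv, 0)
    expect_gt(s$sap_dia, 0)  # no negative arterial pressures
  }
})

test_that("simulation is deterministic: identical config gives identical records", {
  cfg <- experiment_config(builtin_profile("RCM"))
  r1 <- run_steady(cfg, duration = 3)
  r2 <- run_steady(cfg, duration = 3)
  expect_identical(r1$record$hemo, r2$record$hemo)
  expect_identical(r1$record$pump, r2$record$pump)
})

test_that("detected beat period equals the heart period within one sample", {
  run <- cached_steady("DCM")
  b <- detect_beats(run$record$pump$q_est, fs = 50)
  expect_gt(nrow(b), 5)
  expect_lt(abs(median(b$duration) - 60 / 78), 1 / 50 + 1e-9)
})

test_that("50-Hz decimation preserves beat means of smooth channels", {
  # a 1.3-Hz modulated signal decimated through the pump pipeline keeps
  # its mean to better than 1%
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  x <- 4 + sin(2 * pi * 1.3 * t)
  filt <- suctionsim:::.lowpass(x, 15, 1000)
  dec <- filt[seq(1, length(filt), by = 20)]
  expect_lt(abs(mean(dec) - mean(x)) / mean(x), 0.01)
  # and the record's 50-Hz estimated flow tracks the true mean flow
  run <- cached_steady("DCM")
  expect_lt(abs(mean(run$record$pump$q_est) -
                  mean(run$record$hemo$q_pump) * 0.06) /
              (mean(run$record$hemo$q_pump) * 0.06), 0.05)
})

test_that("reducing blood volume lowers the LV pressure peak (Frank-Starling)", {
  base <- cached_steady("DCM")
  prof <- builtin_profile("DCM")
  prof$total_blood_volume <- prof$total_blood_volume * 0.9
  dep <- run_steady(experiment_config(prof), duration = 5)
  expect_lt(max(dep$record$hemo$p_lv), max(base$record$hemo$p_lv))
})

test_that("hypovolemia ramp terminates at the stop criterion with labels", {
  ramp <- cached_ramp("DCM")
  st <- attr(ramp, "stages")
  expect_false(any(ramp[[1]]$beats$suction))       # baseline non-suction
  last <- ramp[[length(ramp)]]
  expect_true(any(last$beats$suction))
  expect_lt(min(st$flow_peak_min[nrow(st)]), 2)    # flow peak < 2 L/min
  # per-beat min LV pressure non-increasing across stages (monotone
  # preload loss), modulo the small limit-cycle tolerance
  expect_true(all(diff(st$min_p_lv) < 0.5))
  # volume fractions decrease
  expect_true(all(diff(st$volume_fraction) < 1e-12))
})

test_that("suction-labeled beats sit at the collapse threshold", {
  ramp <- cached_ramp("DCM")
  base_min <- min(ramp[[1]]$beats$min_p_lv)
  labeled <- unlist(lapply(ramp, function(rec)
    rec$beats$min_p_lv[rec$beats$suction]))
  expect_gt(length(labeled), 0)
  # the buckling latch can fire marginally above 0 mmHg; every labeled
  # beat is within the ~1 mmHg engagement band of the threshold and far
  # below any baseline beat
  expect_lt(max(labeled), 1)
  expect_lt(max(labeled), base_min)
})

test_that("full protocol assembles labeled beats near the configured counts", {
  ds <- cached_protocol()
  tab <- table(ds$beats$profile, ds$beats$suction)
  # suction beats match the configured counts to their order of
  # magnitude (deep DCM suction flow has so little pulsatility that
  # not every recorded beat is segmentable from the estimated flow)
  expect_gt(unname(tab["DCM", "TRUE"]), 90)
  expect_lte(unname(tab["DCM", "TRUE"]), 183)
  expect_equal(unname(tab["RCM", "TRUE"]), 168)
  expect_equal(unname(tab["DCM", "FALSE"]), 19)
  expect_equal(unname(tab["RCM", "FALSE"]), 21)
  expect_equal(length(ds$segments), nrow(ds$beats))
  # every segment carries the pump channels for its beat
  expect_true(all(vapply(ds$segments, function(s)
    all(c("omega_rpm", "q_est") %in% names(s)), logical(1))))
})
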