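test_that("beat detector recovers the heart rate on synthetic telemetry", {
  for (suction in c(FALSE, TRUE)) {
    syn <- synthetic_telemetry(hr = 78, duration = 62, suction = suction)
    b <- detect_beats(syn$telemetry$flow_est_lpm)
    # beat rate over the tiled span of detected beats
    n_per_min <- nrow(b) / (sum(b$duration) / 60)
    expect_lt(abs(n_per_min - 78), 2)
    expect_lt(abs(median(b$duration) - 60 / 78), 1 / 50 + 1e-9)
  }
})

test_that("flat or degenerate signals yield zero beats with a warning", {
  expect_warning(b <- detect_beats(rep(4, 500)), "flat")
  expect_equal(nrow(b), 0)
  expect_error(detect_beats(rep(4, 100)), "5 s")
})

test_that("features match analytic derivatives on a sinusoid", {
  fs <- 50
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  q <- 4 + sin(2 * pi * 1.3 * t)
  omega <- rep(2800, length(t))
  beat <- list(start = 101L, end = 101L + 38L, diastole_start = 101L)
  f <- extract_features(beat, q, omega, fs)
  expect_equal(unname(f["dqdt_min"]), -2 * pi * 1.3, tolerance = 0.02)
  expect_equal(unname(f["d_omega_min"]), 0)
  expect_gte(f["t_dqdt_max"], 0); expect_lte(f["t_dqdt_max"], 1)
})

test_that("flow-derived features are invariant to a constant flow offset", {
  syn <- synthetic_telemetry(hr = 78, duration = 30, suction = TRUE)
  q <- syn$telemetry$flow_est_lpm
  w <- syn$telemetry$speed_rpm
  b <- detect_beats(q)
  f1 <- extract_features(b[3, ], q, w)
  f2 <- extract_features(b[3, ], q + 2.5, w)
  expect_equal(f1[c("dqdt_min", "t_dqdt_max")],
               f2[c("dqdt_min", "t_dqdt_max")])
})

test_that("short beats are rejected by feature extraction", {
  expect_error(extract_features(list(start = 1L, end = 4L,
                                     diastole_start = 1L),
                                rnorm(10), rnorm(10)), "4 samples")
})

test_that("classifier equals its 8-cell truth-table oracle", {
  thr <- tree_thresholds(-0.7, -60, 0.85)
  eps <- 1e-6
  sides <- expand.grid(f1 = c(-0.7 - eps, -0.7 + eps),
                       f2 = c(-60 - eps, -60 + eps),
                       f3 = c(0.85 - eps, 0.85 + eps))
  for (i in seq_len(nrow(sides))) {
    f <- data.frame(dqdt_min = sides$f1[i], d_omega_min = sides$f2[i],
                    t_dqdt_max = sides$f3[i])
    got <- classify_beats(f, thr)
    want <- sides$f1[i] >= -0.7 || sides$f2[i] >= -60 ||
      sides$f3[i] >= 0.85
    expect_equal(got$label == "suction", want)
    # branch order: first split that fires
    want_branch <- if (sides$f1[i] >= -0.7) 1L
    else if (sides$f2[i] >= -60) 2L
    else if (sides$f3[i] >= 0.85) 3L else 0L
    expect_equal(got$branch, want_branch)
  }
  # equality classifies as suction at every split
  expect_equal(classify_beats(
    data.frame(dqdt_min = -0.7, d_omega_min = -100, t_dqdt_max = 0.1),
    thr)$branch, 1L)
})

test_that("classifier matches brute-force evaluation on random features", {
  thr <- tree_thresholds(-0.7, -60, 0.85)
  set.seed(7)
  f <- data.frame(dqdt_min = runif(1000, -3, 1),
                  d_omega_min = runif(1000, -200, 10),
                  t_dqdt_max = runif(1000))
  got <- classify_beats(f, thr)
  brute <- f$dqdt_min >= -0.7 | f$d_omega_min >= -60 | f$t_dqdt_max >= 0.85
  expect_identical(got$label == "suction", brute)
  expect_error(classify_beats(
    data.frame(dqdt_min = NaN, d_omega_min = 0, t_dqdt_max = 0.5), thr),
    "non-finite")
})

test_that("threshold calibration separates separable classes perfectly", {
  set.seed(11)
  n <- 60
  pos <- data.frame(dqdt_min = rnorm(n, -0.4, 0.05),
                    d_omega_min = rnorm(n, -30, 5),
                    t_dqdt_max = runif(n, 0.9, 1))
  neg <- data.frame(dqdt_min = rnorm(n, -1.5, 0.2),
                    d_omega_min = rnorm(n, -110, 15),
                    t_dqdt_max = runif(n, 0.4, 0.7))
  f <- rbind(pos, neg)
  lab <- rep(c(TRUE, FALSE), each = n)
  thr <- calibrate_thresholds(f, lab)
  expect_equal(attr(thr, "sensitivity"), 1)
  expect_equal(attr(thr, "specificity"), 1)
  cls <- classify_beats(f, thr)
  expect_identical(cls$label == "suction", lab)
  expect_error(calibrate_thresholds(pos, rep(TRUE, n)), "20 beats")
})

test_that("calibration is stable under bootstrap resampling", {
  set.seed(23)
  n <- 150
  f <- rbind(data.frame(dqdt_min = rnorm(n, -0.4, 0.08),
                        d_omega_min = rnorm(n, -30, 8),
                        t_dqdt_max = pmin(runif(n, 0.85, 1.05), 1)),
             data.frame(dqdt_min = rnorm(n, -1.5, 0.2),
                        d_omega_min = rnorm(n, -110, 15),
                        t_dqdt_max = runif(n, 0.3, 0.75)))
  lab <- rep(c(TRUE, FALSE), each = n)
  thr0 <- calibrate_thresholds(f, lab)
  for (i in 1:5) {
    idx <- sample(nrow(f), replace = TRUE)
    if (sum(lab[idx]) < 20 || sum(!lab[idx]) < 20) next
    thr <- calibrate_thresholds(f[idx, ], lab[idx])
    expect_lt(abs(thr$thr_dqdt_min - thr0$thr_dqdt_min) /
                abs(thr0$thr_dqdt_min), 0.2)
    expect_lt(abs(thr$thr_d_omega_min - thr0$thr_d_omega_min) /
                abs(thr0$thr_d_omega_min), 0.2)
  }
})

test_that("telemetry CSV writes and reads the documented schema", {
  syn <- synthetic_telemetry(duration = 10)
  path <- file.path(tempdir(), "telemetry.csv")
  write_telemetry(syn$telemetry, path)
  back <- read_telemetry(path)
  expect_equal(back, syn$telemetry, tolerance = 1e-12)
  run <- cached_steady("DCM")
  write_telemetry(run$record, path)
  back <- read_telemetry(path)
  expect_equal(back$flow_est_lpm, run$record$pump$q_est, tolerance = 1e-12)
  bad <- syn$telemetry[, -2]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_telemetry(path), "speed_rpm")
})
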