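test_that("confusion statistics use the standard definitions", {
  # the published counts: 316/351 suction, 39/40 non-suction detected
  pred <- c(rep(TRUE, 316), rep(FALSE, 35), rep(FALSE, 39), rep(TRUE, 1))
  truth <- c(rep(TRUE, 351), rep(FALSE, 40))
  cf <- confusion_stats(pred, truth)
  expect_equal(cf$tp, 316); expect_equal(cf$fn, 35)
  expect_equal(cf$tn, 39); expect_equal(cf$fp, 1)
  expect_equal(cf$sensitivity, 316 / 351)
  expect_equal(round(cf$sensitivity, 3), 0.900)
  expect_equal(cf$specificity, 0.975)

  perfect <- confusion_stats(truth, truth)
  expect_equal(perfect$sensitivity, 1); expect_equal(perfect$specificity, 1)
  all_pos <- confusion_stats(rep(TRUE, length(truth)), truth)
  expect_equal(all_pos$sensitivity, 1); expect_equal(all_pos$specificity, 0)
  expect_error(confusion_stats(c(TRUE, FALSE), c(TRUE, TRUE)),
               "specificity")
  expect_error(confusion_stats(c(TRUE, FALSE), c(FALSE, FALSE)),
               "sensitivity")
})

test_that("confusion statistics match brute-force counting on random labels", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    truth <- runif(n) < 0.6
    if (!any(truth) || all(truth)) next
    pred <- runif(n) < 0.5
    cf <- confusion_stats(pred, truth)
    expect_equal(cf$tp, sum(pred & truth))
    expect_equal(cf$fp, sum(pred & !truth))
    expect_equal(cf$sensitivity, sum(pred & truth) / sum(truth))
    expect_equal(cf$specificity, sum(!pred & !truth) / sum(!truth))
  }
})

test_that("boxplot statistics use inclusive-method quartiles", {
  s <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(s, list(median = 3, q1 = 2, q3 = 4, min = 1, max = 5))
  s <- boxplot_stats(rep(7, 10))
  expect_true(all(unlist(s) == 7))
  # permutation invariance
  set.seed(3)
  x <- rnorm(31)
  expect_equal(boxplot_stats(x), boxplot_stats(sample(x)))
  expect_error(boxplot_stats(numeric(0)), "empty")
  expect_error(boxplot_stats(1:3), "4 values")
})

test_that("distribution comparison gates on Shapiro-Wilk normality", {
  set.seed(5)
  a <- rnorm(200); b <- rnorm(200, 0.1)
  res <- compare_distributions(a, b)
  expect_equal(res$test, "t")
  # grossly shifted samples are detected regardless of path
  res <- compare_distributions(rnorm(100), rnorm(100, 5))
  expect_lt(res$p, 0.001)
  # skewed samples go to Mann-Whitney
  res <- compare_distributions(rexp(100), rexp(100))
  expect_equal(res$test, "mann_whitney")
  # identical (non-normal) samples: U = n^2 / 2, p ~ 1
  set.seed(8)
  x <- rexp(20)
  res <- suppressWarnings(compare_distributions(x, x))
  expect_equal(res$test, "mann_whitney")
  expect_equal(unname(res$statistic), 20^2 / 2)
  expect_gt(res$p, 0.95)
  # zero-variance sample falls back to Mann-Whitney with a warning
  expect_warning(res <- compare_distributions(rep(1, 10), rnorm(10)),
                 "Mann-Whitney")
  expect_equal(res$test, "mann_whitney")
  expect_error(compare_distributions(1:2, 1:10), "3 values")
})

test_that("report assembles confusion, boxplot and comparison blocks", {
  rep_all <- cached_report()
  r <- rep_all$report
  expect_s3_class(r, "validation_report")
  expect_equal(r$counts$suction + r$counts$non_suction, r$counts$total)
  expect_true(r$sensitivity >= 0 && r$sensitivity <= 1)
  expect_true(r$specificity >= 0 && r$specificity <= 1)
  with(r$confusion, {
    expect_equal(tp + fn, r$counts$suction)
    expect_equal(tn + fp, r$counts$non_suction)
  })
  for (f in c("dqdt_min", "d_omega_min", "t_dqdt_max")) {
    bs <- r$features[[f]]$suction
    expect_true(bs$q1 <= bs$median && bs$median <= bs$q3)
    expect_false(is.null(r$features[[f]]$comparison$p))
  }
  # JSON round trip
  path <- file.path(tempdir(), "report.json")
  write_report(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sensitivity, r$sensitivity)
  expect_equal(back$confusion$tp, r$confusion$tp)
  expect_equal(back$features$dqdt_min$suction$median,
               r$features$dqdt_min$suction$median)
})

test_that("report handles an all-negative ground truth gracefully", {
  ds <- cached_protocol()
  keep <- which(!ds$beats$suction)
  sub <- list(beats = ds$beats[keep, ], segments = ds$segments[keep])
  class(sub) <- "beat_dataset"
  r <- generate_report(sub, tree_thresholds())
  expect_true(is.na(r$sensitivity))
  expect_true(r$specificity >= 0 && r$specificity <= 1)
})
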