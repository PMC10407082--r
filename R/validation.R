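#' Confusion statistics against ground truth
#'
#' Suction is the positive class: sensitivity = TP/(TP+FN) on
#' ground-truth suction beats, specificity = TN/(TN+FP) on ground-truth
#' non-suction beats (the standard definitions).
#'
#' @param predicted logical (or `"suction"`/`"non_suction"`) predicted
#'   labels.
#' @param truth logical ground-truth labels, `TRUE` = suction.
#' @return list with `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_stats <- function(predicted, truth) {
  if (is.character(predicted)) predicted <- predicted == "suction"
  if (is.factor(predicted)) predicted <- as.character(predicted) == "suction"
  stopifnot(length(predicted) == length(truth))
  if (!any(truth))
    stop("undefined metric: sensitivity (no ground-truth suction beats)",
         call. = FALSE)
  if (all(truth))
    stop("undefined metric: specificity (no ground-truth non-suction ",
         "beats)", call. = FALSE)
  tp <- sum(predicted & truth); fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth); fp <- sum(predicted & !truth)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Five-number boxplot statistics
#'
#' Median, quartiles by linear interpolation (the inclusive method,
#' `quantile(type = 7)`), and exact minimum/maximum.
#'
#' @param values numeric vector, `n >= 4`.
#' @return named list `median, q1, q3, min, max`.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  if (length(values) < 4)
    stop("need at least 4 values (got ", length(values), ")",
         call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3],
       min = min(values), max = max(values))
}

#' Compare two samples: Shapiro-Wilk gate, then t-test or Mann-Whitney
#'
#' Both samples are first checked for normality with a Shapiro-Wilk
#' test; if both pass at `alpha`, a two-tailed Welch t-test is used,
#' otherwise a Mann-Whitney U (Wilcoxon rank-sum) test. Zero-variance
#' samples (Shapiro-Wilk undefined) fall back to Mann-Whitney with a
#' warning.
#'
#' @param sample_a,sample_b numeric samples, `n >= 3` each.
#' @param alpha normality significance level.
#' @return list with `test` (`"t"` or `"mann_whitney"`), `statistic`,
#'   `p`, and the two Shapiro-Wilk p-values (`NA` when undefined).
#' @export
compare_distributions <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop("need at least 3 values per sample", call. = FALSE)
  sw <- function(x) {
    if (length(unique(x)) == 1 || length(x) > 5000) return(NA_real_)
    shapiro.test(x)$p.value
  }
  pa <- sw(sample_a); pb <- sw(sample_b)
  if (is.na(pa) || is.na(pb))
    warning("Shapiro-Wilk undefined for a sample; using Mann-Whitney")
  normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  if (normal) {
    ht <- t.test(sample_a, sample_b)
    list(test = "t", statistic = unname(ht$statistic), p = ht$p.value,
         shapiro_a = pa, shapiro_b = pb)
  } else {
    ht <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = FALSE))
    list(test = "mann_whitney", statistic = unname(ht$statistic),
         p = ht$p.value, shapiro_a = pa, shapiro_b = pb)
  }
}

#' Validation report for a labeled beat dataset
#'
#' Runs the quantitative validation over a [full_protocol()] dataset:
#' extracts the three suction features from every beat, classifies each
#' beat with the decision tree, computes the confusion statistics
#' against the simulator ground truth, the branch-1 fraction (share of
#' ground-truth suction beats detected at the first, flow-slope split),
#' per-feature per-class boxplot summaries, Shapiro-Wilk normality
#' p-values and suction vs non-suction distribution comparisons.
#'
#' @param dataset a `beat_dataset` from [full_protocol()].
#' @param thresholds a [tree_thresholds()].
#' @param path optional path; when given the report is also written as
#'   JSON.
#' @return object of class `validation_report`.
#' @export
generate_report <- function(dataset, thresholds = tree_thresholds(),
                            path = NULL) {
  feats <- dataset_features(dataset)
  cls <- classify_beats(feats, thresholds)
  truth <- dataset$beats$suction
  report <- list(counts = list(
    total = nrow(feats),
    suction = sum(truth), non_suction = sum(!truth)))
  if (any(truth) && !all(truth)) {
    cf <- confusion_stats(cls$label, truth)
    report$confusion <- cf[c("tp", "fn", "tn", "fp")]
    report$sensitivity <- cf$sensitivity
    report$specificity <- cf$specificity
  } else {
    report$confusion <- NULL
    report$sensitivity <- NA
    report$specificity <- if (!any(truth))
      mean(cls$label[!truth] == "non_suction") else NA
  }
  report$branch1_fraction <- if (any(truth))
    sum(cls$branch == 1 & truth) / sum(truth) else NA
  fs <- list()
  for (f in c("dqdt_min", "d_omega_min", "t_dqdt_max")) {
    fs[[f]] <- list()
    for (cl in c("suction", "non_suction")) {
      v <- feats[[f]][if (cl == "suction") truth else !truth]
      fs[[f]][[cl]] <- if (length(v) >= 4) boxplot_stats(v) else NULL
      fs[[f]][[paste0("shapiro_p_", cl)]] <-
        if (length(v) >= 3 && length(unique(v)) > 1)
          shapiro.test(v)$p.value else NA
    }
    fs[[f]]$comparison <- if (sum(truth) >= 3 && sum(!truth) >= 3)
      compare_distributions(feats[[f]][truth], feats[[f]][!truth]) else NULL
  }
  report$features <- fs
  report$thresholds <- unclass(thresholds)[c("thr_dqdt_min",
                                             "thr_d_omega_min",
                                             "thr_t_dqdt_max")]
  out <- structure(report, class = "validation_report")
  if (!is.null(path)) write_report(out, path)
  out
}

#' Feature table of a beat dataset
#'
#' Applies [extract_features()] to every beat segment of a
#' [full_protocol()] dataset.
#'
#' @param dataset a `beat_dataset`.
#' @return data.frame with the three feature columns, one row per beat.
#' @export
dataset_features <- function(dataset) {
  out <- lapply(dataset$segments, function(seg) {
    n <- nrow(seg)
    extract_features(list(start = 1L, end = n + 1L, diastole_start = 1L),
                     seg$q_est, seg$omega_rpm)
  })
  as.data.frame(do.call(rbind, out))
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$counts$total, "beats (",
      x$counts$suction, "suction /", x$counts$non_suction,
      "non-suction )\n")
  if (!is.null(x$confusion))
    cat(sprintf("  sensitivity %.1f%% | specificity %.1f%% | branch-1 %.1f%%\n",
                100 * x$sensitivity, 100 * x$specificity,
                100 * x$branch1_fraction))
  for (f in names(x$features)) {
    s <- x$features[[f]]$suction; ns <- x$features[[f]]$non_suction
    if (!is.null(s) && !is.null(ns))
      cat(sprintf("  %-12s median suction %8.3f | non-suction %8.3f\n",
                  f, s$median, ns$median))
  }
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
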