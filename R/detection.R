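#' Segment cardiac cycles from 50-Hz estimated pump flow
#'
#' Beat onsets are placed at the beginning of diastole: the flow minimum
#' that follows the systolic decay, advanced past any rapid recovery
#' transient (the re-opening upstroke after a suction spike) so that the
#' onset sits at the start of the diastolic plateau. Detected minima are
#' separated by a refractory period; beats are contiguous, half-open
#' `[start, end)` index windows.
#'
#' @param q_est estimated pump flow, L/min, sampled at `fs`.
#' @param fs sample rate, Hz (50 for pump telemetry).
#' @param refractory minimum spacing between beat onsets, s.
#' @param min_duration,max_duration admissible beat durations, s.
#' @param rec_frac fraction of the steepest positive slope between two
#'   systolic peaks above which samples after a minimum are treated as
#'   a recovery transient and skipped (a suction spike recovers much
#'   faster than diastolic refill, so the onset is placed after it).
#' @param min_amplitude flow range (L/min) below which the signal is
#'   declared flat: zero beats are returned with a warning.
#' @return data.frame with columns `start`, `end` (1-based half-open),
#'   `diastole_start`, `duration` (s).
#' @export
detect_beats <- function(q_est, fs = 50, refractory = 0.3,
                         min_duration = 0.3, max_duration = 2.0,
                         rec_frac = 0.5, min_amplitude = 0.02) {
  n <- length(q_est)
  if (n < 5 * fs)
    stop("need at least 5 s of signal (got ", round(n / fs, 2), " s)",
         call. = FALSE)
  empty <- data.frame(start = integer(0), end = integer(0),
                      diastole_start = integer(0), duration = numeric(0))
  # light smoothing, then removal of slow baseline drift (running
  # median over ~2.5 s) so beats remain detectable while the mean flow
  # settles after a condition change
  qs <- stats::filter(q_est, rep(1 / 3, 3), sides = 2)
  qs[is.na(qs)] <- q_est[is.na(qs)]
  qs <- as.numeric(qs)
  k <- 2 * round(1.25 * fs) + 1
  if (n > k) qs <- qs - stats::runmed(qs, k, endrule = "median")
  lo <- quantile(qs, 0.05, names = FALSE)
  hi <- quantile(qs, 0.95, names = FALSE)
  rng <- hi - lo
  if (rng < min_amplitude) {
    warning("flat signal: no beats detected")
    return(empty)
  }
  # one systolic peak per cycle: greedy maxima with refractory spacing,
  # merging peak pairs not separated by a sufficiently deep dip
  # (suppresses low-amplitude diastolic ripple)
  is_max <- c(FALSE, diff(qs) >= 0) & c(qs[-n] >= qs[-1], FALSE)
  cand <- which(is_max)
  if (length(cand) < 2) {
    warning("no repeating flow peaks found: no beats detected")
    return(empty)
  }
  cand <- cand[order(qs[cand], decreasing = TRUE)]
  spacing <- round(refractory * fs)
  peaks <- integer(0)
  for (i in cand)
    if (!length(peaks) || all(abs(peaks - i) >= spacing))
      peaks <- c(peaks, i)
  peaks <- sort(peaks)
  repeat {
    if (length(peaks) < 2) break
    dip <- vapply(seq_len(length(peaks) - 1), function(j) {
      seg <- qs[peaks[j]:peaks[j + 1]]
      min(qs[peaks[j]], qs[peaks[j + 1]]) - min(seg)
    }, numeric(1))
    weak <- which(dip < 0.25 * rng)
    if (!length(weak)) break
    j <- weak[1]  # merge the shallower neighbour of the weakest dip
    drop <- if (qs[peaks[j]] < qs[peaks[j + 1]]) j else j + 1
    peaks <- peaks[-drop]
  }
  if (length(peaks) < 2) {
    warning("fewer than two flow peaks: no beats detected")
    return(empty)
  }
  # beat onset: the first local flow minimum after the systolic decay
  # (not the global minimum, which slow estimator drift can push into
  # late diastole), advanced past any rapid recovery transient to the
  # start of the diastolic plateau
  dq <- c(diff(qs), 0) * fs
  max_adv <- round(0.15 * fs)
  onsets <- vapply(seq_len(length(peaks) - 1), function(j) {
    seg <- peaks[j]:peaks[j + 1]
    depth <- qs[peaks[j]] - min(qs[seg])
    gate <- qs[peaks[j]] - 0.6 * depth
    i <- peaks[j]
    while (i < peaks[j + 1] &&
           !(qs[i] <= qs[i + 1] && qs[i] < gate)) i <- i + 1L
    i0 <- i
    # skip a rapid recovery transient: jump past the last steep
    # positive slope within the advance window (the reopening after a
    # suction spike); slow diastolic refill never reaches the gate
    rec_thresh <- max(rec_frac * max(dq[seg[-length(seg)]]), 0.05)
    win <- i0:min(i0 + max_adv, n - 1L, peaks[j + 1] - 1L)
    steep <- win[dq[win] >= rec_thresh]
    if (length(steep)) i <- win[which.max(dq[win])] + 1L
    i
  }, integer(1))
  onsets <- unique(onsets)
  if (length(onsets) < 2) {
    warning("fewer than two beat onsets: no beats detected")
    return(empty)
  }
  out <- data.frame(start = onsets[-length(onsets)], end = onsets[-1])
  out$diastole_start <- out$start
  out$duration <- (out$end - out$start) / fs
  out <- out[out$duration >= min_duration & out$duration <= max_duration, ]
  rownames(out) <- NULL
  out
}

#' Extract the three suction features of one beat
#'
#' From the 50-Hz pump channels of a segmented beat:
#' \describe{
#'   \item{`dqdt_min`}{minimum of the two-point finite-difference
#'     derivative of estimated flow, L/min/s (the minimum negative
#'     flow slope);}
#'   \item{`t_dqdt_max`}{timing of the maximum positive flow slope,
#'     normalized to the beat duration from the beginning of diastole
#'     and wrapped into `[0, 1)`;}
#'   \item{`d_omega_min`}{minimum impeller speed pulsatility: minimum
#'     over the beat of speed minus the beat-median speed, rpm
#'     (non-positive).}
#' }
#'
#' @param beat one row of [detect_beats()] output (or a list with
#'   `start`, `end`, `diastole_start`).
#' @param q_est estimated flow series, L/min.
#' @param omega impeller speed series, rpm, aligned with `q_est`.
#' @param fs sample rate, Hz.
#' @return named numeric vector with the three features.
#' @export
extract_features <- function(beat, q_est, omega, fs = 50) {
  i0 <- beat$start; i1 <- beat$end
  if (is.null(i0) || is.null(i1) || i1 - i0 < 4)
    stop("beat shorter than 4 samples", call. = FALSE)
  if (i0 < 1 || i1 - 1 > length(q_est))
    stop("beat indices out of range", call. = FALSE)
  qw <- q_est[i0:(i1 - 1)]
  ow <- omega[i0:(i1 - 1)]
  dq <- diff(qw) * fs
  dqdt_min <- min(dq)
  imax <- which.max(dq)
  dur <- (i1 - i0) / fs
  t_rel <- ((i0 + imax - 1) - beat$diastole_start) / fs / dur
  t_rel <- t_rel %% 1
  if (t_rel == 0) t_rel <- 1  # boundary-coincident: wrap into (0, 1]
  c(dqdt_min = dqdt_min,
    d_omega_min = min(ow - median(ow)),
    t_dqdt_max = t_rel)
}

#' Decision-tree thresholds
#'
#' The 3-split binary tree compares the suction features to fixed
#' thresholds in the order minimum flow slope, speed pulsatility,
#' timing; a beat exceeding any threshold is classified as suction. The
#' shipped defaults are calibration constants obtained by maximizing
#' balanced accuracy on the full-protocol dataset (the clinically used
#' thresholds are device-specific and not public); override them per
#' device or dataset with [calibrate_thresholds()].
#'
#' @param thr_dqdt_min threshold on `dqdt_min`, L/min/s.
#' @param thr_d_omega_min threshold on `d_omega_min`, rpm.
#' @param thr_t_dqdt_max threshold on `t_dqdt_max`, normalized.
#' @return object of class `tree_thresholds`.
#' @export
tree_thresholds <- function(thr_dqdt_min = -0.54,
                            thr_d_omega_min = -25,
                            thr_t_dqdt_max = 0.80) {
  v <- c(thr_dqdt_min = thr_dqdt_min, thr_d_omega_min = thr_d_omega_min,
         thr_t_dqdt_max = thr_t_dqdt_max)
  if (any(!is.finite(v))) stop("thresholds must be finite", call. = FALSE)
  structure(as.list(v), class = "tree_thresholds",
            split_order = c("dqdt_min", "d_omega_min", "t_dqdt_max"))
}

#' @export
print.tree_thresholds <- function(x, ...) {
  cat(sprintf(
    paste0("<tree_thresholds> suction if dqdt_min >= %g L/min/s, else if\n",
           "  d_omega_min >= %g rpm, else if t_dqdt_max >= %g\n"),
    x$thr_dqdt_min, x$thr_d_omega_min, x$thr_t_dqdt_max))
  invisible(x)
}

#' Classify beats with the 3-split decision tree
#'
#' Split 1: `dqdt_min >= thr` is suction (branch 1); otherwise split 2:
#' `d_omega_min >= thr` is suction (branch 2); otherwise split 3:
#' `t_dqdt_max >= thr` is suction (branch 3); otherwise non-suction
#' (branch 0). Equality classifies as suction (conservative for a
#' safety-relevant detector). Deterministic and vectorized.
#'
#' @param features data.frame (or named vector for one beat) with
#'   columns `dqdt_min`, `d_omega_min`, `t_dqdt_max`.
#' @param thresholds a [tree_thresholds()].
#' @return data.frame with `label` (`"suction"`/`"non_suction"`) and
#'   `branch` (0-3).
#' @export
classify_beats <- function(features, thresholds = tree_thresholds()) {
  if (!is.data.frame(features))
    features <- as.data.frame(as.list(features))
  f1 <- features$dqdt_min; f2 <- features$d_omega_min
  f3 <- features$t_dqdt_max
  if (any(!is.finite(c(f1, f2, f3))))
    stop("classification error: non-finite feature value", call. = FALSE)
  branch <- ifelse(f1 >= thresholds$thr_dqdt_min, 1L,
                   ifelse(f2 >= thresholds$thr_d_omega_min, 2L,
                          ifelse(f3 >= thresholds$thr_t_dqdt_max, 3L, 0L)))
  data.frame(label = ifelse(branch > 0L, "suction", "non_suction"),
             branch = branch)
}

#' Calibrate the decision-tree thresholds on labeled beats
#'
#' Calibration respecting the fixed split order and orientation (the
#' suction side is high for all three features):
#' a full grid search over the three thresholds maximizing the balanced
#' accuracy (mean of sensitivity and specificity) of the tree on the
#' labeled beats. Each split may also choose to pass every beat on
#' (exclude-all candidate). The search is deterministic: ties break
#' toward the first candidate triple in grid order, with flow-slope
#' candidates scanned from the most negative up, so the bulk of the
#' detections stays on the first split whenever accuracy permits. Candidate thresholds per feature are
#' midpoints of the sorted observed values, thinned to at most
#' `grid_n`.
#'
#' @param features data.frame of features (see [classify_beats()]).
#' @param labels logical vector, `TRUE` = suction ground truth.
#' @param grid_n maximum grid size per feature.
#' @return a [tree_thresholds()] with attributes `balanced_accuracy`,
#'   `sensitivity`, `specificity` (of the full tree on the training
#'   beats).
#' @export
calibrate_thresholds <- function(features, labels, grid_n = 40) {
  stopifnot(nrow(features) == length(labels))
  if (sum(labels) < 20 || sum(!labels) < 20)
    stop("calibration error: need at least 20 beats per class (got ",
         sum(labels), " suction, ", sum(!labels), " non-suction)",
         call. = FALSE)
  grid1 <- c(.threshold_grid(features$dqdt_min, grid_n),
             max(features$dqdt_min) + 1e-6)
  grid2 <- c(.threshold_grid(features$d_omega_min, grid_n),
             max(features$d_omega_min) + 1e-6)
  grid3 <- c(.threshold_grid(features$t_dqdt_max, grid_n),
             max(features$t_dqdt_max) + 1e-6)
  # with the fixed orientation the tree is the OR of the three
  # comparisons; the appended exclude-all candidate lets a split pass
  # everything on
  B1 <- outer(features$dqdt_min, grid1, `>=`)
  B2 <- outer(features$d_omega_min, grid2, `>=`)
  B3 <- outer(features$t_dqdt_max, grid3, `>=`)
  pos <- labels; neg <- !labels
  best <- list(ba = -Inf)
  for (j in seq_along(grid1)) {
    for (k in seq_along(grid2)) {
      or12 <- B1[, j] | B2[, k]
      pred <- or12 | B3  # vectorized over the third grid
      sens <- colSums(pred & pos) / sum(pos)
      spec <- colSums(!pred & neg) / sum(neg)
      ba <- (sens + spec) / 2
      l <- which.max(ba)
      if (ba[l] > best$ba + 1e-12)
        best <- list(ba = ba[l], j = j, k = k, l = l)
    }
  }
  thr <- tree_thresholds(grid1[best$j], grid2[best$k], grid3[best$l])
  cls <- classify_beats(features, thr)
  cf <- confusion_stats(cls$label, labels)
  attr(thr, "balanced_accuracy") <- (cf$sensitivity + cf$specificity) / 2
  attr(thr, "sensitivity") <- cf$sensitivity
  attr(thr, "specificity") <- cf$specificity
  thr
}

.threshold_grid <- function(x, grid_n) {
  u <- sort(unique(x))
  mids <- (u[-1] + u[-length(u)]) / 2
  cand <- c(u[1] - 1e-6, mids, u[length(u)] + 1e-6)
  if (length(cand) > grid_n)
    cand <- cand[unique(round(seq(1, length(cand), length.out = grid_n)))]
  cand
}

#' Read / write 50-Hz pump telemetry as delimited text
#'
#' Column schema: `time_s, speed_rpm, current_A, power_W, flow_est_lpm`.
#'
#' @param path CSV path.
#' @return `read_telemetry`: data.frame with the schema columns.
#' @export
read_telemetry <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "speed_rpm", "current_A", "power_W", "flow_est_lpm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("telemetry file misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_telemetry
#' @param record a `signal_record` (its 50-Hz pump channels are written)
#'   or a data.frame already in the schema.
#' @export
write_telemetry <- function(record, path) {
  df <- if (inherits(record, "signal_record"))
    data.frame(time_s = record$pump$t, speed_rpm = record$pump$omega_rpm,
               current_A = record$pump$current, power_W = record$pump$power,
               flow_est_lpm = record$pump$q_est)
  else record
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
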