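#' Match detected crackle onsets against ground truth
#'
#' A detection is correct if it lies within `tolerance` samples of an
#' inserted crackle's onset. Matching is one-to-one and maximum-cardinality:
#' ground-truth onsets are scanned in increasing order and each is paired
#' with the earliest unused detection inside its tolerance window — the
#' optimal rule for interval matching on a line, and identical to
#' nearest-first pairing whenever events are farther apart than one
#' tolerance (always the case for the crackle scenarios, whose insertions
#' are separated by at least one crackle duration). Unmatched ground truths
#' are false negatives, unmatched detections false positives.
#'
#' True negatives need a decision unit: they are counted over the detector's
#' 4 ms analysis windows, a window being a true negative when it contains
#' neither a ground-truth onset nor a detection.
#'
#' @param truth Ground truth: a `crackle_scenario`, its `truth` data frame,
#'   or a numeric vector of onset samples.
#' @param detections A [detect_crackles()] result or numeric vector of
#'   detected onset samples.
#' @param tolerance Matching tolerance in samples (default 3).
#' @param n_windows Number of analysis windows (taken from `detections` when
#'   it is a `crackle_detection`).
#' @param window Window length in samples used to bin onsets for the
#'   true-negative count (default 40 = 4 ms at 10 kHz).
#' @return An object of class `confusion_counts`: list with `tp`, `fn`,
#'   `fp`, `tn`, and `delta_t` (signed detection minus truth, in samples,
#'   one entry per matched pair).
#' @examples
#' cc <- match_events(c(100, 500), c(102, 700), tolerance = 3,
#'                    n_windows = 100)
#' c(cc$tp, cc$fn, cc$fp)  # 1 1 1
#' @export
match_events <- function(truth, detections, tolerance = 3L,
                         n_windows = NULL, window = 40L) {
  if (tolerance < 0) stop("'tolerance' must be non-negative")
  t_on <- .onset_vector(truth)
  if (inherits(detections, "crackle_detection")) {
    if (is.null(n_windows)) n_windows <- detections$n_windows
    window <- as.integer(round(detections$config$window_ms *
                                 detections$fs / 1000))
    d_on <- detections$events$onset_sample
  } else {
    d_on <- as.numeric(detections)
  }
  if (is.null(n_windows)) stop("'n_windows' must be supplied")

  t_on <- sort(t_on)
  d_sorted <- sort(d_on)
  used <- logical(length(d_sorted))
  delta <- numeric(0)
  for (t in t_on) {
    ok <- which(!used & d_sorted >= t - tolerance & d_sorted <= t + tolerance)
    if (length(ok) > 0) {
      pick <- ok[1L]  # earliest unused detection in the window
      used[pick] <- TRUE
      delta <- c(delta, d_sorted[pick] - t)
    }
  }
  tp <- length(delta)
  fn <- length(t_on) - tp
  fp <- length(d_sorted) - tp

  win_of <- function(s) pmin(pmax(ceiling((s - 1) / window), 1L), n_windows)
  occupied <- unique(c(win_of(t_on), win_of(d_sorted)))
  tn <- n_windows - length(occupied)

  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, delta_t = delta,
                 tolerance = tolerance, n_windows = n_windows),
            class = "confusion_counts")
}

.onset_vector <- function(truth) {
  if (inherits(truth, "crackle_scenario")) truth$truth$onset_sample
  else if (is.data.frame(truth)) truth$onset_sample
  else as.numeric(truth)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d (tolerance %d samples, %d windows)\n",
              x$tp, x$fn, x$fp, x$tn, x$tolerance, x$n_windows))
  invisible(x)
}

#' Sum confusion counts over recordings
#' @param ... `confusion_counts` objects (or a single list of them).
#' @return A pooled `confusion_counts`.
#' @export
pool_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "confusion_counts")) xs <- xs[[1]]
  structure(list(
    tp = sum(vapply(xs, `[[`, 0, "tp")),
    fn = sum(vapply(xs, `[[`, 0, "fn")),
    fp = sum(vapply(xs, `[[`, 0, "fp")),
    tn = sum(vapply(xs, `[[`, 0, "tn")),
    delta_t = unlist(lapply(xs, `[[`, "delta_t")),
    tolerance = xs[[1]]$tolerance,
    n_windows = sum(vapply(xs, `[[`, 0, "n_windows"))
  ), class = "confusion_counts")
}

#' Detection performance indices
#'
#' Computes, as percentages,
#' \deqn{Acc = \frac{TP}{TP+FN+FP}, \quad Sen = \frac{TP}{TP+FN}, \quad
#'       Spe = \frac{TN}{TN+FP},}
#' (note accuracy deliberately excludes true negatives, which would swamp it
#' in long recordings with sparse events) plus localization-error summaries
#' over matched pairs: mean |dt| in ms and median |dt| in samples.
#'
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' as 0 or 100.
#'
#' @param counts A `confusion_counts` from [match_events()] /
#'   [pool_counts()].
#' @param fs Sampling rate in Hz used to express mean |dt| in ms.
#' @return An object of class `performance_report`: list with `acc`, `sen`,
#'   `spe` (percent), `mean_abs_dt_ms`, `median_abs_dt_samples`, `counts`.
#' @examples
#' cc <- structure(list(tp = 9, fn = 1, fp = 1, tn = 989,
#'                      delta_t = rep(2, 9)), class = "confusion_counts")
#' performance_metrics(cc)
#' @export
performance_metrics <- function(counts, fs = 10000) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  dt <- abs(counts$delta_t)
  structure(list(
    acc = pct(counts$tp, counts$tp + counts$fn + counts$fp),
    sen = pct(counts$tp, counts$tp + counts$fn),
    spe = pct(counts$tn, counts$tn + counts$fp),
    mean_abs_dt_ms = if (length(dt)) mean(dt) * 1000 / fs else NA_real_,
    median_abs_dt_samples = if (length(dt)) stats::median(dt) else NA_real_,
    counts = counts
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.2f", v)
  cat(sprintf("Acc %s%%  Sen %s%%  Spe %s%%  mean|dt| %s ms  median|dt| %s samples\n",
              fmt(x$acc), fmt(x$sen), fmt(x$spe),
              fmt(x$mean_abs_dt_ms), fmt(x$median_abs_dt_samples)))
  invisible(x)
}

#' Sweep the detection threshold over a set of simulated recordings
#'
#' Runs the detector at every threshold of `grid` on each recording,
#' pooling TP/FN/FP/TN over recordings before computing the indices. The
#' TVAR trajectory and windowed derivative statistics are computed once per
#' recording and reused across thresholds.
#'
#' @param scenarios List of `crackle_scenario` objects (or lists with
#'   `recording` and `truth`).
#' @param grid Threshold values (default `seq(0.010, 0.060, by = 0.001)`).
#' @param tolerance Matching tolerance in samples.
#' @param window_ms,order,lambda,delta Detector settings, see
#'   [detect_crackles()].
#' @return An object of class `threshold_sweep`: a data frame with one row
#'   per threshold (`threshold`, `tp`, `fn`, `fp`, `tn`, `acc`, `sen`,
#'   `spe`).
#' @export
threshold_sweep <- function(scenarios, grid = seq(0.010, 0.060, by = 0.001),
                            tolerance = 3L, window_ms = 4, order = 4L,
                            lambda = 0.97, delta = 0.01) {
  stopifnot(length(grid) > 0, length(scenarios) > 0)
  per_rec <- lapply(scenarios, function(sc) {
    rec <- sc$recording
    fit <- tvar_rls(rec$samples, order = order, lambda = lambda, delta = delta)
    window <- as.integer(round(window_ms * rec$fs / 1000))
    frames <- .crackle_frames(coefficient_derivatives(fit), window)
    list(frames = frames, truth = sc$truth$onset_sample, window = window)
  })
  rows <- lapply(grid, function(thr) {
    counts <- pool_counts(lapply(per_rec, function(pr) {
      onsets <- .apply_threshold(pr$frames, thr)
      match_events(pr$truth, onsets, tolerance = tolerance,
                   n_windows = pr$frames$n_windows, window = pr$window)
    }))
    pm <- performance_metrics(counts)
    data.frame(threshold = thr, tp = counts$tp, fn = counts$fn,
               fp = counts$fp, tn = counts$tn,
               acc = pm$acc, sen = pm$sen, spe = pm$spe)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' @export
plot.threshold_sweep <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::matplot(x$threshold, cbind(x$acc, x$sen, x$spe), type = "l",
                    lty = 1, col = c("black", "blue", "red"),
                    xlab = "threshold", ylab = "%", ...)
  graphics::legend("bottomright", c("Acc", "Sen", "Spe"), lty = 1,
                   col = c("black", "blue", "red"), bty = "n")
  graphics::plot(100 - x$spe, x$sen, type = "b", xlab = "100 - Spe (%)",
                 ylab = "Sen (%)", ...)
  invisible(x)
}

#' Select the operating threshold from a sweep
#'
#' Reproduces the ROC-based selection rule: the lower limit is the threshold
#' whose (Sen, Spe) point is closest (Euclidean) to the ideal (100, 100)
#' corner of the ROC; the upper limit is the threshold maximizing the
#' accuracy curve (earliest on ties); the operating threshold is their
#' midpoint. With lower limit 0.019 and upper limit 0.029 the rule yields
#' the detector's default 0.024.
#'
#' @param sweep A [threshold_sweep()] result (data frame with `threshold`,
#'   `acc`, `sen`, `spe`).
#' @return List with `thr_lower`, `thr_upper`, `thr_mid`.
#' @export
select_threshold <- function(sweep) {
  if (nrow(sweep) < 3L) stop("sweep must cover at least 3 thresholds")
  sen <- sweep$sen; spe <- sweep$spe; acc <- sweep$acc
  flat <- function(v) all(is.na(v)) || (!anyNA(v) && all(v == v[1]))
  if (flat(sen) && flat(spe) && flat(acc)) {
    warning("degenerate selection: all sweep metrics are identical; ",
            "returning the grid midpoint")
    mid <- stats::median(sweep$threshold)
    return(list(thr_lower = mid, thr_upper = mid, thr_mid = mid))
  }
  dist2 <- (100 - sen)^2 + (100 - spe)^2
  dist2[is.na(dist2)] <- Inf
  thr_lower <- sweep$threshold[which.min(dist2)]
  acc2 <- acc
  acc2[is.na(acc2)] <- -Inf
  thr_upper <- sweep$threshold[which.max(acc2)]
  list(thr_lower = thr_lower, thr_upper = thr_upper,
       thr_mid = (thr_lower + thr_upper) / 2)
}

#' Write a per-scenario performance report as CSV
#'
#' One row per (scenario, gain): Acc, Sen, Spe and mean |dt| in ms.
#'
#' @param reports Data frame or list of rows with columns `scenario`,
#'   `gain`, and a `performance_report` per row under `report`, or an
#'   already-flat data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  if (!is.data.frame(reports)) {
    reports <- do.call(rbind, lapply(reports, function(r) {
      data.frame(scenario = r$scenario, gain = r$gain, acc = r$report$acc,
                 sen = r$report$sen, spe = r$report$spe,
                 mean_abs_dt_ms = r$report$mean_abs_dt_ms)
    }))
  }
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}
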