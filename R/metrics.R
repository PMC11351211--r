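#' Match detected events to ground truth within a frame tolerance
#'
#' Optimal one-to-one assignment between the two sorted frame lists: the
#' matching maximizes the number of pairs within `tolerance` frames and,
#' among those, minimizes the total absolute error. Because both lists are
#' ordered in time an optimal matching never crosses, so the assignment is
#' computed by dynamic programming over the two streams in
#' `O(n_truth * n_detected)`. Unmatched truths are false negatives,
#' unmatched detections false positives.
#'
#' @param truth Sorted ascending numeric vector of annotated event frames.
#' @param detected Sorted ascending numeric vector of detected event frames.
#' @param tolerance Non-negative matching tolerance in frames (default 5).
#' @return An object of class `match_result`: list with `pairs` (data frame
#'   `truth`, `detected`, `error = detected - truth`), `tp`, `fp`, `fn` and
#'   `tolerance_frames`.
#' @examples
#' match_events(c(100, 160), c(102, 158, 300), tolerance = 5)
#' @export
match_events <- function(truth, detected, tolerance = 5) {
  truth <- as.numeric(truth); detected <- as.numeric(detected)
  if (is.unsorted(truth) || is.unsorted(detected)) {
    stop("'truth' and 'detected' must be sorted ascending (contract violation)")
  }
  if (tolerance < 0) stop("'tolerance' must be non-negative")
  nt <- length(truth); nd <- length(detected)
  pairs <- data.frame(truth = numeric(0), detected = numeric(0),
                      error = numeric(0))
  if (nt > 0 && nd > 0) {
    # dp over prefixes; objective lexicographic (max tp, min total |error|)
    tp <- matrix(0L, nt + 1, nd + 1)
    er <- matrix(0, nt + 1, nd + 1)
    for (i in seq_len(nt)) {
      for (j in seq_len(nd)) {
        # skip truth i or detection j
        if (tp[i, j + 1] > tp[i + 1, j] ||
            (tp[i, j + 1] == tp[i + 1, j] && er[i, j + 1] <= er[i + 1, j])) {
          best_tp <- tp[i, j + 1]; best_er <- er[i, j + 1]
        } else {
          best_tp <- tp[i + 1, j]; best_er <- er[i + 1, j]
        }
        e <- abs(truth[i] - detected[j])
        if (e <= tolerance) {
          m_tp <- tp[i, j] + 1L
          m_er <- er[i, j] + e
          if (m_tp > best_tp || (m_tp == best_tp && m_er < best_er)) {
            best_tp <- m_tp; best_er <- m_er
          }
        }
        tp[i + 1, j + 1] <- best_tp
        er[i + 1, j + 1] <- best_er
      }
    }
    # backtrack, preferring a match when it attains the optimum
    i <- nt; j <- nd
    ti <- integer(0); di <- integer(0)
    while (i > 0 && j > 0) {
      e <- abs(truth[i] - detected[j])
      if (e <= tolerance &&
          tp[i + 1, j + 1] == tp[i, j] + 1L &&
          er[i + 1, j + 1] == er[i, j] + e) {
        ti <- c(i, ti); di <- c(j, di)
        i <- i - 1; j <- j - 1
      } else if (tp[i + 1, j + 1] == tp[i, j + 1] &&
                 er[i + 1, j + 1] == er[i, j + 1]) {
        i <- i - 1
      } else {
        j <- j - 1
      }
    }
    if (length(ti)) {
      pairs <- data.frame(truth = truth[ti], detected = detected[di],
                          error = detected[di] - truth[ti])
    }
  }
  structure(
    list(pairs = pairs, tp = nrow(pairs), fp = nd - nrow(pairs),
         fn = nt - nrow(pairs), tolerance_frames = tolerance),
    class = "match_result"
  )
}

#' Sensitivity (true positive rate), in percent
#'
#' `100 * tp / (tp + fn)`. Undefined when no positives exist; following the
#' reporting convention for event-free scenarios this returns `NA` (printed
#' as not applicable) in that case.
#'
#' @param tp,fn True-positive and false-negative counts.
#' @return Percentage in `[0, 100]`, or `NA` when `tp + fn == 0`.
#' @export
sensitivity <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fn == 0) return(NA_real_)
  100 * tp / (tp + fn)
}

#' Mean absolute frame difference of matched pairs
#'
#' `(1/N) * sum(|P_actual - P_detected|)` over matched pairs; 0 for an
#' empty pair set (the convention used for event-free scenario rows).
#'
#' @param pairs A `match_result`, or a data frame with an `error` column.
#' @return Mean absolute difference in frames.
#' @export
average_difference <- function(pairs) {
  err <- if (inherits(pairs, "match_result")) pairs$pairs$error
         else pairs$error
  if (length(err) == 0) return(0)
  mean(abs(err))
}

#' Matthews correlation coefficient
#'
#' `((TP*TN) - (FP*FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' correlation of a binary confusion matrix, in `[-1, 1]`. Any zero factor
#' in the denominator yields 0 (the standard convention for degenerate
#' margins).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, tn, fn) {
  if (min(tp, fp, tn, fn) < 0) stop("counts must be non-negative")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(denom2)
}

#' Detection rate, in percent
#'
#' The fraction of annotated events that found a match within the matching
#' tolerance: `100 * matched / n_truth`. Scenarios with no annotated events
#' report 0.00% by convention (whether or not spurious detections occurred).
#'
#' @param n_matched Number of truth events with a match.
#' @param n_truth Number of truth events.
#' @return Percentage in `[0, 100]`.
#' @export
detection_rate <- function(n_matched, n_truth) {
  if (n_truth < 0 || n_matched < 0) stop("counts must be non-negative")
  if (n_truth == 0) return(0)
  100 * min(n_matched, n_truth) / n_truth
}

#' Signed frame-error histogram of matched pairs
#'
#' Tabulates the signed errors `detected - truth` of matched pairs and the
#' fraction of exact (zero-error) matches.
#'
#' @param pairs A `match_result`, or a data frame with an `error` column.
#' @return List with `histogram` (named integer vector, names are signed
#'   errors) and `zero_fraction`.
#' @export
error_histogram <- function(pairs) {
  err <- if (inherits(pairs, "match_result")) pairs$pairs$error
         else pairs$error
  if (length(err) == 0) {
    return(list(histogram = integer(0), zero_fraction = NA_real_))
  }
  tab <- table(factor(err, levels = sort(unique(err))))
  h <- as.integer(tab)
  names(h) <- names(tab)
  list(histogram = h, zero_fraction = mean(err == 0))
}

# True negatives for sparse event streams: the recording is partitioned
# into gait-cycle-sized bins (median truth inter-event interval; fallback
# `fallback_bin`), and a bin containing neither a truth nor a detection
# counts as one TN.
count_true_negatives <- function(truth, detected, n_frames,
                                 fallback_bin = 60) {
  bin <- if (length(truth) >= 2) stats::median(diff(sort(truth)))
         else fallback_bin
  bin <- max(1, round(bin))
  edges <- seq(0, n_frames, by = bin)
  if (edges[length(edges)] < n_frames) edges <- c(edges, n_frames)
  occupied_t <- unique(pmin(findInterval(truth, edges,
                                         rightmost.closed = TRUE),
                            length(edges) - 1))
  occupied_d <- unique(pmin(findInterval(detected, edges,
                                         rightmost.closed = TRUE),
                            length(edges) - 1))
  nbins <- length(edges) - 1
  sum(!(seq_len(nbins) %in% c(occupied_t, occupied_d)))
}

#' Evaluate detected events against annotations
#'
#' Per event type (HS and TO), matches detections to truth and derives the
#' standard report: detection rate (matched fraction at `tolerance`,
#' default +-5 frames), sensitivity (at the stricter `sens_tolerance`,
#' default +-3 frames), mean absolute difference of the matched pairs,
#' Matthews correlation coefficient, and the signed error histogram. True
#' negatives for the MCC come from gait-cycle-sized bins containing neither
#' a truth nor a detection (see Details).
#'
#' @details The negative class is ill-defined for sparse point events; this
#' implementation partitions the recording into bins of the median truth
#' inter-event interval and counts empty bins as true negatives. Supply
#' `tn` to override with your own count.
#'
#' @param detected A `gait_events` data frame (or any data frame with
#'   `frame` and `type`).
#' @param truth Same layout, the annotations.
#' @param n_frames Length of the recording in frames (bounds the TN bins).
#' @param tolerance Matching tolerance in frames for detection rate, MAD
#'   and MCC (default 5).
#' @param sens_tolerance Stricter tolerance for sensitivity (default 3).
#' @param scenario Optional scenario label carried into the report.
#' @param tn Optional user-supplied true-negative count (per event type).
#' @return An object of class `eval_report`: a list with one entry per
#'   event type (`HS`, `TO`), each holding `n_truth`, `tp`, `fp`, `fn`,
#'   `tn`, `detection_rate`, `sensitivity`, `average_difference`, `mcc`,
#'   `error_histogram` and `zero_fraction`, plus `scenario`.
#' @export
evaluate_events <- function(detected, truth, n_frames,
                            tolerance = 5, sens_tolerance = 3,
                            scenario = NA_character_, tn = NULL) {
  per_type <- function(type) {
    tf <- sort(truth$frame[truth$type == type])
    df <- sort(detected$frame[detected$type == type])
    m5 <- match_events(tf, df, tolerance)
    m3 <- match_events(tf, df, sens_tolerance)
    tn_type <- if (!is.null(tn)) tn
               else count_true_negatives(tf, df, n_frames)
    hist <- error_histogram(m5)
    list(
      n_truth = length(tf), n_detected = length(df),
      tp = m5$tp, fp = m5$fp, fn = m5$fn, tn = tn_type,
      detection_rate = detection_rate(m5$tp, length(tf)),
      sensitivity = if (length(tf) == 0) 0 else sensitivity(m3$tp, m3$fn),
      average_difference = average_difference(m5),
      mcc = mcc(m5$tp, m5$fp, tn_type, m5$fn),
      error_histogram = hist$histogram,
      zero_fraction = hist$zero_fraction,
      match = m5
    )
  }
  structure(
    list(scenario = scenario, tolerance = tolerance,
         sens_tolerance = sens_tolerance,
         HS = per_type("HS"), TO = per_type("TO")),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> scenario: %s (tol %g / %g frames)\n",
              x$scenario, x$tolerance, x$sens_tolerance))
  for (type in c("HS", "TO")) {
    r <- x[[type]]
    cat(sprintf("  %s: n=%d  rate=%.2f%%  sens=%s  MAD=%.2f  MCC=%.3f\n",
                type, r$n_truth, r$detection_rate,
                ifelse(is.na(r$sensitivity), "NA",
                       sprintf("%.2f%%", r$sensitivity)),
                r$average_difference, r$mcc))
  }
  invisible(x)
}
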