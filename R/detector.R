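#' Detector configuration
#'
#' Tunables of the gait-event state machine. The shipped defaults are the
#' recommended operating point found by grid search (`sleeptime0 = 60`,
#' `bar = 9`, threshold fraction 0.6, queue length 5): at 60 Hz a sleep time
#' of 60 frames is one second, about one stride of comfortable walking.
#'
#' @param sleeptime0 Non-negative integer: the cold-start (and minimum
#'   reference) refractory period in frames, used until the interval queue
#'   has observations. This is the grid-searched *sleeptime* hyperparameter.
#' @param bar Non-negative real: the grid-searched *bar* hyperparameter. It
#'   is used both as the indicator threshold of the DGEI curves and as the
#'   baseline a curve extremum must exceed to become a candidate.
#' @param threshold0 Amplitude threshold used while the peak queue is empty.
#'   Default 0 so the first genuine peak always seeds the queue.
#' @param threshold_fraction Fraction of the weighted mean of recent
#'   accepted peak amplitudes that a new candidate must exceed; default 0.60.
#' @param queue_len_q Capacity of the weighted queues (intervals and peak
#'   amplitudes), default 5: long enough to smooth noise, short enough to
#'   adapt within a few strides.
#' @param ws_quiet_frames Quiet span (frames) after which the next validated
#'   gait event is additionally flagged as a walking start. Default 120
#'   frames (2 s at 60 Hz).
#' @param wp_quiet_multiplier A walking pause is emitted when no event is
#'   validated for this multiple of the sleep time in force; default 2.
#' @param alternation `"soft"` (default) rejects a candidate whose type
#'   equals the type of the last accepted gait event (one heel strike and
#'   one toe-off per cycle); `"off"` disables the rule, useful for
#'   pathological gaits where events drop out.
#' @param sleep_floor Lower clamp on the adaptive sleep time, preventing
#'   refractory collapse when short intervals enter the queue. Default
#'   `sleeptime0 / 2`.
#' @param sleep_margin Factor applied to the weighted mean of recent
#'   intervals when deriving the refractory period. The refractory must be
#'   the shortest credible stride, not the average one: with the default
#'   0.9 a stride up to 10% quicker than recent cadence is still accepted,
#'   which covers the stride-time variability of steady gait.
#' @param cadence_cap A candidate-to-candidate interval is admitted into the
#'   interval queue only if it is below `cadence_cap` times the sleep time
#'   in force: longer gaps span a missed event or a pause, not one stride,
#'   and would lock the refractory onto a multiple of the true interval.
#'   Default 1.75 (midway between one and two strides).
#' @param refine Logical; when `TRUE` (default) an accepted event is stamped
#'   at the raw-signal extremum (maximum for toe-off, minimum for heel
#'   strike) within `refine_window` frames of the curve candidate, so
#'   reported frames align with annotations even though the decision is
#'   taken early on the slope curves.
#' @param refine_window Half-width in frames of the refinement search;
#'   `NULL` (default) uses the DGEI window width.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(sleeptime0 = 60L,
                            bar = 9,
                            threshold0 = 0,
                            threshold_fraction = 0.60,
                            queue_len_q = 5L,
                            ws_quiet_frames = 120L,
                            wp_quiet_multiplier = 2,
                            alternation = c("soft", "off"),
                            sleep_floor = NULL,
                            sleep_margin = 0.9,
                            cadence_cap = 1.75,
                            refine = TRUE,
                            refine_window = NULL) {
  alternation <- match.arg(alternation)
  sleeptime0 <- as.integer(sleeptime0)
  if (is.na(sleeptime0) || sleeptime0 < 0) stop("'sleeptime0' must be >= 0")
  if (bar < 0) stop("'bar' must be non-negative")
  if (threshold0 < 0) stop("'threshold0' must be non-negative")
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("'threshold_fraction' must be in (0, 1]")
  }
  queue_len_q <- as.integer(queue_len_q)
  if (is.na(queue_len_q) || queue_len_q < 1 || queue_len_q > 50) {
    stop("'queue_len_q' must be in 1..50")
  }
  if (ws_quiet_frames < 1) stop("'ws_quiet_frames' must be positive")
  if (wp_quiet_multiplier <= 1) stop("'wp_quiet_multiplier' must exceed 1")
  if (is.null(sleep_floor)) sleep_floor <- sleeptime0 / 2
  if (sleep_floor < 0) stop("'sleep_floor' must be non-negative")
  if (sleep_margin <= 0 || sleep_margin > 1) stop("'sleep_margin' must be in (0, 1]")
  if (cadence_cap <= 0) stop("'cadence_cap' must be positive")
  structure(
    list(sleeptime0 = sleeptime0, bar = as.numeric(bar),
         threshold0 = as.numeric(threshold0),
         threshold_fraction = threshold_fraction,
         queue_len_q = queue_len_q,
         ws_quiet_frames = as.numeric(ws_quiet_frames),
         wp_quiet_multiplier = as.numeric(wp_quiet_multiplier),
         alternation = alternation,
         sleep_floor = as.numeric(sleep_floor),
         sleep_margin = as.numeric(sleep_margin),
         cadence_cap = as.numeric(cadence_cap),
         refine = isTRUE(refine),
         refine_window = if (is.null(refine_window)) NULL
                         else as.integer(refine_window)),
    class = "detector_config"
  )
}

#' Sleep time currently in force
#'
#' The positionally weighted mean of the recent same-type inter-event
#' intervals, scaled by `sleep_margin` and clamped below by the configured
#' floor; the cold-start value `sleeptime0` while the queue is empty.
#' Faster cadence shortens the queue entries and therefore the refractory
#' period.
#'
#' @param intervals A [weighted_queue] of recent intervals (frames).
#' @param config A [detector_config].
#' @return Sleep time in frames.
#' @export
current_sleeptime <- function(intervals, config) {
  wm <- weighted_mean(intervals, empty = NA_real_)
  if (is.na(wm)) return(as.numeric(config$sleeptime0))
  max(config$sleep_floor, config$sleep_margin * wm)
}

#' Amplitude threshold currently in force
#'
#' `threshold_fraction` times the positionally weighted mean of recent
#' accepted peak amplitudes; `threshold0` while the queue is empty.
#'
#' @param peaks A [weighted_queue] of recent accepted peak amplitudes.
#' @param config A [detector_config].
#' @return Threshold in curve-amplitude units.
#' @export
current_threshold <- function(peaks, config) {
  wm <- weighted_mean(peaks, empty = NA_real_)
  if (is.na(wm)) return(config$threshold0)
  config$threshold_fraction * wm
}

# Plateau-aware interior extrema of a curve with baseline hysteresis.
# Returns 0-based frames (from the curve frame vector) of strict local
# maxima of `x` exceeding `baseline`; a plateau counts once, at its first
# frame, and endpoints are never candidates. A new maximum only counts
# after the curve has dropped back to the baseline since the previous one
# (peaks must emerge after crossing the baseline), so small ripples on top
# of one excursion yield a single candidate.
plateau_maxima <- function(frames, x, baseline) {
  r <- rle(x)
  nr <- length(r$values)
  if (nr < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-nr]))
  keep <- logical(nr)
  armed <- TRUE
  for (t in seq_len(nr)) {
    if (r$values[t] <= baseline) {
      armed <- TRUE
    } else if (armed && t >= 2 && t <= nr - 1 &&
               r$values[t] > r$values[t - 1] &&
               r$values[t] > r$values[t + 1]) {
      keep[t] <- TRUE
      armed <- FALSE
    }
  }
  frames[starts[keep]]
}

#' Candidate peaks and troughs of the DGEI curves
#'
#' Toe-off candidates are strict interior local maxima of the positive curve
#' whose value exceeds the baseline; heel-strike candidates are strict
#' interior local minima of the negative curve whose magnitude exceeds the
#' baseline. A plateau of equal values yields a single candidate at its
#' first frame.
#'
#' @param curves A [dgei_curves] object.
#' @param bar Non-negative baseline the extremum must cross.
#' @return A list with data frames `to` and `hs`, each with columns `frame`
#'   (0-based) and `value` (positive magnitude of the curve at the
#'   candidate).
#' @export
candidate_peaks <- function(curves, bar = 0) {
  stopifnot(inherits(curves, "dgei_curves"))
  if (bar < 0) stop("'bar' must be non-negative")
  f_to <- plateau_maxima(curves$frame, curves$pos, bar)
  f_hs <- plateau_maxima(curves$frame, -curves$neg, bar)
  list(
    to = data.frame(frame = f_to,
                    value = curves$pos[match(f_to, curves$frame)]),
    hs = data.frame(frame = f_hs,
                    value = -curves$neg[match(f_hs, curves$frame)])
  )
}

# Stamp an event at the raw-signal extremum near a curve candidate.
# frame0 is 0-based; returns a 0-based frame. Ties resolve to the earliest
# frame (which.max/which.min semantics).
refine_event_frame <- function(values, frame0, type, window) {
  n <- length(values)
  lo <- max(1L, frame0 + 1L - window)
  hi <- min(n, frame0 + 1L + window)
  seg <- values[lo:hi]
  k <- if (type == "TO") which.max(seg) else which.min(seg)
  (lo + k - 1L) - 1L
}

new_detector_state <- function(config) {
  q <- config$queue_len_q
  list(
    config = config,
    to_amp = weighted_queue(q), hs_amp = weighted_queue(q),
    to_int = weighted_queue(q), hs_int = weighted_queue(q),
    last_emit = c(TO = NA_real_, HS = NA_real_),
    last_cand = c(TO = NA_real_, HS = NA_real_),
    last_cand_frame_any = -Inf,
    last_emit_any = NA_real_,
    last_type = NA_character_
  )
}

# One validation step. `cand` has candidate frame (curve), refined frame,
# type ("TO"/"HS") and value (positive magnitude). Returns the updated state
# plus a log row; `accepted` tells whether an event is emitted.
detector_step <- function(state, cand) {
  cfg <- state$config
  if (cand$frame < state$last_cand_frame_any) {
    stop("candidates must arrive in frame order (contract violation)")
  }
  state$last_cand_frame_any <- cand$frame
  type <- cand$type
  f <- cand$refined
  v <- cand$value

  intervals <- if (type == "TO") state$to_int else state$hs_int
  amps <- if (type == "TO") state$to_amp else state$hs_amp
  st <- current_sleeptime(intervals, cfg)
  th <- current_threshold(amps, cfg)

  reason <- "accepted"
  accepted <- FALSE
  if (!is.na(state$last_emit_any) && f <= state$last_emit_any) {
    reason <- "superseded"
  } else if (v < th) {
    reason <- "threshold"
  } else {
    # Above-threshold candidates inform the cadence estimate even when the
    # refractory gate suppresses emission, so the sleep time tracks
    # accelerations; implausibly long gaps (pauses) are not cadence.
    prev_c <- state$last_cand[[type]]
    if (!is.na(prev_c)) {
      gap <- f - prev_c
      if (gap >= 1 && gap < cfg$cadence_cap * st) {
        if (type == "TO") state$to_int <- wq_push(state$to_int, gap)
        else state$hs_int <- wq_push(state$hs_int, gap)
      }
    }
    state$last_cand[[type]] <- max(f, prev_c, na.rm = TRUE)

    last_e <- state$last_emit[[type]]
    if (!is.na(last_e) && f < last_e + st) {
      reason <- "sleep"
    } else if (cfg$alternation == "soft" && !is.na(state$last_type) &&
               state$last_type == type) {
      reason <- "alternation"
    } else {
      accepted <- TRUE
      if (type == "TO") state$to_amp <- wq_push(state$to_amp, v)
      else state$hs_amp <- wq_push(state$hs_amp, v)
      state$last_emit[[type]] <- f
      state$last_emit_any <- f
      state$last_type <- type
    }
  }
  log <- data.frame(cand_frame = cand$frame, frame = f, type = type,
                    value = v, sleeptime = st, threshold = th,
                    accepted = accepted, reason = reason,
                    stringsAsFactors = FALSE)
  list(state = state, accepted = accepted, log = log)
}

gait_events_frame <- function(frame = integer(0), type = character(0),
                              value = numeric(0), source = character(0),
                              sleep_frames = numeric(0), sample_rate_hz = 60) {
  df <- data.frame(frame = as.integer(frame),
                   time_s = as.numeric(frame) / sample_rate_hz,
                   type = as.character(type),
                   value = as.numeric(value),
                   source = as.character(source),
                   sleep_frames = as.numeric(sleep_frames),
                   stringsAsFactors = FALSE)
  class(df) <- c("gait_events", "data.frame")
  df
}

#' Walking-start and walking-pause events from a validated event stream
#'
#' The method's two remaining event types bound quiescent spans. A walking
#' start (WS) is stamped at the first validated gait event of the recording
#' and at any validated event preceded by a quiet span of at least
#' `ws_quiet_frames`. A walking pause (WP) is stamped at
#' `last_event_frame + wp_quiet_multiplier * sleeptime` whenever no event is
#' validated for that long after an event (including a trailing quiet span
#' at the end of the recording). Sub-threshold tremor during standing never
#' reaches this stage, so stationary phases produce no spurious starts.
#'
#' @param events A `gait_events` data frame of validated HS/TO events (as
#'   produced by [run_detector()]'s validation stage).
#' @param signal The [gait_signal] the events were detected on (its length
#'   bounds the trailing span).
#' @param config A [detector_config].
#' @return A `gait_events` data frame of WS/WP events (possibly empty).
#' @export
detect_walk_transitions <- function(events, signal, config) {
  n_frames <- if (inherits(signal, "gait_signal")) length(signal$values)
              else as.integer(signal)
  sr <- if (inherits(signal, "gait_signal")) signal$sample_rate_hz else 60
  gait <- events[events$type %in% c("HS", "TO"), , drop = FALSE]
  out_frame <- integer(0); out_type <- character(0); out_value <- numeric(0)
  k <- nrow(gait)
  if (k > 0) {
    gait <- gait[order(gait$frame), , drop = FALSE]
    sleep <- gait$sleep_frames
    sleep[is.na(sleep)] <- config$sleeptime0
    out_frame <- gait$frame[1]
    out_type <- "WS"
    out_value <- gait$value[1]
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        gap <- gait$frame[i + 1] - gait$frame[i]
        limit <- config$wp_quiet_multiplier * sleep[i]
        if (gap > limit) {
          out_frame <- c(out_frame, gait$frame[i] + as.integer(round(limit)))
          out_type <- c(out_type, "WP")
          out_value <- c(out_value, 0)
        }
        if (gap >= config$ws_quiet_frames) {
          out_frame <- c(out_frame, gait$frame[i + 1])
          out_type <- c(out_type, "WS")
          out_value <- c(out_value, gait$value[i + 1])
        }
      }
    }
    tail_limit <- config$wp_quiet_multiplier * sleep[k]
    if ((n_frames - 1) - gait$frame[k] > tail_limit) {
      out_frame <- c(out_frame, gait$frame[k] + as.integer(round(tail_limit)))
      out_type <- c(out_type, "WP")
      out_value <- c(out_value, 0)
    }
  }
  gait_events_frame(out_frame, out_type, out_value,
                    source = rep("state_machine", length(out_frame)),
                    sleep_frames = rep(NA_real_, length(out_frame)),
                    sample_rate_hz = sr)
}

merge_candidates <- function(cand) {
  to <- cand$to; hs <- cand$hs
  df <- rbind(
    if (nrow(to)) data.frame(frame = to$frame, type = "TO", value = to$value,
                             stringsAsFactors = FALSE),
    if (nrow(hs)) data.frame(frame = hs$frame, type = "HS", value = hs$value,
                             stringsAsFactors = FALSE)
  )
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(frame = integer(0), type = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  }
  # tie-break: toe-off (positive curve) before heel strike at equal frames
  df[order(df$frame, df$type == "HS"), , drop = FALSE]
}

#' Run the full gait-event detector
#'
#' Deterministic single-pass composition: [dgei_curves()] ->
#' [candidate_peaks()] -> streaming validation (refractory, adaptive
#' threshold, alternation) -> [detect_walk_transitions()]. The `bar` value
#' of `config` overrides the one in `params` so the grid-searched
#' hyperparameter acts on both the indicator and the candidate baseline.
#'
#' @param signal A [gait_signal] (or numeric vector, taken at 60 Hz).
#' @param params A [dgei_params].
#' @param config A [detector_config].
#' @return A `gait_events` data frame with columns `frame` (0-based),
#'   `time_s`, `type` (`HS`/`TO`/`WS`/`WP`), `value`, `source` and
#'   `sleep_frames` (the sleep time in force when the event was accepted;
#'   `NA` for WS/WP). The full decision log, one row per candidate, is
#'   attached as attribute `"state_log"`.
#' @examples
#' sc <- generate_scenario(scenario_spec("standard_locomotion", n_cycles = 5,
#'                                       period_jitter = 0, amplitude_jitter = 0,
#'                                       noise_sd = 0, seed = 1))
#' ev <- run_detector(sc$signal)
#' table(ev$type)
#' @export
run_detector <- function(signal, params = dgei_params(),
                         config = detector_config()) {
  signal <- as_gait_signal(signal)
  stopifnot(inherits(params, "dgei_params"), inherits(config, "detector_config"))
  params$bar <- config$bar
  curves <- dgei_curves(signal, params)
  cand <- merge_candidates(candidate_peaks(curves, config$bar))
  rw <- if (is.null(config$refine_window)) params$window_w
        else config$refine_window

  state <- new_detector_state(config)
  logs <- vector("list", nrow(cand))
  ev_frame <- integer(0); ev_type <- character(0); ev_value <- numeric(0)
  ev_sleep <- numeric(0)
  if (nrow(cand) > 0) {
    for (i in seq_len(nrow(cand))) {
      f0 <- cand$frame[i]
      type <- cand$type[i]
      refined <- if (config$refine) {
        refine_event_frame(signal$values, f0, type, rw)
      } else f0
      step <- detector_step(state, list(frame = f0, refined = refined,
                                        type = type, value = cand$value[i]))
      state <- step$state
      logs[[i]] <- step$log
      if (step$accepted) {
        ev_frame <- c(ev_frame, refined)
        ev_type <- c(ev_type, type)
        ev_value <- c(ev_value, cand$value[i])
        ev_sleep <- c(ev_sleep, step$log$sleeptime)
      }
    }
  }
  events <- gait_events_frame(
    ev_frame, ev_type, ev_value,
    source = ifelse(ev_type == "TO", "pos_curve", "neg_curve"),
    sleep_frames = ev_sleep, sample_rate_hz = signal$sample_rate_hz
  )
  trans <- detect_walk_transitions(events, signal, config)
  out <- rbind(events, trans)
  rank <- ifelse(out$type %in% c("WS", "WP"), 2L, 1L)
  out <- out[order(out$frame, rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gait_events", "data.frame")
  attr(out, "state_log") <- do.call(rbind, logs)
  attr(out, "sample_rate_hz") <- signal$sample_rate_hz
  out
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d events (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$type)), table(x$type)),
                    collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
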