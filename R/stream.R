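#' Streaming gait-event detector
#'
#' Online counterpart of [run_detector()]: samples are fed one at a time (or
#' in chunks) and events are emitted as soon as they are decidable. The
#' stream maintains the causal DGEI accumulators, confirms curve extrema
#' once the curve drops on their far side, waits for the short refinement
#' look-ahead, and then applies the same validation state machine as the
#' batch path. After [stream_finalize()] the event list is identical to a
#' single batch call on the full signal.
#'
#' @param params A [dgei_params].
#' @param config A [detector_config].
#' @param sample_rate_hz Sampling rate of the incoming samples.
#' @return An object of class `dgei_stream` (a mutable environment).
#' @examples
#' st <- dgei_stream()
#' sc <- generate_scenario(scenario_spec("standard_locomotion", n_cycles = 3,
#'                                       period_jitter = 0, amplitude_jitter = 0,
#'                                       noise_sd = 0, seed = 1))
#' for (x in sc$signal$values) stream_push(st, x)
#' ev <- stream_finalize(st)
#' @export
dgei_stream <- function(params = dgei_params(), config = detector_config(),
                        sample_rate_hz = 60) {
  stopifnot(inherits(params, "dgei_params"), inherits(config, "detector_config"))
  params$bar <- config$bar
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$config <- config
  e$sr <- as.numeric(sample_rate_hz)
  e$w <- params$window_w
  e$rw <- if (is.null(config$refine_window)) params$window_w
          else config$refine_window
  e$values <- numeric(0)
  e$n <- 0L
  # running scalars for the causal alpha estimate
  e$s1 <- 0; e$s2 <- 0; e$srate <- 0
  # growing curve history (cp/cn cumulative masked sums, curve values)
  e$cp <- numeric(0); e$cn <- numeric(0)
  e$pos <- numeric(0); e$neg <- numeric(0)
  e$m <- 0L
  # run tracking per polarity: pos curve -> TO, mirrored neg curve -> HS
  e$run <- list(
    TO = list(value = NA_real_, start = NA_integer_, prev = NA_real_, idx = 0L),
    HS = list(value = NA_real_, start = NA_integer_, prev = NA_real_, idx = 0L)
  )
  e$armed <- list(TO = TRUE, HS = TRUE)
  e$pending <- list()        # confirmed, unprocessed candidates
  e$state <- new_detector_state(config)
  e$logs <- list()
  e$ev_frame <- integer(0); e$ev_type <- character(0)
  e$ev_value <- numeric(0); e$ev_sleep <- numeric(0)
  e$finalized <- FALSE
  class(e) <- "dgei_stream"
  e
}

# close/extend the open run of one polarity with curve value x at index j;
# returns a confirmed candidate (frame, value) or NULL. Mirrors
# plateau_maxima(), including the baseline re-arming hysteresis.
stream_run_update <- function(e, polarity, x, j) {
  r <- e$run[[polarity]]
  out <- NULL
  if (r$idx == 0L) {
    if (x <= e$config$bar) e$armed[[polarity]] <- TRUE
    r <- list(value = x, start = j, prev = NA_real_, idx = 1L)
  } else if (x != r$value) {
    if (r$value <= e$config$bar) {
      e$armed[[polarity]] <- TRUE
    } else if (e$armed[[polarity]] && r$idx >= 2L && !is.na(r$prev) &&
               r$value > r$prev && r$value > x) {
      out <- list(frame = r$start, value = r$value)
      e$armed[[polarity]] <- FALSE
    }
    r <- list(value = x, start = j, prev = r$value, idx = r$idx + 1L)
  }
  e$run[[polarity]] <- r
  out
}

stream_open_start <- function(e, polarity) {
  r <- e$run[[polarity]]
  if (r$idx == 0L) Inf else r$start
}

process_pending <- function(e, flush = FALSE) {
  repeat {
    if (length(e$pending) == 0) break
    ord <- order(vapply(e$pending, `[[`, 0, "frame"),
                 vapply(e$pending, function(p) p$type == "HS", TRUE))
    e$pending <- e$pending[ord]
    p <- e$pending[[1]]
    if (!flush) {
      guard <- if (p$type == "TO") stream_open_start(e, "HS") >= p$frame
               else stream_open_start(e, "TO") > p$frame
      if (!guard || e$n < p$frame + e$rw + 1) break
    }
    e$pending <- e$pending[-1]
    refined <- if (e$config$refine) {
      refine_event_frame(e$values[seq_len(e$n)], p$frame, p$type, e$rw)
    } else p$frame
    step <- detector_step(e$state, list(frame = p$frame, refined = refined,
                                        type = p$type, value = p$value))
    e$state <- step$state
    e$logs[[length(e$logs) + 1L]] <- step$log
    if (step$accepted) {
      e$ev_frame <- c(e$ev_frame, refined)
      e$ev_type <- c(e$ev_type, p$type)
      e$ev_value <- c(e$ev_value, p$value)
      e$ev_sleep <- c(e$ev_sleep, step$log$sleeptime)
    }
  }
  invisible(NULL)
}

#' Feed samples into a detector stream
#'
#' @param stream A [dgei_stream].
#' @param x Numeric sample(s), in time order.
#' @return The stream, invisibly.
#' @export
stream_push <- function(stream, x) {
  e <- stream
  if (e$finalized) stop("stream already finalized")
  for (xi in as.numeric(x)) {
    if (!is.finite(xi)) stop("samples must be finite")
    e$n <- e$n + 1L
    e$values <- c(e$values, xi)
    if (e$n >= 2L) {
      j <- e$m + 1L
      d <- e$values[e$n] - e$values[e$n - 1L]
      rate <- d * e$sr
      ind <- dgei_indicator(d, e$params$bar, e$params$indicator_mode)
      # causal alpha, same arithmetic as the batch cumulative formulation
      e$s1 <- e$s1 + d
      e$s2 <- e$s2 + d * d
      e$srate <- e$srate +
        if (e$params$rate_mean == "signed") rate else abs(rate)
      if (e$params$alpha_beta_mode == "fixed") {
        alpha <- e$params$fixed_alpha
      } else if (j <= e$w) {
        alpha <- 0.5
      } else {
        v <- (e$s2 - e$s1^2 / j) / max(j - 1, 1)
        if (j < 2) v <- 0
        sd_j <- sqrt(max(v, 0))
        mu_j <- e$srate / j
        denom <- sd_j + mu_j
        alpha <- if (is.finite(denom) && denom > 0) sd_j / denom else 0.5
      }
      cp_j <- (if (j > 1) e$cp[j - 1L] else 0) + (if (ind$pos == 1L) d else 0)
      cn_j <- (if (j > 1) e$cn[j - 1L] else 0) + (if (ind$neg == 1L) d else 0)
      e$cp <- c(e$cp, cp_j)
      e$cn <- c(e$cn, cn_j)
      lag <- j - e$w - 1L
      s_pos <- cp_j - if (lag >= 1) e$cp[lag] else 0
      s_neg <- cn_j - if (lag >= 1) e$cn[lag] else 0
      scale <- alpha + (1 - alpha) * e$sr
      pos_j <- scale * s_pos
      neg_j <- scale * s_neg
      e$pos <- c(e$pos, pos_j)
      e$neg <- c(e$neg, neg_j)
      e$m <- j

      c_to <- stream_run_update(e, "TO", pos_j, j)
      if (!is.null(c_to)) {
        e$pending[[length(e$pending) + 1L]] <-
          list(frame = c_to$frame, type = "TO", value = c_to$value)
      }
      c_hs <- stream_run_update(e, "HS", -neg_j, j)
      if (!is.null(c_hs)) {
        e$pending[[length(e$pending) + 1L]] <-
          list(frame = c_hs$frame, type = "HS", value = c_hs$value)
      }
      process_pending(e)
    }
  }
  invisible(stream)
}

#' Validated gait events emitted so far by a stream
#'
#' @param stream A [dgei_stream].
#' @return A `gait_events` data frame of the HS/TO events emitted so far.
#' @export
stream_events <- function(stream) {
  e <- stream
  gait_events_frame(e$ev_frame, e$ev_type, e$ev_value,
                    source = ifelse(e$ev_type == "TO", "pos_curve", "neg_curve"),
                    sleep_frames = e$ev_sleep, sample_rate_hz = e$sr)
}

#' Finalize a detector stream
#'
#' Flushes all pending candidates, derives walking-start/pause events and
#' returns the complete event list, identical to [run_detector()] on the
#' full signal.
#'
#' @param stream A [dgei_stream].
#' @return A `gait_events` data frame (see [run_detector()]).
#' @export
stream_finalize <- function(stream) {
  e <- stream
  if (!e$finalized) {
    process_pending(e, flush = TRUE)
    e$finalized <- TRUE
  }
  events <- stream_events(e)
  sig <- gait_signal(if (e$n > 0) e$values[seq_len(e$n)] else 0, e$sr)
  trans <- detect_walk_transitions(events, sig, e$config)
  out <- rbind(events, trans)
  rank <- ifelse(out$type %in% c("WS", "WP"), 2L, 1L)
  out <- out[order(out$frame, rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gait_events", "data.frame")
  attr(out, "state_log") <- if (length(e$logs)) do.call(rbind, e$logs) else NULL
  attr(out, "sample_rate_hz") <- e$sr
  out
}

#' @export
print.dgei_stream <- function(x, ...) {
  cat(sprintf("<dgei_stream> %d samples seen, %d events emitted, %d pending\n",
              x$n, length(x$ev_frame), length(x$pending)))
  invisible(x)
}
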