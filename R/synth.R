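#' Scenario specification for the synthetic gait generator
#'
#' Describes one recording scenario: a quasi-periodic pulse train with one
#' dominant peak (toe-off) and one dominant trough (heel strike) per gait
#' cycle, or a static-posture span with only low-amplitude tremor. Defaults
#' are chosen per scenario kind to be physiologically plausible for a
#' shank-mounted sensor at 60 Hz; a standard stride of one second (60
#' frames) with a channel amplitude of 30 degrees is the reference
#' condition.
#'
#' @param kind One of `"standard_locomotion"`, `"fast_start_stop"`,
#'   `"turning"`, `"static_posture"`, `"shuffling"`,
#'   `"tremor_pathological"`.
#' @param n_cycles Number of gait cycles (for `static_posture`: the span
#'   lasts `n_cycles * period_frames` frames with no gait events).
#' @param period_frames Mean gait-cycle length in frames (>= 4).
#' @param period_jitter Coefficient of variation of the per-cycle period.
#' @param amplitude Peak amplitude of the channel, degrees.
#' @param amplitude_jitter Coefficient of variation of per-cycle amplitude.
#' @param noise_sd Standard deviation of additive Gaussian noise, degrees.
#' @param tremor_rate Expected tremor spikes per 100 frames during static
#'   spans.
#' @param drop_prob Probability that a cycle's pulse is dropped (flat
#'   cycle, no truth events); nonzero only for the pathological kind.
#' @param seed Integer seed; fixes the full output.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("standard_locomotion", "fast_start_stop",
                                   "turning", "static_posture", "shuffling",
                                   "tremor_pathological"),
                          n_cycles = 20L,
                          period_frames = NULL,
                          period_jitter = NULL,
                          amplitude = NULL,
                          amplitude_jitter = NULL,
                          noise_sd = NULL,
                          tremor_rate = 1.5,
                          drop_prob = NULL,
                          seed = 1L) {
  kind <- match.arg(kind)
  defs <- switch(kind,
    standard_locomotion = list(period = 60, pj = 0.02, amp = 30, aj = 0.05,
                               noise = 0.3, drop = 0),
    fast_start_stop     = list(period = 40, pj = 0.05, amp = 36, aj = 0.08,
                               noise = 0.4, drop = 0),
    turning             = list(period = 70, pj = 0.08, amp = 27, aj = 0.10,
                               noise = 0.4, drop = 0),
    static_posture      = list(period = 60, pj = 0,    amp = 0,  aj = 0,
                               noise = 0.3, drop = 0),
    shuffling           = list(period = 50, pj = 0.06, amp = 15, aj = 0.10,
                               noise = 0.4, drop = 0),
    tremor_pathological = list(period = 60, pj = 0.12, amp = 30, aj = 0.20,
                               noise = 0.6, drop = 0.1)
  )
  period_frames <- if (is.null(period_frames)) defs$period else period_frames
  if (period_frames < 4) stop("'period_frames' must be >= 4")
  spec <- structure(
    list(kind = kind,
         n_cycles = as.integer(n_cycles),
         period_frames = as.numeric(period_frames),
         period_jitter = if (is.null(period_jitter)) defs$pj
                         else period_jitter,
         amplitude = if (is.null(amplitude)) defs$amp else amplitude,
         amplitude_jitter = if (is.null(amplitude_jitter)) defs$aj
                            else amplitude_jitter,
         noise_sd = if (is.null(noise_sd)) defs$noise else noise_sd,
         tremor_rate = as.numeric(tremor_rate),
         drop_prob = if (is.null(drop_prob)) defs$drop else drop_prob,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
  if (spec$period_jitter < 0 || spec$amplitude_jitter < 0 ||
      spec$noise_sd < 0 || spec$tremor_rate < 0 ||
      spec$drop_prob < 0 || spec$drop_prob > 1) {
    stop("jitter/noise/tremor/drop parameters must be valid")
  }
  spec
}

# asymmetric raised-cosine bump centred at `centre` (0-based), evaluated on
# 0..(period-1): rising half of total width `width_rise`, falling half of
# total width `width_fall`
rc_bump <- function(period, centre, width_rise, width_fall) {
  t <- seq_len(period) - 1
  x <- numeric(period)
  rise <- t >= centre - width_rise / 2 & t <= centre
  fall <- t > centre & t <= centre + width_fall / 2
  x[rise] <- 0.5 * (1 + cos(2 * pi * (t[rise] - centre) / width_rise))
  x[fall] <- 0.5 * (1 + cos(2 * pi * (t[fall] - centre) / width_fall))
  x
}

#' One synthetic gait-cycle waveform
#'
#' A smooth composite of a raised-cosine pulse (the toe-off peak, at 30% of
#' the cycle) and an equal-depth raised-cosine trough (the heel strike, at
#' 70%), with zero endpoints so cycles concatenate continuously. Both
#' features are asymmetric, as in a tibial channel: the pulse has a steep
#' rising edge (8% of the period, the sharp push-off transient) and a
#' gentle fall (30%), the trough a
#' steep descent and a gentle recovery. Only the steep edges of a standard
#' 30-degree, 60-frame cycle exceed the default indicator threshold, so
#' the positive DGEI curve fires once per cycle (before the peak) and the
#' negative curve once (before the trough).
#'
#' @param period Cycle length in frames (>= 4).
#' @param amplitude Peak (and trough) amplitude, degrees.
#' @return List with `values` (length `period`), `to_offset` and
#'   `hs_offset` (0-based frames of the cycle maximum and minimum).
#' @export
generate_cycle_waveform <- function(period, amplitude) {
  period <- as.integer(round(period))
  if (is.na(period) || period < 4) stop("'period' must be >= 4 frames")
  to_off <- round(0.3 * period)
  hs_off <- round(0.7 * period)
  steep <- max(3, round(0.08 * period))
  gentle <- max(4, round(0.30 * period))
  values <- amplitude * rc_bump(period, to_off, steep, gentle) -
            amplitude * rc_bump(period, hs_off, steep, gentle)
  list(values = values, to_offset = as.integer(to_off),
       hs_offset = as.integer(hs_off))
}

truth_frame <- function(frame = integer(0), type = character(0),
                        value = numeric(0), sample_rate_hz = 60) {
  gait_events_frame(frame, type, value,
                    source = rep("truth", length(frame)),
                    sleep_frames = rep(NA_real_, length(frame)),
                    sample_rate_hz = sample_rate_hz)
}

#' Generate one annotated synthetic scenario
#'
#' Draws per-cycle periods and amplitudes with the specified jitter,
#' concatenates cycle waveforms, adds Gaussian noise, and returns the
#' signal together with its ground-truth annotations: one TO (pulse peak)
#' and one HS (trough) per non-dropped cycle, a WS at the first gait event,
#' and no gait events at all for `static_posture`, which instead emits a
#' flat baseline with sparse sub-threshold tremor spikes (3-frame bumps of
#' at most 0.28 times the standard gait amplitude).
#'
#' Everything is drawn under the spec's seed through an isolated RNG scope,
#' so identical specs produce byte-identical output and the caller's RNG
#' state is untouched.
#'
#' @param spec A [scenario_spec].
#' @param sample_rate_hz Sampling rate, default 60.
#' @return An object of class `annotated_signal`: list with `signal`
#'   ([gait_signal]), `truth` (a `gait_events` data frame) and `spec`.
#' @examples
#' sc <- generate_scenario(scenario_spec("standard_locomotion", n_cycles = 5,
#'                                       seed = 7))
#' table(sc$truth$type)
#' @export
generate_scenario <- function(spec, sample_rate_hz = 60) {
  stopifnot(inherits(spec, "scenario_spec"))
  withr::with_seed(spec$seed, {
    if (spec$kind == "static_posture") {
      n <- as.integer(round(spec$n_cycles * spec$period_frames))
      n <- max(n, 8L)
      values <- numeric(n)
      n_spikes <- stats::rpois(1, spec$tremor_rate * n / 100)
      if (n_spikes > 0) {
        at <- sample(seq_len(max(n - 3, 1)), n_spikes, replace = TRUE)
        for (p in at) {
          amp <- stats::runif(1, 0.05, 0.28) * 30 * sample(c(-1, 1), 1)
          idx <- p:(p + 2)
          values[idx] <- values[idx] + amp * c(0.5, 1, 0.5)
        }
      }
      values <- values + stats::rnorm(n, 0, spec$noise_sd)
      truth <- truth_frame(sample_rate_hz = sample_rate_hz)
    } else {
      pieces <- list()
      tf <- integer(0); tt <- character(0); tv <- numeric(0)
      base <- 0L
      for (c_i in seq_len(spec$n_cycles)) {
        p_c <- max(4L, as.integer(round(spec$period_frames *
          (1 + stats::rnorm(1, 0, spec$period_jitter)))))
        a_c <- spec$amplitude *
          max(0, 1 + stats::rnorm(1, 0, spec$amplitude_jitter))
        dropped <- spec$drop_prob > 0 && stats::runif(1) < spec$drop_prob
        if (dropped) {
          pieces[[c_i]] <- numeric(p_c)
        } else {
          cyc <- generate_cycle_waveform(p_c, a_c)
          pieces[[c_i]] <- cyc$values
          tf <- c(tf, base + cyc$to_offset, base + cyc$hs_offset)
          tt <- c(tt, "TO", "HS")
          tv <- c(tv, a_c, -a_c)
        }
        base <- base + p_c
      }
      values <- unlist(pieces, use.names = FALSE)
      if (spec$noise_sd > 0) {
        values <- values + stats::rnorm(length(values), 0, spec$noise_sd)
      }
      ord <- order(tf)
      truth <- truth_frame(tf[ord], tt[ord], tv[ord], sample_rate_hz)
      if (nrow(truth) > 0) {
        ws <- truth_frame(truth$frame[1], "WS", truth$value[1],
                          sample_rate_hz)
        truth <- rbind(truth, ws)
        truth <- truth[order(truth$frame,
                             truth$type %in% c("WS", "WP")), , drop = FALSE]
        rownames(truth) <- NULL
        class(truth) <- c("gait_events", "data.frame")
      }
    }
    structure(list(signal = gait_signal(values, sample_rate_hz),
                   truth = truth, spec = spec),
              class = "annotated_signal")
  })
}

#' Splice scenarios into one continuous annotated stream
#'
#' Concatenates the scenario signals in order, blending each boundary over
#' a short linear cross-fade, re-offsets the truth frames, and inserts the
#' walking-start / walking-pause truths implied by the walking/static
#' structure: a WS at the first gait event of the stream and at the first
#' gait event after a static span, a WP at the end of a walking span that
#' is followed by a static span. Total length is the sum of the component
#' lengths minus `crossfade` frames per interior boundary.
#'
#' @param specs A list of [scenario_spec] objects (each with its own seed).
#' @param crossfade Cross-fade length in frames (default 5).
#' @param sample_rate_hz Sampling rate, default 60.
#' @return An `annotated_signal`; its `spec` is the list of component
#'   specs.
#' @examples
#' sp <- list(scenario_spec("standard_locomotion", n_cycles = 5, seed = 1),
#'            scenario_spec("static_posture", n_cycles = 4, seed = 2),
#'            scenario_spec("standard_locomotion", n_cycles = 5, seed = 3))
#' st <- splice_scenarios(sp)
#' table(st$truth$type)
#' @export
splice_scenarios <- function(specs, crossfade = 5L, sample_rate_hz = 60) {
  if (length(specs) < 1) stop("need at least one scenario spec")
  if (any(!vapply(specs, inherits, TRUE, "scenario_spec"))) {
    stop("'specs' must be a list of scenario_spec objects")
  }
  crossfade <- as.integer(crossfade)
  if (crossfade < 0) stop("'crossfade' must be non-negative")
  parts <- lapply(specs, generate_scenario, sample_rate_hz = sample_rate_hz)
  if (length(parts) == 1) return(parts[[1]])

  values <- parts[[1]]$signal$values
  offsets <- numeric(length(parts))
  offsets[1] <- 0
  for (i in 2:length(parts)) {
    seg <- parts[[i]]$signal$values
    cf <- min(crossfade, length(seg), length(values))
    if (cf > 0) {
      wgt <- seq_len(cf) / (cf + 1)
      tail_idx <- (length(values) - cf + 1):length(values)
      values[tail_idx] <- (1 - wgt) * values[tail_idx] + wgt * seg[seq_len(cf)]
      values <- c(values, seg[(cf + 1):length(seg)])
      offsets[i] <- offsets[i - 1] + length(parts[[i - 1]]$signal$values) - cf
    } else {
      values <- c(values, seg)
      offsets[i] <- offsets[i - 1] + length(parts[[i - 1]]$signal$values)
    }
  }

  # gait-event truths, re-offset; WS/WP recomputed from the span structure
  tf <- integer(0); tt <- character(0); tv <- numeric(0)
  is_walking <- vapply(parts, function(p) any(p$truth$type %in% c("HS", "TO")),
                       TRUE)
  prev_walking_end <- NA_real_
  first_ws_done <- FALSE
  for (i in seq_along(parts)) {
    if (!is_walking[i]) {
      if (i > 1 && is_walking[i - 1] && !is.na(prev_walking_end)) {
        tf <- c(tf, prev_walking_end); tt <- c(tt, "WP"); tv <- c(tv, 0)
      }
      next
    }
    g <- parts[[i]]$truth
    g <- g[g$type %in% c("HS", "TO"), , drop = FALSE]
    fr <- g$frame + offsets[i]
    prev_static <- i > 1 && !is_walking[i - 1]
    if (!first_ws_done || prev_static) {
      tf <- c(tf, fr[1]); tt <- c(tt, "WS"); tv <- c(tv, g$value[1])
      first_ws_done <- TRUE
    }
    tf <- c(tf, fr); tt <- c(tt, g$type); tv <- c(tv, g$value)
    prev_walking_end <- fr[length(fr)] +
      round(parts[[i]]$spec$period_frames / 2)
  }
  ord <- order(tf, tt %in% c("WS", "WP"))
  truth <- truth_frame(tf[ord], tt[ord], tv[ord], sample_rate_hz)
  structure(list(signal = gait_signal(values, sample_rate_hz),
                 truth = truth, spec = specs),
            class = "annotated_signal")
}

#' @export
print.annotated_signal <- function(x, ...) {
  kinds <- if (inherits(x$spec, "scenario_spec")) x$spec$kind
           else paste(vapply(x$spec, `[[`, "", "kind"), collapse = " + ")
  cat(sprintf("<annotated_signal> %s: %d frames, %d truth events\n",
              kinds, length(x$signal$values), nrow(x$truth)))
  invisible(x)
}
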