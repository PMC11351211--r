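# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: naive loops, closed forms and reference
# formulations only.

# Naive O(n*w) re-evaluation of the positive/negative windowed accumulators,
# frame by frame, with the causal alpha estimate recomputed from scratch via
# stats::sd / mean at every frame.
brute_force_curves <- function(values, sample_rate_hz, window_w, bar,
                               indicator_mode = "symmetric",
                               alpha_fixed = NULL) {
  d <- diff(values)
  rate <- d * sample_rate_hz
  m <- length(d)
  pos <- neg <- alpha <- numeric(m)
  for (j in seq_len(m)) {
    a <- if (!is.null(alpha_fixed)) {
      alpha_fixed
    } else if (j <= window_w) {
      0.5
    } else {
      sdv <- stats::sd(d[1:j])
      mu <- mean(abs(rate[1:j]))
      den <- sdv + mu
      if (is.finite(den) && den > 0) sdv / den else 0.5
    }
    alpha[j] <- a
    b <- 1 - a
    ks <- max(1, j - window_w):j
    contrib <- a * d[ks] + b * rate[ks]
    pm <- d[ks] > bar
    nm <- if (indicator_mode == "symmetric") d[ks] < -bar else d[ks] <= bar
    pos[j] <- sum(contrib[pm])
    neg[j] <- sum(contrib[nm])
  }
  list(pos = pos, neg = neg, alpha = alpha)
}

# Exhaustive optimal one-to-one assignment within tolerance: maximizes the
# number of matched pairs, then minimizes the total absolute error.
# Recursive enumeration; only usable for small instances.
optimal_assignment <- function(truth, detected, tolerance) {
  nt <- length(truth)
  best <- list(tp = -1L, err = Inf)
  recurse <- function(ti, used_d, tp, err) {
    if (ti > nt) {
      if (tp > best$tp || (tp == best$tp && err < best$err)) {
        best <<- list(tp = tp, err = err)
      }
      return(invisible(NULL))
    }
    # option: leave truth ti unmatched
    recurse(ti + 1L, used_d, tp, err)
    for (di in seq_along(detected)) {
      if (!used_d[di] && abs(truth[ti] - detected[di]) <= tolerance) {
        used_d[di] <- TRUE
        recurse(ti + 1L, used_d, tp + 1L, err + abs(truth[ti] - detected[di]))
        used_d[di] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(detected)), 0L, 0)
  best
}

# MCC as the Pearson correlation of the binary truth/prediction vectors
# implied by the confusion counts; degenerate margins give 0.
mcc_cor_oracle <- function(tp, fp, tn, fn) {
  actual <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  if (length(unique(actual)) < 2 || length(unique(pred)) < 2) return(0)
  suppressWarnings(stats::cor(actual, pred))
}

# Replay the detector's decision log and assert the refractory and
# threshold invariants on every accepted event.
assert_detector_invariants <- function(events) {
  log <- attr(events, "state_log")
  if (is.null(log) || !nrow(log)) return(invisible(TRUE))
  acc <- log[log$accepted, , drop = FALSE]
  for (type in c("TO", "HS")) {
    a <- acc[acc$type == type, , drop = FALSE]
    if (nrow(a) >= 2) {
      gaps <- diff(a$frame)
      # the sleep time in force when the later event crossed the gate
      expect_true(all(gaps >= a$sleeptime[-1] - 1e-9),
                  label = paste("refractory invariant for", type))
    }
    expect_true(all(a$value >= a$threshold - 1e-9),
                label = paste("threshold invariant for", type))
  }
  invisible(TRUE)
}

# Convenience: a clean, deterministic walking scenario.
clean_walk <- function(n_cycles = 20, period = 60, seed = 1) {
  generate_scenario(scenario_spec("standard_locomotion", n_cycles = n_cycles,
                                  period_frames = period, period_jitter = 0,
                                  amplitude_jitter = 0, noise_sd = 0,
                                  seed = seed))
}

frames_of <- function(events, type) sort(events$frame[events$type == type])
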