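#' Parameters of the DGEI curve computation
#'
#' @param window_w Positive integer width of the sliding window, in frames.
#'   At frame `i` the accumulators sum over frames `i - w .. i` inclusive
#'   (`w + 1` terms once the window is full; earlier frames use the partial
#'   window from the start of the signal so the curves are causal from the
#'   first difference). Default 10 frames (~167 ms at 60 Hz).
#' @param bar Non-negative indicator threshold on the per-frame difference:
#'   only differences beyond `bar` contribute to the accumulators.
#' @param alpha_beta_mode `"running"` (default) recomputes the balance
#'   weights alpha/beta causally at every frame from the samples seen so
#'   far; `"fixed"` uses `fixed_alpha`/`fixed_beta` throughout.
#' @param fixed_alpha,fixed_beta Constants used when
#'   `alpha_beta_mode = "fixed"`; must sum to 1 (tolerance 1e-9).
#' @param indicator_mode `"symmetric"` (default) sends differences `> bar`
#'   to the positive accumulator and `< -bar` to the negative one, so both
#'   branches gate on magnitude. `"verbatim"` gates the negative branch on
#'   `<= bar`, i.e. the exact complement of the positive branch; with
#'   `bar > 0` this routes small positive changes into the negative
#'   accumulator.
#' @param rate_mean `"absolute"` (default) computes the mean rate of change
#'   used in the alpha/beta balance from `|dy|/dt`, keeping both weights in
#'   `[0, 1]` on symmetric signals; `"signed"` uses the raw mean.
#'
#' @return An object of class `dgei_params` (a validated list).
#' @seealso [dgei_curves()]
#' @export
dgei_params <- function(window_w = 10L,
                        bar = 0,
                        alpha_beta_mode = c("running", "fixed"),
                        fixed_alpha = NULL,
                        fixed_beta = NULL,
                        indicator_mode = c("symmetric", "verbatim"),
                        rate_mean = c("absolute", "signed")) {
  alpha_beta_mode <- match.arg(alpha_beta_mode)
  indicator_mode <- match.arg(indicator_mode)
  rate_mean <- match.arg(rate_mean)
  window_w <- as.integer(window_w)
  if (is.na(window_w) || window_w < 1) stop("'window_w' must be >= 1")
  if (!is.numeric(bar) || length(bar) != 1 || !is.finite(bar) || bar < 0) {
    stop("'bar' must be a single non-negative number")
  }
  if (alpha_beta_mode == "fixed") {
    if (is.null(fixed_alpha) || is.null(fixed_beta)) {
      stop("fixed alpha/beta mode requires 'fixed_alpha' and 'fixed_beta'")
    }
    if (abs(fixed_alpha + fixed_beta - 1) > 1e-9) {
      stop("'fixed_alpha' + 'fixed_beta' must equal 1 (tolerance 1e-9)")
    }
  }
  structure(
    list(window_w = window_w, bar = as.numeric(bar),
         alpha_beta_mode = alpha_beta_mode,
         fixed_alpha = fixed_alpha, fixed_beta = fixed_beta,
         indicator_mode = indicator_mode, rate_mean = rate_mean),
    class = "dgei_params"
  )
}

#' Indicator function of the DGEI accumulators
#'
#' Decides, per frame, whether a difference feeds the positive or the
#' negative accumulator. The positive branch always fires iff
#' `delta_y > bar`. In `"symmetric"` mode the negative branch fires iff
#' `delta_y < -bar` (magnitude gating, matching the trough-detection role of
#' the negative curve); in `"verbatim"` mode it fires iff `delta_y <= bar`
#' (the exact complement of the positive branch).
#'
#' @param delta_y Numeric vector of per-frame differences.
#' @param bar Non-negative threshold.
#' @param mode `"symmetric"` or `"verbatim"`.
#' @return A list with integer vectors `pos` and `neg` of 0/1 flags.
#' @examples
#' dgei_indicator(c(10, -10, 0), bar = 9)
#' @export
dgei_indicator <- function(delta_y, bar, mode = c("symmetric", "verbatim")) {
  mode <- match.arg(mode)
  if (bar < 0) stop("'bar' must be non-negative")
  pos <- as.integer(delta_y > bar)
  neg <- if (mode == "symmetric") as.integer(delta_y < -bar)
         else as.integer(delta_y <= bar)
  list(pos = pos, neg = neg)
}

#' Balance weights between difference and rate terms
#'
#' Each windowed contribution is `alpha * dy + beta * dy/dt`. The weights
#' balance the immediate change against its rate:
#' `alpha = sd(dy) / (sd(dy) + mean_rate)` and `beta = 1 - alpha`, where
#' `mean_rate` is the mean of `|dy/dt|` (or of the signed rate when
#' `signed_mean = TRUE`). When the denominator is not positive (constant
#' signal, or a signed mean cancelling the deviation) the weights fall back
#' to 0.5/0.5 with a warning.
#'
#' @param diff_history Numeric vector of per-frame differences seen so far.
#' @param rate_history Numeric vector of per-frame rates `dy/dt`, same length.
#' @param signed_mean Use the signed mean rate instead of the mean magnitude.
#' @return Named numeric vector `c(alpha = , beta = )`, summing to 1.
#' @examples
#' adaptive_weights(c(3, -3, 3, -3), c(1, 1, 1, 1))
#' @export
adaptive_weights <- function(diff_history, rate_history, signed_mean = FALSE) {
  if (length(diff_history) == 0 || length(diff_history) != length(rate_history)) {
    stop("histories must be non-empty and of equal length")
  }
  sd_dy <- if (length(diff_history) > 1) stats::sd(diff_history) else 0
  mu_dv <- if (signed_mean) mean(rate_history) else mean(abs(rate_history))
  denom <- sd_dy + mu_dv
  if (!is.finite(denom) || denom <= 0) {
    warning("degenerate alpha/beta denominator; falling back to 0.5/0.5")
    return(c(alpha = 0.5, beta = 0.5))
  }
  c(alpha = sd_dy / denom, beta = mu_dv / denom)
}

# cumsum with per-step rounding to double, so the batch curves are
# bit-identical to the streaming accumulators (base cumsum carries extended
# precision across steps)
cumsum_dbl <- function(x) {
  s <- numeric(length(x))
  a <- 0
  for (i in seq_along(x)) {
    a <- a + x[i]
    s[i] <- a
  }
  s
}

# Causal per-frame alpha series from cumulative sums. Index j corresponds to
# the j-th difference; frames j <= warmup use 0.5. Same arithmetic as the
# streaming core so batch and stream agree bit for bit.
running_alpha <- function(d, rate, warmup, signed_mean = FALSE) {
  m <- length(d)
  j <- seq_len(m)
  s1 <- cumsum_dbl(d)
  s2 <- cumsum_dbl(d * d)
  v <- (s2 - s1^2 / j) / pmax(j - 1, 1)
  v[j < 2] <- 0
  sd_j <- sqrt(pmax(v, 0))
  mu_j <- if (signed_mean) cumsum_dbl(rate) / j else cumsum_dbl(abs(rate)) / j
  denom <- sd_j + mu_j
  alpha <- ifelse(is.finite(denom) & denom > 0, sd_j / denom, 0.5)
  alpha[j <= warmup] <- 0.5
  alpha
}

#' Compute the DGEI curves of a signal
#'
#' Builds the first-difference series and the positive/negative DGEI
#' accumulators. At difference index `i` (0-based signal frame `i`),
#' \deqn{pos_i = \sum_{k=i-w}^{i} (\alpha_i \Delta y_k +
#'   \beta_i \Delta y_k / \Delta t_k) \cdot 1[\Delta y_k > bar]}
#' and `neg` analogously with the negative branch of the indicator.
#' `dt` is the constant `1 / sample_rate_hz`; irregular sampling is not
#' supported. With `alpha_beta_mode = "running"` the weights at index `i`
#' are estimated from the differences seen up to `i` (causal), with a
#' warm-up of `window_w` frames at 0.5/0.5.
#'
#' The positive curve accumulates rising-slope activity and peaks around
#' toe-off pulses; the negative curve accumulates falling-slope activity and
#' dips around heel-strike troughs. Because the curves react to slope, their
#' extrema typically occur at or slightly before the raw-signal extrema,
#' which is what gives the detector its anticipatory behaviour.
#'
#' @param signal A [gait_signal] (or numeric vector, taken at 60 Hz).
#' @param params A [dgei_params] object.
#' @return An object of class `dgei_curves`: list with `frame` (0-based,
#'   aligned with the differences), `diff`, `rate`, `pos`, `neg`, `alpha`,
#'   `beta` and `sample_rate_hz`. Use `as.data.frame()` to export.
#' @examples
#' s <- gait_signal(c(0, 1, 3, 6, 8, 9, 8, 6, 3, 1, 0, 0))
#' cv <- dgei_curves(s, dgei_params(window_w = 3))
#' head(as.data.frame(cv))
#' @export
dgei_curves <- function(signal, params = dgei_params()) {
  signal <- as_gait_signal(signal)
  stopifnot(inherits(params, "dgei_params"))
  n <- length(signal$values)
  w <- params$window_w
  if (n < w + 1) {
    stop("signal too short: need at least window_w + 1 = ", w + 1, " samples")
  }
  sr <- signal$sample_rate_hz
  d <- first_difference(signal)
  rate <- d * sr
  m <- length(d)

  ind <- dgei_indicator(d, params$bar, params$indicator_mode)

  if (params$alpha_beta_mode == "fixed") {
    alpha <- rep(params$fixed_alpha, m)
  } else {
    alpha <- running_alpha(d, rate, warmup = w,
                           signed_mean = params$rate_mean == "signed")
  }
  beta <- 1 - alpha

  cp <- cumsum_dbl(ifelse(ind$pos == 1L, d, 0))
  cn <- cumsum_dbl(ifelse(ind$neg == 1L, d, 0))
  j <- seq_len(m)
  lag <- j - w - 1L
  s_pos <- cp - ifelse(lag >= 1, cp[pmax(lag, 1)], 0)
  s_neg <- cn - ifelse(lag >= 1, cn[pmax(lag, 1)], 0)
  scale <- alpha + beta * sr
  structure(
    list(frame = j, diff = d, rate = rate,
         pos = scale * s_pos, neg = scale * s_neg,
         alpha = alpha, beta = beta, sample_rate_hz = sr),
    class = "dgei_curves"
  )
}

#' @export
as.data.frame.dgei_curves <- function(x, ...) {
  data.frame(frame = x$frame, diff = x$diff, rate = x$rate,
             pos = x$pos, neg = x$neg, alpha = x$alpha, beta = x$beta)
}

#' @export
print.dgei_curves <- function(x, ...) {
  cat(sprintf("<dgei_curves> %d frames @ %g Hz; pos range [%.3g, %.3g], neg range [%.3g, %.3g]\n",
              length(x$frame), x$sample_rate_hz,
              min(x$pos), max(x$pos), min(x$neg), max(x$neg)))
  invisible(x)
}
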