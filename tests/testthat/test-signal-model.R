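test_that("first difference matches direct subtraction and inverts cumsum", {
  expect_equal(first_difference(c(1, 1, 1, 1)), c(0, 0, 0))
  expect_equal(first_difference(c(0, 2, 5, 3)), c(2, 3, -2))
  d <- c(0.5, -2, 3.25, 0, 7, -1.5)
  expect_equal(first_difference(cumsum(c(10, d))), d)
  expect_error(first_difference(5), "at least 2")
})

test_that("gait_signal validates its inputs", {
  expect_error(gait_signal(c(1, NA, 3)), "finite")
  expect_error(gait_signal(1:10, sample_rate_hz = 0), "positive")
  s <- gait_signal(1:10, sample_rate_hz = 100, start_frame = 5)
  expect_equal(length(s), 10)
  df <- as.data.frame(s)
  expect_equal(df$frame[1], 5)
  expect_equal(df$time_s, df$frame / 100)
})

test_that("indicator branches follow both modes over all sign cases", {
  # positive branch fires iff dy > bar, in either mode
  expect_equal(dgei_indicator(10, 9, "verbatim")$pos, 1L)
  expect_equal(dgei_indicator(0, 0, "symmetric")$pos, 0L)  # strict inequality
  # enumerate sign/mode combinations against the two published rules
  cases <- expand.grid(dy = c(-10, -5, 0, 5, 10), bar = c(0, 9))
  for (i in seq_len(nrow(cases))) {
    dy <- cases$dy[i]; bar <- cases$bar[i]
    sym <- dgei_indicator(dy, bar, "symmetric")
    ver <- dgei_indicator(dy, bar, "verbatim")
    expect_identical(sym$pos, as.integer(dy > bar))
    expect_identical(ver$pos, as.integer(dy > bar))
    expect_identical(sym$neg, as.integer(dy < -bar))
    expect_identical(ver$neg, as.integer(dy <= bar))
  }
})

test_that("adaptive weights are the normalized deviation/rate ratio", {
  # sd = 3 (samples 3,-3,... have sd 3.098 -> use direct construction)
  d <- c(0, 6) # sd = 4.2426...
  r <- c(1, 1)
  w <- adaptive_weights(d, r)
  expect_equal(unname(w["alpha"]), stats::sd(d) / (stats::sd(d) + 1))
  expect_equal(sum(w), 1)
  # symmetry when sd equals the mean rate
  d2 <- c(-2, 2)         # sd = 2.828
  r2 <- rep(stats::sd(d2), 2)
  w2 <- adaptive_weights(d2, r2)
  expect_equal(unname(w2["alpha"]), 0.5)
  # normalization holds across random histories
  set.seed(4)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    w3 <- adaptive_weights(rnorm(n), rnorm(n) * 60)
    expect_equal(sum(w3), 1)
    expect_true(all(w3 >= 0 & w3 <= 1))
  }
  expect_warning(adaptive_weights(c(0, 0), c(0, 0)), "degenerate")
})

test_that("curves match the brute-force double-loop evaluation", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    w <- sample(1:15, 1)
    bar <- runif(1, 0, 4)
    mode <- sample(c("symmetric", "verbatim"), 1)
    v <- cumsum(rnorm(n)) + 15 * sin(seq(0, 8, length.out = n))
    cv <- dgei_curves(gait_signal(v),
                      dgei_params(window_w = w, bar = bar,
                                  indicator_mode = mode))
    o <- brute_force_curves(v, 60, w, bar, mode)
    expect_equal(cv$pos, o$pos, tolerance = 1e-9)
    expect_equal(cv$neg, o$neg, tolerance = 1e-9)
    expect_equal(cv$alpha, o$alpha, tolerance = 1e-12)
  }
})

test_that("constant signals yield identically zero accumulators", {
  v <- rep(7, 50)
  for (mode in c("symmetric", "verbatim")) {
    cv <- dgei_curves(gait_signal(v),
                      dgei_params(window_w = 5, bar = 1,
                                  indicator_mode = mode))
    expect_true(all(cv$pos == 0))
    expect_true(all(cv$neg == 0))
  }
})

test_that("a steady ramp gives the closed-form windowed sum", {
  s <- 2
  v <- s * (0:29)
  cv <- dgei_curves(gait_signal(v),
                    dgei_params(window_w = 3, bar = 0,
                                alpha_beta_mode = "fixed",
                                fixed_alpha = 1, fixed_beta = 0))
  # inclusive window i-w..i holds w + 1 terms of s each once full
  full <- cv$pos[(3 + 1):length(cv$pos)]
  expect_true(all(abs(full - 4 * s) < 1e-12))
  # warm-up frames use the growing partial window
  expect_equal(cv$pos[1:3], s * (1:3))
})

test_that("alpha/beta sum to one and stay within [0, 1] at every frame", {
  set.seed(21)
  for (i in 1:10) {
    v <- cumsum(rnorm(120))
    cv <- dgei_curves(gait_signal(v), dgei_params(window_w = 8))
    expect_true(all(abs(cv$alpha + cv$beta - 1) < 1e-12))
    expect_true(all(cv$alpha >= 0 & cv$alpha <= 1))
  }
})

test_that("fixed-weight curves scale linearly with the signal", {
  set.seed(31)
  v <- cumsum(rnorm(100))
  p <- dgei_params(window_w = 6, bar = 0, alpha_beta_mode = "fixed",
                   fixed_alpha = 0.3, fixed_beta = 0.7)
  c1 <- dgei_curves(gait_signal(v), p)
  c3 <- dgei_curves(gait_signal(3 * v), p)
  expect_equal(c3$pos, 3 * c1$pos, tolerance = 1e-12)
  expect_equal(c3$neg, 3 * c1$neg, tolerance = 1e-12)
})

test_that("at bar 0 the two accumulators partition the full windowed sum", {
  set.seed(41)
  v <- cumsum(rnorm(150))
  w <- 7
  cv <- dgei_curves(gait_signal(v), dgei_params(window_w = w, bar = 0))
  d <- diff(v); rate <- d * 60
  full <- vapply(seq_along(d), function(j) {
    ks <- max(1, j - w):j
    sum(cv$alpha[j] * d[ks] + cv$beta[j] * rate[ks])
  }, 0)
  expect_equal(cv$pos + cv$neg, full, tolerance = 1e-9)
})

test_that("signal shorter than the window is rejected", {
  expect_error(dgei_curves(gait_signal(1:5), dgei_params(window_w = 10)),
               "too short")
})

test_that("the positive curve crests at or before the raw pulse peak", {
  t <- 0:199
  pulse <- 30 * exp(-((t - 100) / 12)^2)
  cv <- dgei_curves(gait_signal(pulse), dgei_params(window_w = 10, bar = 0))
  dt <- (which.max(pulse) - 1) - cv$frame[which.max(cv$pos)]
  expect_gte(dt, 0)
})
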