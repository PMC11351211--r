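small_fixture <- function() {
  generate_scenario(scenario_spec("standard_locomotion", n_cycles = 4,
                                  period_frames = 50, period_jitter = 0,
                                  amplitude_jitter = 0, noise_sd = 0,
                                  seed = 1))
}

test_that("a degenerate 1x1 grid equals a direct detect-and-evaluate call", {
  sc <- small_fixture()
  res <- grid_search(sc, grid_spec(60, 9))
  expect_equal(nrow(res$table), 1)
  ev <- run_detector(sc$signal, config = detector_config(sleeptime0 = 60,
                                                         bar = 9))
  rep <- evaluate_events(ev, sc$truth, length(sc$signal$values))
  expect_equal(res$table$sensitivity_to, rep$TO$sensitivity)
  expect_equal(res$table$mcc_hs, rep$HS$mcc)
})

test_that("the grid enumerates every cell once and argmax rows dominate", {
  sc <- small_fixture()
  res <- grid_search(sc, grid_spec(seq(0, 100, by = 20), c(0, 9, 15)))
  expect_equal(nrow(res$table), 6 * 3)
  expect_equal(nrow(unique(res$table[, c("sleeptime", "bar")])), 18)
  expect_true(all(res$table$sensitivity <= res$argmax$sensitivity$sensitivity))
  expect_true(all(res$table$average_difference >=
                  res$argmax$average_difference$average_difference))
})

test_that("1-D profiles are exact slices that partition the table", {
  sc <- small_fixture()
  grid <- grid_spec(c(0, 50, 100), c(0, 9))
  res <- grid_search(sc, grid)
  sl <- profile_1d(res, "sleeptime", fixed_other = 9)
  expect_equal(nrow(sl), 3)
  expect_equal(sl$sleeptime, c(0, 50, 100))
  stacked <- do.call(rbind, lapply(grid$bar_range, function(b)
    profile_1d(res, "sleeptime", b)))
  expect_equal(nrow(stacked), nrow(res$table))
  expect_setequal(interaction(stacked$sleeptime, stacked$bar),
                  interaction(res$table$sleeptime, res$table$bar))
  expect_error(profile_1d(res, "sleeptime", 7), "not in")
})

test_that("coupling report flags flat and spiked surfaces correctly", {
  mk <- function(m) {
    tab <- expand.grid(sleeptime = as.integer(rownames(m)),
                       bar = as.integer(colnames(m)))
    tab$sensitivity <- as.vector(m)
    tab$detection_rate <- as.vector(m)
    tab$average_difference <- as.vector(m)
    tab$mcc <- as.vector(m)
    structure(list(table = tab,
                   surfaces = list(sensitivity = m, detection_rate = m,
                                   average_difference = m, mcc = m),
                   grid = grid_spec(as.integer(rownames(m)),
                                    as.integer(colnames(m)))),
              class = "grid_result")
  }
  flat <- matrix(5, 3, 4, dimnames = list(0:2, 0:3))
  rep1 <- coupling_report(mk(flat))
  expect_true(all(rep1$max_step_sleeptime == 0))
  expect_true(all(rep1$region_size[rep1$metric == "sensitivity"] == 12))
  spike <- matrix(0, 3, 4, dimnames = list(0:2, 0:3))
  spike[2, 2] <- 10
  rep2 <- coupling_report(mk(spike))
  expect_equal(rep2$region_size[rep2$metric == "sensitivity"], 1)
  expect_equal(rep2$max_step_sleeptime[rep2$metric == "sensitivity"], 10)
})

test_that("smoothness values match a direct neighbour-difference scan", {
  sc <- small_fixture()
  res <- grid_search(sc, grid_spec(c(0, 30, 60), c(0, 9)))
  rep <- coupling_report(res)
  s <- res$surfaces$sensitivity
  expect_equal(rep$max_step_sleeptime[rep$metric == "sensitivity"],
               max(abs(s[-1, ] - s[-nrow(s), ])))
  expect_equal(rep$max_step_bar[rep$metric == "sensitivity"],
               max(abs(s[, -1] - s[, -ncol(s)])))
})

test_that("on steady gait the sensitivity-optimal sleeptime band ends at the period", {
  sc <- clean_walk(15)  # period 60
  prof <- vapply(c(0, 30, 60, 66, 80, 100), function(st0) {
    cfg <- detector_config(sleeptime0 = st0, sleep_floor = st0 / 2)
    r <- evaluate_events(run_detector(sc$signal, config = cfg), sc$truth,
                         length(sc$signal$values))
    mean(c(r$TO$sensitivity, r$HS$sensitivity))
  }, 0)
  names(prof) <- c(0, 30, 60, 66, 80, 100)
  best <- max(prof)
  band <- as.integer(names(prof)[prof == best])
  expect_true(60 %in% band)       # the stride period is in the optimal band
  expect_lte(max(band), 60)       # refractories beyond one stride cost events
})
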