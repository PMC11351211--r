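#' Hyperparameter grid specification
#'
#' The default grid is the one used to tune the detector: *sleeptime*
#' 0..100 and *bar* 0..30, both with step 1 (3131 configurations).
#'
#' @param sleeptime_range Integer vector of sleeptime values to evaluate.
#' @param bar_range Integer vector of bar values to evaluate.
#' @param metrics Metrics to compute per cell; subset of
#'   `c("sensitivity", "average_difference", "mcc")` (detection rate is
#'   always reported too).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(sleeptime_range = 0:100, bar_range = 0:30,
                      metrics = c("sensitivity", "average_difference",
                                  "mcc")) {
  if (length(sleeptime_range) == 0 || length(bar_range) == 0) {
    stop("grid ranges must be non-empty")
  }
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(list(sleeptime_range = as.integer(sleeptime_range),
                 bar_range = as.integer(bar_range), metrics = metrics),
            class = "grid_spec")
}

grid_cell_metrics <- function(annotated, sleeptime, bar, base_config, params,
                              tolerance = 5, sens_tolerance = 3) {
  cfg <- base_config
  cfg$sleeptime0 <- as.integer(sleeptime)
  cfg$sleep_floor <- sleeptime / 2
  cfg$bar <- as.numeric(bar)
  ev <- run_detector(annotated$signal, params, cfg)
  rep <- evaluate_events(ev, annotated$truth,
                         n_frames = length(annotated$signal$values),
                         tolerance = tolerance,
                         sens_tolerance = sens_tolerance)
  row <- data.frame(sleeptime = sleeptime, bar = bar)
  for (type in c("TO", "HS")) {
    r <- rep[[type]]
    row[[paste0("sensitivity_", tolower(type))]] <- r$sensitivity
    row[[paste0("detection_rate_", tolower(type))]] <- r$detection_rate
    row[[paste0("average_difference_", tolower(type))]] <- r$average_difference
    row[[paste0("mcc_", tolower(type))]] <- r$mcc
  }
  row$sensitivity <- mean(c(rep$TO$sensitivity, rep$HS$sensitivity))
  row$detection_rate <- mean(c(rep$TO$detection_rate, rep$HS$detection_rate))
  row$average_difference <- mean(c(rep$TO$average_difference,
                                   rep$HS$average_difference))
  row$mcc <- mean(c(rep$TO$mcc, rep$HS$mcc))
  row
}

#' Exhaustive grid search over sleeptime and bar
#'
#' Runs the detector and evaluation for every (sleeptime, bar) cell of the
#' grid on one annotated input. The per-type metrics and their TO/HS means
#' are tabulated; per-metric argmax rows (minimum for the average
#' difference) and 2-D surfaces are derived from the table. Evaluation of
#' the cells is embarrassingly parallel and order-independent;
#' `cores > 1` uses `parallel::mclapply` with identical results to serial.
#'
#' @param annotated An `annotated_signal` with non-empty gait truth.
#' @param grid A [grid_spec].
#' @param base_config A [detector_config] supplying all non-searched
#'   fields.
#' @param params A [dgei_params].
#' @param cores Number of worker processes (default 1, serial).
#' @return An object of class `grid_result`: list with `table` (one row
#'   per cell), `argmax` (named list of best rows per metric), `surfaces`
#'   (named list of sleeptime x bar matrices) and `grid`.
#' @export
grid_search <- function(annotated, grid = grid_spec(),
                        base_config = detector_config(),
                        params = dgei_params(), cores = 1L) {
  stopifnot(inherits(annotated, "annotated_signal"),
            inherits(grid, "grid_spec"))
  if (!any(annotated$truth$type %in% c("HS", "TO"))) {
    stop("annotated truth must contain at least one gait event")
  }
  cells <- expand.grid(sleeptime = grid$sleeptime_range,
                       bar = grid$bar_range)
  eval_one <- function(i) {
    grid_cell_metrics(annotated, cells$sleeptime[i], cells$bar[i],
                      base_config, params)
  }
  rows <- if (cores > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(cells)), eval_one, mc.cores = cores)
  } else {
    lapply(seq_len(nrow(cells)), eval_one)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  metric_cols <- c("sensitivity", "detection_rate", "average_difference",
                   "mcc")
  surfaces <- lapply(metric_cols, function(mc) {
    m <- matrix(NA_real_, nrow = length(grid$sleeptime_range),
                ncol = length(grid$bar_range),
                dimnames = list(grid$sleeptime_range, grid$bar_range))
    m[cbind(match(table$sleeptime, grid$sleeptime_range),
            match(table$bar, grid$bar_range))] <- table[[mc]]
    m
  })
  names(surfaces) <- metric_cols
  argmax <- lapply(metric_cols, function(mc) {
    v <- table[[mc]]
    idx <- if (mc == "average_difference") which.min(v) else which.max(v)
    table[idx, , drop = FALSE]
  })
  names(argmax) <- metric_cols
  structure(list(table = table, argmax = argmax, surfaces = surfaces,
                 grid = grid),
            class = "grid_result")
}

#' One-dimensional profile of a grid result
#'
#' Slices the grid table along one hyperparameter at a fixed value of the
#' other, e.g. the sensitivity-versus-sleeptime curve at the chosen bar.
#'
#' @param result A `grid_result`.
#' @param axis `"sleeptime"` or `"bar"`: the axis the profile runs along.
#' @param fixed_other Value of the other hyperparameter; must be in the
#'   grid.
#' @return A data frame, one row per value of `axis`.
#' @export
profile_1d <- function(result, axis = c("sleeptime", "bar"), fixed_other) {
  axis <- match.arg(axis)
  stopifnot(inherits(result, "grid_result"))
  other <- if (axis == "sleeptime") "bar" else "sleeptime"
  rng <- if (axis == "sleeptime") result$grid$bar_range
         else result$grid$sleeptime_range
  if (!fixed_other %in% rng) {
    stop("'fixed_other' (", fixed_other, ") is not in the ", other, " range")
  }
  out <- result$table[result$table[[other]] == fixed_other, , drop = FALSE]
  out <- out[order(out[[axis]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Smoothness and optimum-region summary of the grid surfaces
#'
#' Reports, per metric surface, the maximum absolute first difference along
#' each axis (a discontinuity proxy: smooth coupling surfaces have small
#' values) and the size of the connected cell region within 1% of the
#' global optimum (4-neighbour connectivity, grown from the optimum cell).
#'
#' @param result A `grid_result`.
#' @return A data frame with one row per metric: `metric`,
#'   `max_step_sleeptime`, `max_step_bar`, `optimum`, `region_size`.
#' @export
coupling_report <- function(result) {
  stopifnot(inherits(result, "grid_result"))
  rows <- lapply(names(result$surfaces), function(mc) {
    s <- result$surfaces[[mc]]
    step_sleep <- if (nrow(s) > 1) max(abs(diff(s)), na.rm = TRUE) else 0
    step_bar <- if (ncol(s) > 1) max(abs(t(diff(t(s)))), na.rm = TRUE) else 0
    minimize <- mc == "average_difference"
    opt <- if (minimize) min(s) else max(s)
    tol <- 0.01 * abs(opt) + 1e-12
    near <- abs(s - opt) <= tol
    seedc <- which(s == opt, arr.ind = TRUE)[1, ]
    # flood fill over the near-optimal mask from the optimum cell
    visited <- matrix(FALSE, nrow(s), ncol(s))
    stack <- list(seedc)
    while (length(stack)) {
      cc <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      r <- cc[[1]]; cl <- cc[[2]]
      if (r < 1 || cl < 1 || r > nrow(s) || cl > ncol(s)) next
      if (visited[r, cl] || !near[r, cl]) next
      visited[r, cl] <- TRUE
      stack <- c(stack, list(c(r - 1, cl), c(r + 1, cl),
                             c(r, cl - 1), c(r, cl + 1)))
    }
    data.frame(metric = mc, max_step_sleeptime = step_sleep,
               max_step_bar = step_bar, optimum = opt,
               region_size = sum(visited), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
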