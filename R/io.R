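#' Read a gait signal from CSV
#'
#' Expects a header with either a `frame` column (0-based integers) or a
#' `time_s` column (seconds), plus `angle_deg`. Frames must be consecutive;
#' timestamps must be uniform, and the sampling rate is then inferred as
#' the reciprocal of the median step. Non-finite values are rejected with
#' the offending row number.
#'
#' @param path Path to a CSV file.
#' @param default_rate_hz Sampling rate assumed when only `frame` is
#'   present (default 60).
#' @return A [gait_signal].
#' @export
read_gait_signal <- function(path, default_rate_hz = 60) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path)
  if (!"angle_deg" %in% names(df)) {
    stop("missing required column 'angle_deg' in ", path)
  }
  bad <- which(!is.finite(df$angle_deg))
  if (length(bad)) {
    stop("non-finite 'angle_deg' at data row ", bad[1], " of ", path)
  }
  start_frame <- 0L
  if ("time_s" %in% names(df)) {
    if (nrow(df) >= 2) {
      dt <- diff(df$time_s)
      if (any(dt <= 0)) stop("'time_s' must be strictly increasing in ", path)
      med <- stats::median(dt)
      if (any(abs(dt - med) > 1e-6 + 1e-4 * med)) {
        stop("non-uniform sampling in ", path,
             " (first irregular step at row ",
             which(abs(dt - med) > 1e-6 + 1e-4 * med)[1] + 1, ")")
      }
      rate <- 1 / med
    } else {
      rate <- default_rate_hz
    }
    start_frame <- as.integer(round(df$time_s[1] * rate))
  } else if ("frame" %in% names(df)) {
    fr <- df$frame
    if (nrow(df) >= 2 && any(diff(fr) != 1)) {
      stop("'frame' must be consecutive integers in ", path,
           " (first gap after row ", which(diff(fr) != 1)[1], ")")
    }
    rate <- default_rate_hz
    start_frame <- as.integer(fr[1])
  } else {
    stop("need a 'frame' or 'time_s' column in ", path)
  }
  gait_signal(df$angle_deg, sample_rate_hz = rate, start_frame = start_frame)
}

#' Write a gait signal to CSV
#'
#' Columns `frame`, `time_s`, `angle_deg`; lossless round trip with
#' [read_gait_signal()] at full double precision.
#'
#' @param signal A [gait_signal].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gait_signal <- function(signal, path) {
  stopifnot(inherits(signal, "gait_signal"))
  df <- as.data.frame(signal)
  df$time_s <- format(df$time_s, digits = 17, scientific = FALSE,
                      trim = TRUE)
  df$angle_deg <- format(df$angle_deg, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

VALID_EVENT_TYPES <- c("HS", "TO", "WS", "WP")

#' Read gait events from CSV
#'
#' Schema `frame,time_s,type,value,source` (header required); `type` must
#' be one of HS, TO, WS, WP. Extra columns are ignored; an empty file with
#' a header yields an empty event list.
#'
#' @param path Path to a CSV file.
#' @param sample_rate_hz Rate used to recompute `time_s` from `frame`.
#' @return A `gait_events` data frame.
#' @export
read_gait_events <- function(path, sample_rate_hz = 60) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "type", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  }
  bad <- which(!df$type %in% VALID_EVENT_TYPES)
  if (length(bad)) {
    stop("unknown event type '", df$type[bad[1]], "' at data row ", bad[1],
         " of ", path)
  }
  if (!"source" %in% names(df)) df$source <- "unknown"
  gait_events_frame(df$frame, df$type, df$value, df$source,
                    sleep_frames = rep(NA_real_, nrow(df)),
                    sample_rate_hz = sample_rate_hz)
}

#' Write gait events to CSV
#'
#' Writes the public schema `frame,time_s,type,value,source` (internal
#' bookkeeping columns are dropped).
#'
#' @param events A `gait_events` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gait_events <- function(events, path) {
  df <- as.data.frame(events)[, c("frame", "time_s", "type", "value",
                                  "source")]
  df$time_s <- format(df$time_s, digits = 17, scientific = FALSE,
                      trim = TRUE)
  df$value <- format(df$value, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detector configuration file
#'
#' YAML or JSON (by extension) with any subset of the [detector_config()]
#' and [dgei_params()] fields; unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `config` ([detector_config]) and `params`
#'   ([dgei_params]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg_keys <- names(formals(detector_config))
  par_keys <- names(formals(dgei_params))
  unknown <- setdiff(names(raw), c(cfg_keys, par_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config <- do.call(detector_config, raw[intersect(names(raw), cfg_keys)])
  params <- do.call(dgei_params, raw[intersect(names(raw), par_keys)])
  list(config = config, params = params)
}

#' Write a run manifest
#'
#' JSON record sufficient to re-run a command: the command line, a config
#' snapshot, MD5 checksums of the inputs, package version, timestamp and
#' seed.
#'
#' @param path Output path (`.json`).
#' @param command Character description of the command.
#' @param config Config snapshot (any list).
#' @param inputs Character vector of input file paths to checksum.
#' @param seed Seed(s) used, if any.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = NULL,
                               inputs = character(0), seed = NULL) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  manifest <- list(
    command = command,
    config = config,
    input_md5 = sums,
    package = "gaitdgei",
    version = as.character(utils::packageVersion("gaitdgei")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
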