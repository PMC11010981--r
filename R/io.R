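#' Write a session log to CSV + JSON sidecar
#'
#' The per-stimulus record table goes to `<path>` as plain CSV (columns
#' `t_s`, `intensity_ma`, `zscore`, `response`, `valid`, `nwrt_ma`,
#' `method`); everything else — events, executed dosing, suppression-ratio
#' series, subject and protocol parameters, seed, config hash, package
#' version — goes to `<path>.json`. Both files are diffable text.
#'
#' @param log a [session_log][run_session()].
#' @param path output CSV path (the sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  write.csv(log$records, path, row.names = FALSE)
  side <- list(events = as.list(log$events),
               stopped_by = log$stopped_by,
               induction_dose_mg_kg = log$induction_dose_mg_kg,
               dosing = list(boli = log$dosing$boli,
                             infusions = log$dosing$infusions,
                             stop_min = log$dosing$stop_min),
               sr = log$sr,
               subject = unclass(log$subject),
               protocol = unclass(log$protocol),
               seed = log$seed,
               subject_id = attr(log, "subject"),
               day_id = attr(log, "day"),
               config_hash = log$config_hash,
               version = log$version)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path the CSV path (a `<path>.json` sidecar must sit next to it).
#' @return a [session_log][run_session()].
#' @export
read_session_log <- function(path) {
  records <- read.csv(path, stringsAsFactors = FALSE)
  records$method <- as.character(records$method)
  records$response <- as.character(records$response)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dosing <- dosing_schedule(
    boli = as.data.frame(side$dosing$boli),
    infusions = as.data.frame(side$dosing$infusions),
    stop_min = side$dosing$stop_min %||% Inf)
  subject <- do.call(subject_params, side$subject)
  protocol <- do.call(protocol_config, lapply(side$protocol, unlist))
  nwrt <- records[records$valid & !is.na(records$nwrt_ma),
                  c("t_s", "nwrt_ma", "method")]
  rownames(nwrt) <- NULL
  log <- structure(list(records = records, nwrt = nwrt,
                        sr = as.data.frame(side$sr),
                        dosing = dosing,
                        events = unlist(side$events),
                        stopped_by = side$stopped_by,
                        induction_dose_mg_kg = side$induction_dose_mg_kg,
                        subject = subject, protocol = protocol,
                        seed = side$seed, config_hash = side$config_hash,
                        version = side$version),
                   class = "session_log")
  attr(log, "subject") <- side$subject_id
  attr(log, "day") <- side$day_id
  log
}

#' Simulate a test–retest cohort
#'
#' Draws one parameter set per subject (baseline threshold and threshold
#' gain are log-normally dispersed around the defaults; all other
#' parameters are shared), then runs every subject through the full
#' closed-loop protocol once per day with the *same* subject parameters on
#' each day (test–retest design) but a distinct per-session seed derived
#' from `seed`.
#'
#' @param n_subjects number of subjects.
#' @param n_days number of repeated days per subject.
#' @param seed cohort-level seed; per-session seeds are
#'   `(seed + 7919*subject + 104729*day) mod (2^31 - 1)`.
#' @param cfg a [protocol_config()].
#' @param base a [subject_params()] giving the population-typical values.
#' @param sdlog_T0,sdlog_k log-scale standard deviations of the
#'   between-subject spread of `T0` and `k_thr`.
#' @param drop_one if `TRUE`, omit subject 2 / day 1, producing an
#'   incomplete panel (exercises complete-row deletion in the Friedman
#'   tests).
#' @param out_dir if non-`NULL`, each log is also written there as
#'   `subject<i>_day<j>.csv` (+ sidecar).
#' @return a list of session logs, each tagged with attributes `subject`
#'   and `day`.
#' @export
simulate_cohort <- function(n_subjects = 5, n_days = 3, seed = 1,
                            cfg = protocol_config(), base = subject_params(),
                            sdlog_T0 = 0.4, sdlog_k = 0.25,
                            drop_one = FALSE, out_dir = NULL) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  subjects <- lapply(seq_len(n_subjects), function(i) {
    p <- unclass(base)
    ## draws truncated at +-2 sd: keeps every subject's awake threshold
    ## reachable well inside the baseline recording period
    p$T0 <- base$T0 * exp(clamp(rnorm(1, 0, sdlog_T0), -2 * sdlog_T0, 2 * sdlog_T0))
    p$k_thr <- base$k_thr * exp(clamp(rnorm(1, 0, sdlog_k), -2 * sdlog_k, 2 * sdlog_k))
    do.call(subject_params, p)
  })
  logs <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(n_days)) {
      if (drop_one && i == 2L && j == 1L) next
      s_ij <- (seed + 7919 * i + 104729 * j) %% 2147483647
      log <- run_session(subjects[[i]], cfg, seed = s_ij)
      attr(log, "subject") <- i
      attr(log, "day") <- j
      if (!is.null(out_dir))
        write_session_log(log, file.path(out_dir, sprintf("subject%d_day%d.csv", i, j)))
      logs[[length(logs) + 1L]] <- log
    }
  }
  logs
}

#' Read an EMG trace from CSV
#'
#' Expects columns `time_ms` (relative to stimulus onset, uniformly
#' sampled) and `amplitude_uv`.
#'
#' @param path CSV path.
#' @return an [emg_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_ms", "amplitude_uv") %in% names(d)))
    stop(sprintf("%s: expected columns time_ms, amplitude_uv", path))
  dt <- diff(d$time_ms)
  if (max(abs(dt - dt[1])) > 1e-6) stop(sprintf("%s: non-uniform sampling", path))
  emg_trace(d$amplitude_uv, fs = 1000 / dt[1],
            onset_index = which.min(abs(d$time_ms)))
}

#' Read a multi-trace JSON bundle
#'
#' A JSON array of objects with fields `fs`, `onset_index`, `samples` (and
#' optionally `id`).
#'
#' @param path JSON path.
#' @return a named list of [emg_trace()] objects.
#' @export
read_trace_bundle <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  traces <- lapply(raw, function(r) emg_trace(unlist(r$samples), r$fs, r$onset_index))
  names(traces) <- vapply(seq_along(raw), function(i)
    as.character(raw[[i]]$id %||% i), character(1))
  traces
}

#' Score trace files
#'
#' Classifies every trace in the given files (CSV single traces or JSON
#' bundles, decided by extension) and returns one row per trace. Malformed
#' files produce an error row rather than aborting the batch.
#'
#' @param paths character vector of trace files.
#' @param ... detector settings passed to [classify_trace()].
#' @return data.frame with columns `file`, `trace`, `zscore`, `noise_peak`,
#'   `valid`, `response`, `error`.
#' @export
detect_traces <- function(paths, ...) {
  rows <- list()
  for (p in paths) {
    traces <- tryCatch({
      if (grepl("\\.json$", p, ignore.case = TRUE)) read_trace_bundle(p)
      else list(`1` = read_trace_csv(p))
    }, error = function(e) e)
    if (inherits(traces, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        file = p, trace = NA_character_, zscore = NA_real_,
        noise_peak = NA_real_, valid = NA, response = NA_character_,
        error = conditionMessage(traces), stringsAsFactors = FALSE)
      next
    }
    for (nm in names(traces)) {
      d <- classify_trace(traces[[nm]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        file = p, trace = nm, zscore = d$zscore, noise_peak = d$noise_peak,
        valid = d$is_valid, response = d$response, error = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(file = character(), trace = character(),
                      zscore = numeric(), noise_peak = numeric(),
                      valid = logical(), response = character(),
                      error = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Default run configuration as a plain list
#'
#' Subject and protocol settings in one serializable structure, suitable
#' for [write_config()] / [read_config()].
#'
#' @return a list with components `subject` and `protocol`.
#' @export
default_config <- function() {
  list(subject = unclass(subject_params()),
       protocol = unclass(protocol_config()))
}

#' @rdname default_config
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (part in c("subject", "protocol")) {
    if (is.null(cfg[[part]])) stop(sprintf("config is missing the '%s' section", part))
  }
  bad <- setdiff(names(cfg$subject), names(unclass(subject_params())))
  if (length(bad)) stop("unknown subject fields: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$protocol), names(unclass(protocol_config())))
  if (length(bad)) stop("unknown protocol fields: ", paste(bad, collapse = ", "))
  list(subject = do.call(subject_params, cfg$subject),
       protocol = do.call(protocol_config, cfg$protocol))
}

#' Re-analyze a directory of recorded session logs
#'
#' Replay/analysis entry point for deposited or previously simulated data:
#' reads every `*.csv` session log (with JSON sidecar) in `dir` and runs
#' [analyze_sessions()]. Files that do not parse are skipped with a
#' warning; if none parse, an error lists the expected layout.
#'
#' @param dir directory of session-log CSVs.
#' @return a `cohort_analysis` (see [analyze_sessions()]).
#' @export
reproduce_from_deposit <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("\\.json$", files)]
  if (!length(files)) stop("no .csv session logs found in ", dir)
  logs <- list()
  for (f in files) {
    log <- tryCatch(read_session_log(f), error = function(e) e)
    if (inherits(log, "error")) {
      warning(sprintf(
        "%s: %s\n  expected a per-stimulus CSV with columns t_s, intensity_ma, zscore, response, valid, nwrt_ma, method and a .json sidecar with events/dosing/sr",
        f, conditionMessage(log)))
      next
    }
    logs[[length(logs) + 1L]] <- log
  }
  if (!length(logs)) stop("no session log in ", dir, " could be parsed")
  analyze_sessions(logs)
}
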