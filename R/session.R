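#' Protocol configuration
#'
#' Numeric settings of the closed-loop dosing and recording protocol. The
#' defaults encode the reference protocol: recording starts on the awake
#' subject, induction uses a 4–5 mg/kg bolus followed by 0.5–1 mg/kg top-ups
#' every 30–60 s with a parallel 20 mg/kg/h infusion, a 15 min stabilization
#' follows intubation, then the rate rises by 6 mg/kg/h with a 0.5 mg/kg
#' bolus every 10 min until the EEG suppression ratio has stayed within
#' 10–30% for 10 consecutive minutes.
#'
#' @param baseline_min awake recording period before the first bolus, min.
#' @param first_bolus_mg_kg range of the induction bolus, mg/kg.
#' @param topup_mg_kg range of the repeated induction top-up boli, mg/kg.
#' @param topup_interval_s range of the interval between top-ups, s.
#' @param ce_intub effect-site concentration at which intubation is
#'   possible, µg/mL (the intubation condition is modeled as a concentration
#'   threshold; only its timing and dose consequences matter downstream).
#' @param induction_cap_min abort induction if intubation is not reached
#'   within this many minutes.
#' @param infusion_start_mg_kg_h initial infusion rate, mg/kg/h.
#' @param stabilization_min wait after intubation, min.
#' @param increment_mg_kg_h infusion-rate increment, mg/kg/h.
#' @param increment_period_min interval between increments, min.
#' @param increment_bolus_mg_kg bolus accompanying each increment, mg/kg.
#' @param sr_band suppression-ratio target band, percent.
#' @param sr_stable_min minutes the ratio must stay inside the band.
#' @param sr_cadence_min suppression-ratio sampling cadence, min.
#' @param max_escalation_min safety cap on the escalation phase, min.
#' @param stim_period_s nominal inter-stimulus interval, s.
#' @param stim_jitter fractional inter-stimulus randomization.
#' @param start_intensity staircase start intensity, mA.
#' @param step_small,step_big staircase step sizes, mA.
#' @param intensity_floor,intensity_cap staircase intensity limits, mA.
#' @param n_window estimator window length (valid trials).
#' @param noise_window,reflex_window detector windows, ms around onset.
#' @param artifact_uv artifact cutoff, µV.
#' @param z_cut Z-score positivity cutoff.
#' @param fs EMG sampling rate, Hz.
#' @return a list of class `protocol_config`.
#' @export
protocol_config <- function(baseline_min = 10,
                            first_bolus_mg_kg = c(4, 5),
                            topup_mg_kg = c(0.5, 1),
                            topup_interval_s = c(30, 60),
                            ce_intub = 3.4,
                            induction_cap_min = 15,
                            infusion_start_mg_kg_h = 20,
                            stabilization_min = 15,
                            increment_mg_kg_h = 6,
                            increment_period_min = 10,
                            increment_bolus_mg_kg = 0.5,
                            sr_band = c(10, 30),
                            sr_stable_min = 10,
                            sr_cadence_min = 1,
                            max_escalation_min = 150,
                            stim_period_s = 10,
                            stim_jitter = 0.5,
                            start_intensity = 1.0,
                            step_small = 0.3,
                            step_big = 0.5,
                            intensity_floor = 0.3,
                            intensity_cap = 60,
                            n_window = 12,
                            noise_window = c(-130, -10),
                            reflex_window = c(40, 140),
                            artifact_uv = 15,
                            z_cut = 10,
                            fs = 1000) {
  cfg <- as.list(environment())
  structure(cfg, class = "protocol_config")
}

#' Simulate the induction phase
#'
#' Administers the first bolus (drawn uniformly from `first_bolus_mg_kg`)
#' and starts the continuous infusion at the same moment, then repeats
#' top-up boli every `topup_interval_s` until the effect-site concentration
#' reaches `ce_intub`. Uses the current RNG stream.
#'
#' @param params a [subject_params()].
#' @param cfg a [protocol_config()].
#' @param t0_min session time of the first bolus, min.
#' @return a list with `schedule` (the [dosing_schedule()] fragment, still
#'   running), `intubation_min`, and `total_dose_mg_kg` (boli only).
#' @export
run_induction <- function(params, cfg = protocol_config(), t0_min = 0) {
  boli <- data.frame(time_min = t0_min,
                     dose_mg_kg = runif(1, cfg$first_bolus_mg_kg[1], cfg$first_bolus_mg_kg[2]))
  infusions <- data.frame(start_min = t0_min, rate_mg_kg_h = cfg$infusion_start_mg_kg_h)
  sch <- dosing_schedule(boli, infusions, stop_min = Inf)
  t <- t0_min
  if (effect_site(sch, t, params) >= cfg$ce_intub) {
    return(list(schedule = sch, intubation_min = t,
                total_dose_mg_kg = sum(boli$dose_mg_kg)))
  }
  repeat {
    t <- t + runif(1, cfg$topup_interval_s[1], cfg$topup_interval_s[2]) / 60
    if (t - t0_min > cfg$induction_cap_min)
      stop(sprintf("intubation concentration %.2f ug/mL not reached within %g min of induction",
                   cfg$ce_intub, cfg$induction_cap_min))
    if (effect_site(sch, t, params) >= cfg$ce_intub) {
      return(list(schedule = sch, intubation_min = t,
                  total_dose_mg_kg = sum(sch$boli$dose_mg_kg)))
    }
    sch$boli <- rbind(sch$boli,
                      data.frame(time_min = t,
                                 dose_mg_kg = runif(1, cfg$topup_mg_kg[1], cfg$topup_mg_kg[2])))
  }
}

#' Suppression-ratio stop rule
#'
#' Fires at the first sample time at which all samples in the trailing
#' stability window (inclusive of both endpoints; 10 min at a 1/min cadence
#' means 11 samples) lie inside the target band. Any sample outside the
#' band resets the window.
#'
#' @param sr data.frame with columns `t_min`, `sr_pct`, sampled at a fixed
#'   cadence.
#' @param band target band, percent.
#' @param stable_min required stable duration, min.
#' @param cadence_min sampling cadence, min.
#' @param from_min earliest admissible start of the stability window, min.
#' @return the firing time in minutes, or `NA` if the rule never fires.
#' @export
stop_rule <- function(sr, band = c(10, 30), stable_min = 10, cadence_min = 1,
                      from_min = -Inf) {
  need <- as.integer(round(stable_min / cadence_min)) + 1L
  inb <- sr$sr_pct >= band[1] & sr$sr_pct <= band[2]
  run <- 0L
  for (i in seq_along(inb)) {
    run <- if (inb[i]) run + 1L else 0L
    if (run >= need && sr$t_min[i - need + 1L] >= from_min)
      return(sr$t_min[i])
  }
  NA_real_
}

## Build the dosing schedule, SR series and event times for one session.
## Deterministic apart from the induction draws (current RNG stream).
build_protocol <- function(params, cfg) {
  ps <- cfg$baseline_min                       # propofol start, session min
  ind <- run_induction(params, cfg, t0_min = ps)
  intub <- ind$intubation_min
  stab_end <- intub + cfg$stabilization_min

  ## provisional schedule with every increment up to the safety cap; events
  ## later than time t do not influence Ce(t), so the stop time can be
  ## located on the full schedule and the tail truncated afterwards
  inc_times <- seq(stab_end, stab_end + cfg$max_escalation_min,
                   by = cfg$increment_period_min)
  rates <- cfg$infusion_start_mg_kg_h + cfg$increment_mg_kg_h * seq_along(inc_times)
  sch <- ind$schedule
  sch$boli <- rbind(sch$boli,
                    data.frame(time_min = inc_times,
                               dose_mg_kg = cfg$increment_bolus_mg_kg))
  sch$infusions <- rbind(sch$infusions,
                         data.frame(start_min = inc_times, rate_mg_kg_h = rates))

  t_sr <- seq(ps, stab_end + cfg$max_escalation_min, by = cfg$sr_cadence_min)
  sr <- data.frame(t_min = t_sr,
                   sr_pct = suppression_ratio(effect_site(sch, t_sr, params), params))
  fire <- stop_rule(sr, cfg$sr_band, cfg$sr_stable_min, cfg$sr_cadence_min,
                    from_min = stab_end)
  if (is.na(fire)) {
    stopped_by <- "cap"
    infusion_end <- stab_end + cfg$max_escalation_min
    warning("suppression-ratio stop rule never fired; escalation ended by safety cap")
  } else {
    stopped_by <- "sr"
    infusion_end <- fire
  }

  keep <- sch$infusions$start_min < infusion_end
  keep_b <- sch$boli$time_min < infusion_end
  sch <- dosing_schedule(sch$boli[keep_b, ], sch$infusions[keep, ],
                         stop_min = infusion_end)
  sr <- sr[sr$t_min <= infusion_end, , drop = FALSE]

  list(schedule = sch, sr = sr,
       events = c(propofol_start = ps, intubation = intub,
                  stabilization_end = stab_end, infusion_end = infusion_end),
       stopped_by = stopped_by,
       induction_dose_mg_kg = ind$total_dose_mg_kg)
}

## Core stimulus loop: track a time-varying threshold with the staircase,
## the EMG detector and the 12-trial estimator. threshold_fn maps session
## seconds to the true threshold. deterministic = TRUE bypasses the EMG
## stage (response positive iff intensity >= threshold, no artifacts).
track_threshold <- function(threshold_fn, end_s, params, cfg,
                            deterministic = FALSE) {
  st <- staircase_init(cfg$start_intensity, cfg$step_small)
  cap <- max(64L, as.integer(end_s / (cfg$stim_period_s * (1 - cfg$stim_jitter))) + 8L)
  o_t <- numeric(cap); o_int <- numeric(cap); o_z <- numeric(cap)
  o_resp <- character(cap); o_valid <- logical(cap)
  o_nwrt <- numeric(cap); o_meth <- character(cap)
  nv <- 0L
  vi <- numeric(cap); vr <- logical(cap)   # valid intensities / responses
  prev <- NULL
  t <- 0
  i <- 0L
  while (t <= end_s) {
    i <- i + 1L
    thr <- threshold_fn(t)
    if (deterministic) {
      valid <- TRUE
      z <- NA_real_
      pos <- st$intensity >= thr
    } else {
      tr <- generate_trace(st$intensity, thr, params, fs = cfg$fs)
      d <- classify_trace(tr, cfg$noise_window, cfg$reflex_window,
                          cfg$artifact_uv, cfg$z_cut)
      valid <- d$is_valid
      z <- d$zscore
      pos <- identical(d$response, "positive")
    }
    nwrt <- NA_real_; method <- NA_character_
    o_int[i] <- st$intensity
    if (valid) {
      nv <- nv + 1L
      vi[nv] <- st$intensity; vr[nv] <- pos
      if (nv >= cfg$n_window) {
        w <- (nv - cfg$n_window + 1L):nv
        est <- suppressWarnings(
          estimate_nwrt(vi[w], vr[w], previous = prev,
                        n_window = cfg$n_window))
        if (!is.na(est$nwrt)) prev <- est
        nwrt <- est$nwrt; method <- est$method
      }
      st <- staircase_update(st, if (pos) "positive" else "negative",
                             cfg$step_small, cfg$step_big,
                             cfg$intensity_floor, cfg$intensity_cap)
    }
    o_t[i] <- t; o_z[i] <- z; o_valid[i] <- valid
    o_resp[i] <- if (valid) {if (pos) "positive" else "negative"} else "undetermined"
    o_nwrt[i] <- nwrt; o_meth[i] <- method
    t <- next_stimulus_time(t, cfg$stim_period_s, cfg$stim_jitter)
  }
  idx <- seq_len(i)
  data.frame(t_s = o_t[idx], intensity_ma = o_int[idx], zscore = o_z[idx],
             response = o_resp[idx], valid = o_valid[idx],
             nwrt_ma = o_nwrt[idx], method = o_meth[idx],
             stringsAsFactors = FALSE)
}

#' Run one closed-loop session
#'
#' Full simulated protocol on one synthetic subject: awake baseline
#' recording, bolus induction with a parallel infusion, intubation once the
#' effect-site concentration allows it, 15 min stabilization, stepwise dose
#' escalation, and stop once the suppression ratio has been inside the
#' target band for the required time. Stimuli are scheduled by the
#' staircase, traces generated by the subject model, scored by the
#' detector, and the threshold re-estimated after every valid stimulus.
#' All randomness flows from `seed` (a single `set.seed()` at entry; draws
#' are consumed in a fixed order: protocol first, then the stimulus
#' stream), so runs are bit-reproducible.
#'
#' @param params a [subject_params()].
#' @param cfg a [protocol_config()].
#' @param seed integer seed for the session.
#' @return an object of class `session_log`: list with `records`
#'   (per-stimulus data.frame), `nwrt` (estimate series), `sr`
#'   (suppression-ratio series), `dosing` (executed [dosing_schedule()]),
#'   `events` (named minutes: `propofol_start < intubation <
#'   stabilization_end < infusion_end`), `stopped_by`, subject and protocol
#'   parameters, `seed` and `config_hash`.
#' @examples
#' \donttest{
#' log <- run_session(subject_params(), seed = 1)
#' print(log)
#' }
#' @export
run_session <- function(params = subject_params(), cfg = protocol_config(),
                        seed = 1) {
  stopifnot(inherits(params, "subject_params"), inherits(cfg, "protocol_config"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  proto <- build_protocol(params, cfg)
  thr_fn <- function(t_s) true_threshold(effect_site(proto$schedule, t_s / 60, params), params)
  records <- track_threshold(thr_fn, proto$events[["infusion_end"]] * 60,
                             params, cfg, deterministic = FALSE)
  nwrt <- records[records$valid & !is.na(records$nwrt_ma),
                  c("t_s", "nwrt_ma", "method")]
  rownames(nwrt) <- NULL
  structure(list(records = records, nwrt = nwrt, sr = proto$sr,
                 dosing = proto$schedule, events = proto$events,
                 stopped_by = proto$stopped_by,
                 induction_dose_mg_kg = proto$induction_dose_mg_kg,
                 subject = params, protocol = cfg, seed = seed,
                 config_hash = config_hash(list(subject = unclass(params),
                                                protocol = unclass(cfg))),
                 version = as.character(packageVersion("nwrtsim"))),
            class = "session_log")
}

#' Track an arbitrary threshold trajectory
#'
#' Runs only the stimulation/detection/estimation loop (no dosing model)
#' against a user-supplied true-threshold trajectory. Useful for validating
#' the tracking machinery: a constant trajectory with `deterministic =
#' TRUE` is the classical step-threshold oracle subject.
#'
#' @param threshold_fn function mapping session time (s) to the true
#'   threshold (mA), or a single number for a constant threshold.
#' @param duration_s length of the run, s.
#' @param params a [subject_params()] (EMG parameters are used unless
#'   `deterministic`).
#' @param cfg a [protocol_config()].
#' @param seed integer seed.
#' @param deterministic if `TRUE`, the subject responds positive exactly
#'   when `intensity >= threshold`, with no artifacts and no EMG stage.
#' @param n_trials if not `NULL`, run exactly this many stimuli instead of
#'   a fixed duration.
#' @return a list with `records` (as in [run_session()]) and `nwrt`.
#' @export
run_tracking <- function(threshold_fn, duration_s = 600,
                         params = subject_params(), cfg = protocol_config(),
                         seed = 1, deterministic = FALSE, n_trials = NULL) {
  if (is.numeric(threshold_fn)) {
    thr <- threshold_fn
    threshold_fn <- function(t) thr
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  if (!is.null(n_trials)) {
    ## run long enough, then truncate to the requested trial count
    records <- track_threshold(threshold_fn, n_trials * cfg$stim_period_s * 2,
                               params, cfg, deterministic = deterministic)
    records <- head(records, n_trials)
  } else {
    records <- track_threshold(threshold_fn, duration_s, params, cfg,
                               deterministic = deterministic)
  }
  nwrt <- records[records$valid & !is.na(records$nwrt_ma),
                  c("t_s", "nwrt_ma", "method")]
  rownames(nwrt) <- NULL
  list(records = records, nwrt = nwrt)
}

#' @export
print.session_log <- function(x, ...) {
  ev <- x$events
  cat("Closed-loop NWRt session\n")
  cat(sprintf("  %d stimuli (%.1f%% valid), %d threshold estimates\n",
              nrow(x$records), 100 * mean(x$records$valid), nrow(x$nwrt)))
  cat(sprintf("  propofol start %.1f min, intubation %.1f min, stabilization end %.1f min, infusion end %.1f min (stop: %s)\n",
              ev[["propofol_start"]], ev[["intubation"]],
              ev[["stabilization_end"]], ev[["infusion_end"]], x$stopped_by))
  cat(sprintf("  induction dose %.1f mg/kg; final rate %.0f mg/kg/h; seed %d\n",
              x$induction_dose_mg_kg,
              max(x$dosing$infusions$rate_mg_kg_h), x$seed))
  invisible(x)
}

#' Audit a session log against the protocol
#'
#' Re-derives the dosing schedule the protocol demands from the logged
#' event times and checks the executed schedule against it: the infusion
#' rate ladder (start rate plus one increment per period), the increment
#' boli at the period marks, the induction bolus dose ranges and spacing,
#' and — when the session stopped on the suppression-ratio rule — that the
#' trailing stability window lies inside the band and that no earlier
#' window qualified.
#'
#' @param log a [session_log][run_session()].
#' @param tol numeric tolerance for time/dose comparisons.
#' @return a named logical vector of checks, with attribute `ok` (all
#'   passed).
#' @export
audit_session <- function(log, tol = 1e-8) {
  cfg <- log$protocol
  ev <- log$events
  sch <- log$dosing
  inc_times <- seq(ev[["stabilization_end"]], ev[["infusion_end"]] - tol,
                   by = cfg$increment_period_min)
  expected_rates <- cfg$infusion_start_mg_kg_h +
    cfg$increment_mg_kg_h * (0:length(inc_times))
  inf <- sch$infusions
  checks <- c(
    rate_ladder = nrow(inf) == length(inc_times) + 1L &&
      max(abs(inf$rate_mg_kg_h - expected_rates[seq_len(nrow(inf))])) <= tol &&
      abs(inf$start_min[1] - ev[["propofol_start"]]) <= tol &&
      (length(inc_times) == 0 ||
         max(abs(inf$start_min[-1] - inc_times)) <= tol),
    increment_boli = {
      eb <- sch$boli[sch$boli$time_min >= ev[["stabilization_end"]] - tol, ]
      nrow(eb) == length(inc_times) &&
        (nrow(eb) == 0 || (max(abs(eb$time_min - inc_times)) <= tol &&
                             all(abs(eb$dose_mg_kg - cfg$increment_bolus_mg_kg) <= tol)))
    },
    induction_boli = {
      ib <- sch$boli[sch$boli$time_min < ev[["intubation"]] + tol, ]
      nrow(ib) >= 1 &&
        abs(ib$time_min[1] - ev[["propofol_start"]]) <= tol &&
        ib$dose_mg_kg[1] >= cfg$first_bolus_mg_kg[1] - tol &&
        ib$dose_mg_kg[1] <= cfg$first_bolus_mg_kg[2] + tol &&
        (nrow(ib) == 1 ||
           (all(ib$dose_mg_kg[-1] >= cfg$topup_mg_kg[1] - tol) &&
              all(ib$dose_mg_kg[-1] <= cfg$topup_mg_kg[2] + tol) &&
              all(diff(ib$time_min) * 60 >= cfg$topup_interval_s[1] - 1e-6) &&
              all(diff(ib$time_min) * 60 <= cfg$topup_interval_s[2] + 1e-6)))
    },
    stabilization_wait = abs(ev[["stabilization_end"]] - ev[["intubation"]] -
                               cfg$stabilization_min) <= tol,
    infusion_stop = abs(sch$stop_min - ev[["infusion_end"]]) <= tol,
    stop_rule = if (identical(log$stopped_by, "sr")) {
      fire <- stop_rule(log$sr, cfg$sr_band, cfg$sr_stable_min,
                        cfg$sr_cadence_min, from_min = ev[["stabilization_end"]])
      !is.na(fire) && abs(fire - ev[["infusion_end"]]) <= tol
    } else TRUE,
    event_order = ev[["propofol_start"]] < ev[["intubation"]] &&
      ev[["intubation"]] < ev[["stabilization_end"]] &&
      ev[["stabilization_end"]] < ev[["infusion_end"]]
  )
  attr(checks, "ok") <- all(checks)
  checks
}
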