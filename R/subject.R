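#' Synthetic subject parameters
#'
#' Bundles the pharmacokinetic, pharmacodynamic and electromyographic
#' parameters of one synthetic subject. Defaults describe a juvenile pig of
#' about 26 kg with an awake reflex threshold near 7 mA whose threshold
#' rises roughly linearly with the propofol effect-site concentration.
#'
#' @param T0 baseline (awake) reflex threshold, mA.
#' @param k_thr threshold gain per unit effect-site concentration,
#'   mA per µg/mL. `0` gives a drug-insensitive subject.
#' @param beta psychometric slope, 1/mA: steepness of the logistic response
#'   probability around threshold.
#' @param V apparent distribution volume, L/kg.
#' @param ke elimination rate constant, 1/min.
#' @param ke0 effect-site equilibration rate constant, 1/min.
#' @param noise_sd EMG background noise standard deviation, µV.
#' @param reflex_amp evoked reflex burst peak amplitude, µV. Must exceed
#'   `10 * noise_sd` so that true reflexes clear the Z-score criterion.
#' @param p_artifact per-trial probability of injecting a movement artifact
#'   (a >15 µV excursion) into the pre-stimulus noise window.
#' @param sr50 effect-site concentration at which the EEG suppression ratio
#'   reaches 50%, µg/mL.
#' @param sr_slope slope of the suppression-ratio sigmoid, per µg/mL.
#' @param weight body mass, kg (doses are expressed per kg, so
#'   concentrations do not depend on it; recorded for completeness).
#' @return an object of class `subject_params`.
#' @examples
#' p <- subject_params()
#' true_threshold(0, p)  # awake threshold = T0
#' @export
subject_params <- function(T0 = 7.2, k_thr = 4.5, beta = 2, V = 2,
                           ke = 0.085, ke0 = 0.35, noise_sd = 2,
                           reflex_amp = 30, p_artifact = 0.05,
                           sr50 = 7.2, sr_slope = 1.2, weight = 25.8) {
  p <- list(T0 = T0, k_thr = k_thr, beta = beta, V = V, ke = ke, ke0 = ke0,
            noise_sd = noise_sd, reflex_amp = reflex_amp,
            p_artifact = p_artifact, sr50 = sr50, sr_slope = sr_slope,
            weight = weight)
  for (nm in c("T0", "beta", "V", "ke", "ke0", "noise_sd", "reflex_amp", "weight"))
    stop_if_not_scalar(p[[nm]], nm, positive = TRUE)
  stop_if_not_scalar(k_thr, "k_thr"); stop_if_not_scalar(p_artifact, "p_artifact")
  stop_if_not_scalar(sr50, "sr50", positive = TRUE)
  stop_if_not_scalar(sr_slope, "sr_slope", positive = TRUE)
  if (k_thr < 0) stop("k_thr must be >= 0")
  if (p_artifact < 0 || p_artifact >= 0.5) stop("p_artifact must be in [0, 0.5)")
  if (reflex_amp <= 10 * noise_sd)
    stop("reflex_amp must exceed 10 * noise_sd so true reflexes are detectable")
  structure(p, class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat("Synthetic subject:\n")
  cat(sprintf("  threshold: T0 = %.2f mA, gain %.2f mA per ug/mL, slope %.2f /mA\n",
              x$T0, x$k_thr, x$beta))
  cat(sprintf("  kinetics:  V = %.2f L/kg, ke = %.3f /min, ke0 = %.3f /min\n",
              x$V, x$ke, x$ke0))
  cat(sprintf("  EMG: noise sd %.1f uV, burst %.1f uV, artifact p %.2f\n",
              x$noise_sd, x$reflex_amp, x$p_artifact))
  cat(sprintf("  SR sigmoid: sr50 = %.2f ug/mL, slope %.2f\n", x$sr50, x$sr_slope))
  invisible(x)
}

#' Dosing schedule
#'
#' A propofol dosing history: instantaneous IV boli (mg/kg) plus a
#' piecewise-constant infusion (mg/kg/h). Infusion segments are contiguous:
#' each `start_min` switches the running rate, and `stop_min` ends the
#' infusion.
#'
#' @param boli data.frame with columns `time_min`, `dose_mg_kg` (may have
#'   zero rows).
#' @param infusions data.frame with columns `start_min`, `rate_mg_kg_h`
#'   (may have zero rows); starts strictly increasing, rates >= 0.
#' @param stop_min end of the infusion, minutes (`Inf` for a still-running
#'   infusion).
#' @return an object of class `dosing_schedule`.
#' @examples
#' sch <- dosing_schedule(
#'   boli = data.frame(time_min = 0, dose_mg_kg = 4.5),
#'   infusions = data.frame(start_min = 0, rate_mg_kg_h = 20),
#'   stop_min = 60)
#' @export
dosing_schedule <- function(boli = data.frame(time_min = numeric(), dose_mg_kg = numeric()),
                            infusions = data.frame(start_min = numeric(), rate_mg_kg_h = numeric()),
                            stop_min = Inf) {
  boli <- as.data.frame(boli); infusions <- as.data.frame(infusions)
  stopifnot(all(c("time_min", "dose_mg_kg") %in% names(boli)),
            all(c("start_min", "rate_mg_kg_h") %in% names(infusions)))
  if (nrow(boli) && (is.unsorted(boli$time_min) || any(boli$dose_mg_kg < 0)))
    stop("bolus times must be non-decreasing and doses >= 0")
  if (nrow(infusions)) {
    if (any(diff(infusions$start_min) <= 0)) stop("infusion segment starts must be strictly increasing")
    if (any(infusions$rate_mg_kg_h < 0)) stop("infusion rates must be >= 0")
    if (stop_min < max(infusions$start_min)) stop("stop_min precedes the last infusion segment")
  }
  structure(list(boli = boli, infusions = infusions, stop_min = stop_min),
            class = "dosing_schedule")
}

# rate changes as (time, delta rate) pairs, including the stop
rate_deltas <- function(schedule) {
  inf <- schedule$infusions
  if (!nrow(inf)) return(data.frame(time_min = numeric(), delta = numeric()))
  d <- data.frame(time_min = inf$start_min, delta = diff(c(0, inf$rate_mg_kg_h)))
  if (is.finite(schedule$stop_min))
    d <- rbind(d, data.frame(time_min = schedule$stop_min,
                             delta = -inf$rate_mg_kg_h[nrow(inf)]))
  d[d$delta != 0, , drop = FALSE]
}

# effect-site impulse response to a unit (1 mg/kg) bolus at tau >= 0
ce_bolus_unit <- function(tau, V, ke, ke0) {
  out <- numeric(length(tau))
  pos <- tau > 0
  t <- tau[pos]
  if (abs(ke0 - ke) < 1e-9) {
    out[pos] <- (1 / V) * ke * t * exp(-ke * t)
  } else {
    out[pos] <- (1 / V) * ke0 / (ke0 - ke) * (exp(-ke * t) - exp(-ke0 * t))
  }
  out
}

# effect-site step response to a unit rate change (1 mg/kg/h) at tau >= 0
ce_step_unit <- function(tau, V, ke, ke0) {
  out <- numeric(length(tau))
  pos <- tau > 0
  t <- tau[pos]
  css <- 1 / (60 * V * ke)  # mg/kg/h -> ug/mL at steady state
  if (abs(ke0 - ke) < 1e-9) {
    out[pos] <- css * (1 - (1 + ke * t) * exp(-ke * t))
  } else {
    out[pos] <- css * (1 - (ke0 * exp(-ke * t) - ke * exp(-ke0 * t)) / (ke0 - ke))
  }
  out
}

#' Effect-site concentration under a dosing schedule
#'
#' Closed-form solution of a one-compartment model with first-order
#' elimination (`ke`) and a first-order effect site (`ke0`): plasma follows
#' `Cp' = input/V - ke*Cp`, the effect site `Ce' = ke0*(Cp - Ce)`. Because
#' the system is linear, the concentration is the superposition of
#' bolus impulse responses and infusion step responses, evaluated exactly
#' (no numerical integration). With per-kg dosing the body mass cancels.
#'
#' @param schedule a [dosing_schedule()].
#' @param t_min time(s) since the session origin, minutes (vectorized).
#' @param params a [subject_params()].
#' @return effect-site concentration(s), µg/mL; `0` before the first dose.
#' @examples
#' p <- subject_params()
#' sch <- dosing_schedule(infusions = data.frame(start_min = 0, rate_mg_kg_h = 20))
#' effect_site(sch, c(0, 10, 60, 1e4), p)  # approaches 20/(60*V*ke)
#' @export
effect_site <- function(schedule, t_min, params) {
  stopifnot(inherits(schedule, "dosing_schedule"), inherits(params, "subject_params"))
  if (any(t_min < 0)) stop("t_min must be >= 0")
  ce <- numeric(length(t_min))
  b <- schedule$boli
  if (nrow(b)) for (i in seq_len(nrow(b)))
    ce <- ce + b$dose_mg_kg[i] * ce_bolus_unit(t_min - b$time_min[i],
                                               params$V, params$ke, params$ke0)
  d <- rate_deltas(schedule)
  if (nrow(d)) for (i in seq_len(nrow(d)))
    ce <- ce + d$delta[i] * ce_step_unit(t_min - d$time_min[i],
                                         params$V, params$ke, params$ke0)
  pmax(ce, 0)
}

#' True reflex threshold at a given effect-site concentration
#'
#' Linear link `T = T0 + k_thr * Ce`: the simplest monotone dose–effect
#' relationship consistent with a threshold that rises steadily with
#' anesthetic depth. A ceiling (Emax-type) variant can be emulated by
#' passing a pre-saturated `ce`.
#'
#' @param ce effect-site concentration(s), µg/mL (>= 0).
#' @param params a [subject_params()].
#' @return threshold(s), mA.
#' @export
true_threshold <- function(ce, params) {
  stopifnot(inherits(params, "subject_params"))
  if (any(ce < 0)) stop("ce must be >= 0")
  params$T0 + params$k_thr * ce
}

#' Probability of a positive reflex response
#'
#' Logistic psychometric function
#' `p = 1 / (1 + exp(-beta * (intensity - threshold)))`; exactly 0.5 at
#' `intensity == threshold` and strictly increasing in intensity.
#'
#' @param intensity stimulation intensity, mA (>= 0).
#' @param threshold current true threshold, mA.
#' @param beta psychometric slope, 1/mA.
#' @return response probability in \[0, 1\].
#' @export
response_probability <- function(intensity, threshold, beta) {
  if (any(intensity < 0)) stop("intensity must be >= 0")
  stats::plogis(beta * (intensity - threshold))
}

#' EEG suppression ratio at a given effect-site concentration
#'
#' Sigmoid summary readout
#' `SR = 100 / (1 + exp(-sr_slope * (ce - sr50)))`, in percent. No EEG
#' waveform is synthesized; the suppression ratio is generated directly as
#' the monitor's summary number.
#'
#' @inheritParams true_threshold
#' @return suppression ratio(s), percent in \[0, 100\].
#' @export
suppression_ratio <- function(ce, params) {
  stopifnot(inherits(params, "subject_params"))
  if (any(ce < 0)) stop("ce must be >= 0")
  100 * stats::plogis(params$sr_slope * (ce - params$sr50))
}

#' Construct a stimulus-locked EMG trace object
#'
#' @param samples amplitude series, µV.
#' @param fs sampling rate, Hz (>= 1000 so 1 ms pulses are resolved).
#' @param onset_index sample index (1-based) of stimulus onset.
#' @return an object of class `emg_trace`.
#' @export
emg_trace <- function(samples, fs, onset_index) {
  stopifnot(is.numeric(samples), length(samples) > 1)
  stop_if_not_scalar(fs, "fs", positive = TRUE)
  if (fs < 1000) stop("fs must be >= 1000 Hz")
  stop_if_not_scalar(onset_index, "onset_index")
  if (onset_index < 1 || onset_index > length(samples)) stop("onset_index out of range")
  structure(list(samples = as.numeric(samples), fs = fs,
                 onset_index = as.integer(onset_index)),
            class = "emg_trace")
}

#' Sample times of a trace, ms relative to stimulus onset
#' @param trace an [emg_trace()].
#' @return numeric vector of times in ms.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$samples) - trace$onset_index) * 1000 / trace$fs
}

#' Generate one stimulus-locked synthetic EMG trace
#'
#' Background is zero-mean Gaussian noise (`noise_sd`). With probability
#' [response_probability()] a reflex burst is added strictly inside the
#' 40–140 ms post-onset reflex window: a 20 ms half-sine envelope modulating
#' Gaussian noise, rescaled so its absolute peak equals `reflex_amp`, at a
#' latency drawn uniformly in 50–120 ms. With probability `p_artifact` a
#' rectangular 20 µV, 10 ms excursion is injected into the pre-stimulus
#' noise window so the 15 µV artifact rule fires. Draws come from the
#' current R RNG stream; seed upstream for reproducibility.
#'
#' @param intensity stimulation intensity, mA.
#' @param threshold current true threshold, mA.
#' @param params a [subject_params()].
#' @param fs sampling rate, Hz.
#' @param span_ms time span around onset, ms (must cover \[-130, 140\]).
#' @return an [emg_trace()] with attributes `burst` and `artifact` (logical,
#'   ground truth of what was injected).
#' @export
generate_trace <- function(intensity, threshold, params, fs = 1000,
                           span_ms = c(-150, 150)) {
  stopifnot(inherits(params, "subject_params"))
  if (span_ms[1] > -130 || span_ms[2] < 140)
    stop("span_ms must cover [-130, 140] ms")
  dt <- 1000 / fs
  t_ms <- seq(span_ms[1], span_ms[2], by = dt)
  onset_index <- which.min(abs(t_ms))
  t_ms <- (seq_along(t_ms) - onset_index) * dt
  x <- rnorm(length(t_ms), 0, params$noise_sd)

  p <- response_probability(intensity, threshold, params$beta)
  burst <- runif(1) < p
  if (burst) {
    lat <- runif(1, 50, 120)           # burst peak latency, ms
    lo <- lat - 10; hi <- lat + 10     # support inside [40, 130] ms
    idx <- which(t_ms >= lo & t_ms <= hi)
    env <- sin(pi * (t_ms[idx] - lo) / (hi - lo))
    raw <- env * rnorm(length(idx))
    m <- max(abs(raw))
    if (m > 0) x[idx] <- x[idx] + raw * (params$reflex_amp / m)
  }

  artifact <- runif(1) < params$p_artifact
  if (artifact) {
    start <- runif(1, -130, -30)       # 10 ms excursion stays in [-130, -10)
    idx <- which(t_ms >= start & t_ms < start + 10)
    x[idx] <- x[idx] + 20
  }

  tr <- emg_trace(x, fs, onset_index)
  attr(tr, "burst") <- burst
  attr(tr, "artifact") <- artifact
  tr
}
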