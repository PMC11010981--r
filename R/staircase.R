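#' Initial bracketing-staircase state
#'
#' The controller starts at 1 mA with a 0.3 mA step and no change history.
#'
#' @param intensity starting stimulation intensity, mA.
#' @param step base step size, mA.
#' @return an object of class `staircase_state` with fields `intensity`,
#'   `step`, `recent_changes` (directions of up to the last 3 intensity
#'   changes, +1 up / -1 down).
#' @export
staircase_init <- function(intensity = 1.0, step = 0.3) {
  stop_if_not_scalar(intensity, "intensity", positive = TRUE)
  stop_if_not_scalar(step, "step", positive = TRUE)
  structure(list(intensity = intensity, step = step, recent_changes = integer()),
            class = "staircase_state")
}

#' Advance the bracketing staircase after a valid trial
#'
#' A negative (no-reflex) response raises the intensity by the current step;
#' a positive response lowers it. The step is the base 0.3 mA, enlarged to
#' 0.5 mA for the first change after the last three recorded changes all ran
#' in the pending change's direction (and for as long as the run continues);
#' any reversal falls back to the base step. The intensity is clamped to
#' `[floor, cap]`. Artifact (invalid) trials must not be fed to this
#' function: the stimulus is simply repeated at the same intensity.
#'
#' @param state a `staircase_state`.
#' @param response `"positive"` or `"negative"` (from a valid trial only).
#' @param step_small base step, mA.
#' @param step_big escalated step, mA.
#' @param floor minimum intensity, mA (currents at or below zero are
#'   physically meaningless; one base step above zero by default).
#' @param cap maximum intensity, mA (safety cap; the tracked thresholds stay
#'   far below it in practice).
#' @return the updated `staircase_state`.
#' @examples
#' s <- staircase_init()
#' s <- staircase_update(s, "negative")  # 1.0 -> 1.3 mA
#' s$intensity
#' @export
staircase_update <- function(state, response, step_small = 0.3, step_big = 0.5,
                             floor = 0.3, cap = 60) {
  stopifnot(inherits(state, "staircase_state"))
  if (!is.character(response) || length(response) != 1L ||
      !response %in% c("positive", "negative"))
    stop("response must be \"positive\" or \"negative\"")
  dir <- if (response == "negative") 1L else -1L
  rc <- state$recent_changes
  step <- if (length(rc) == 3L && all(rc == dir)) step_big else step_small
  state$intensity <- clamp(state$intensity + dir * step, floor, cap)
  state$step <- step
  state$recent_changes <- tail(c(rc, dir), 3L)
  state
}

#' Schedule the next stimulus time
#'
#' Stimuli repeat nominally every 10 s with 50% interval randomization,
#' interpreted as a uniform draw on `[5, 15]` s.
#'
#' @param t_now current time, s.
#' @param period_s nominal inter-stimulus interval, s.
#' @param jitter fractional randomization (0.5 = ±50%).
#' @return the next stimulus time, s.
#' @export
next_stimulus_time <- function(t_now, period_s = 10, jitter = 0.5) {
  if (t_now < 0) stop("t_now must be >= 0")
  t_now + runif(1, period_s * (1 - jitter), period_s * (1 + jitter))
}

#' Default stimulus train description
#'
#' Five rectangular 1 ms pulses at 200 Hz; the train is treated as a single
#' stimulation event of the given intensity (its internal structure does not
#' enter the simulation).
#'
#' @param intensity stimulation intensity, mA.
#' @return a list with `n_pulses`, `pulse_width_ms`, `pulse_rate_hz`,
#'   `intensity`.
#' @export
stimulus_train <- function(intensity) {
  list(n_pulses = 5L, pulse_width_ms = 1, pulse_rate_hz = 200,
       intensity = intensity)
}
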