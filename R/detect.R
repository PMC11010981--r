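## Reflex scoring. Window convention: half-open [lo, hi) in ms relative to
## stimulus onset; noise window [-130, -10), reflex window [40, 140). A
## sample at exactly +40 ms is included, one at exactly +140 ms is not.

window_idx <- function(trace, lo, hi) {
  t <- trace_times(trace)
  if (min(t) > lo || max(t) < hi - 1000 / trace$fs)
    stop(sprintf("trace does not cover the [%g, %g) ms window", lo, hi))
  which(t >= lo & t < hi)
}

#' Pre-stimulus noise-window statistics
#'
#' Mean, standard deviation and absolute peak of the samples in the noise
#' window (default 130 to 10 ms before stimulus onset).
#'
#' @param trace an [emg_trace()].
#' @param noise_window half-open window `[lo, hi)`, ms relative to onset.
#' @return a list with `mean`, `sd`, `peak` (all µV); `peak` is the maximum
#'   absolute amplitude.
#' @export
noise_stats <- function(trace, noise_window = c(-130, -10)) {
  x <- trace$samples[window_idx(trace, noise_window[1], noise_window[2])]
  list(mean = mean(x), sd = sd(x), peak = max(abs(x)))
}

#' Artifact check on the noise window
#'
#' A trial is an artifact when the EMG amplitude strictly exceeds
#' `artifact_uv` (default 15 µV, on the raw absolute amplitude) anywhere in
#' the noise window; such trials are discarded and the stimulus repeated at
#' the same intensity. A peak of exactly 15.0 µV is not an artifact.
#'
#' @inheritParams noise_stats
#' @param artifact_uv rejection cutoff, µV.
#' @return logical flag.
#' @export
is_artifact <- function(trace, noise_window = c(-130, -10), artifact_uv = 15) {
  noise_stats(trace, noise_window)$peak > artifact_uv
}

#' Interval peak Z-score of the reflex window
#'
#' The peak amplitude in the reflex window (default 40–140 ms after onset),
#' measured as the maximum absolute deviation from the noise-window mean, in
#' units of the noise-window standard deviation:
#' `z = max(|x - noise_mean|) / noise_sd`. Measuring deviation from the
#' noise mean makes the score exactly invariant to a constant offset and to
#' rescaling of the whole trace.
#'
#' @inheritParams noise_stats
#' @param reflex_window half-open reflex window `[lo, hi)`, ms after onset.
#' @return the Z-score, or `NA` if the noise sd is zero (degenerate trace).
#' @export
peak_zscore <- function(trace, noise_window = c(-130, -10),
                        reflex_window = c(40, 140)) {
  ns <- noise_stats(trace, noise_window)
  x <- trace$samples[window_idx(trace, reflex_window[1], reflex_window[2])]
  if (!is.finite(ns$sd) || ns$sd <= 0) return(NA_real_)
  max(abs(x - ns$mean)) / ns$sd
}

#' Classify one trial
#'
#' Applies the artifact rule, then the interval peak Z-score criterion: the
#' reflex is positive when `z > z_cut` (strictly; default 10). Artifact
#' trials — and degenerate traces whose noise window has zero variance —
#' are invalid, and their response is `"undetermined"`.
#'
#' @inheritParams peak_zscore
#' @param artifact_uv artifact cutoff on the noise-window absolute peak, µV.
#' @param z_cut positivity cutoff on the Z-score.
#' @return an object of class `detection_result`: list with `zscore`,
#'   `noise_peak`, `is_valid`, `response` (`"positive"`, `"negative"` or
#'   `"undetermined"`).
#' @examples
#' set.seed(1)
#' tr <- generate_trace(20, 10, subject_params())
#' classify_trace(tr)
#' @export
classify_trace <- function(trace, noise_window = c(-130, -10),
                           reflex_window = c(40, 140), artifact_uv = 15,
                           z_cut = 10) {
  ns <- noise_stats(trace, noise_window)
  if (ns$peak > artifact_uv || !is.finite(ns$sd) || ns$sd <= 0) {
    return(structure(list(zscore = NA_real_, noise_peak = ns$peak,
                          is_valid = FALSE, response = "undetermined"),
                     class = "detection_result"))
  }
  z <- peak_zscore(trace, noise_window, reflex_window)
  structure(list(zscore = z, noise_peak = ns$peak, is_valid = TRUE,
                 response = if (z > z_cut) "positive" else "negative"),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("EMG trial: %s (valid = %s, z = %s, noise peak = %.2f uV)\n",
              x$response, x$is_valid,
              if (is.na(x$zscore)) "NA" else sprintf("%.2f", x$zscore),
              x$noise_peak))
  invisible(x)
}
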