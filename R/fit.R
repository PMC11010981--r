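#' Construct a threshold estimate
#' @param nwrt estimated threshold, mA (may be `NA`).
#' @param slope fitted logistic slope, 1/mA (may be `NA`).
#' @param n_used number of valid trials in the window.
#' @param method one of `"ml"`, `"separable_midpoint"`, `"carry_forward"`.
#' @return an object of class `threshold_estimate`.
#' @export
threshold_estimate <- function(nwrt, slope, n_used, method) {
  stopifnot(method %in% c("ml", "separable_midpoint", "carry_forward"))
  structure(list(nwrt = nwrt, slope = slope, n_used = as.integer(n_used),
                 method = method),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("NWRt = %s mA (method %s, n = %d)\n",
              if (is.na(x$nwrt)) "NA" else sprintf("%.3f", x$nwrt),
              x$method, x$n_used))
  invisible(x)
}

carry_forward <- function(previous, n) {
  if (is.null(previous))
    threshold_estimate(NA_real_, NA_real_, n, "carry_forward")
  else
    threshold_estimate(previous$nwrt, previous$slope, n, "carry_forward")
}

#' Estimate the NWR threshold from the last 12 valid stimuli
#'
#' Fits `P(positive | intensity) = plogis(a + b * intensity)` by maximum
#' likelihood and reads the threshold off at the 50% point, `-a/b`. The
#' 12-trial windows produced by a bracketing staircase are small and often
#' perfectly separated, so two documented fallbacks apply:
#'
#' * perfect separation (every negative below every positive): the
#'   likelihood has no finite maximizer; the threshold is the midpoint
#'   between the highest negative and the lowest positive intensity
#'   (`method = "separable_midpoint"`).
#' * all responses identical, or a non-increasing fit (`b <= 0`): the
#'   window carries no crossing information; the previous estimate is
#'   returned flagged `"carry_forward"`.
#'
#' The `method` flag is propagated into session logs so downstream analyses
#' can filter by it.
#'
#' @param intensity intensities of exactly `n_window` valid trials, mA.
#' @param response logical (or `"positive"`/`"negative"`) responses.
#' @param previous the previous [threshold_estimate()], or `NULL`.
#' @param n_window required window length (12 by default).
#' @return a [threshold_estimate()].
#' @examples
#' estimate_nwrt(c(rep(1, 6), rep(2, 6)),
#'               c(rep(FALSE, 6), rep(TRUE, 6)))  # 1.5 mA, separable
#' @export
estimate_nwrt <- function(intensity, response, previous = NULL, n_window = 12) {
  if (is.character(response)) response <- response == "positive"
  stopifnot(is.logical(response), length(intensity) == length(response))
  if (length(intensity) != n_window)
    stop(sprintf("estimate_nwrt needs exactly %d valid trials (got %d)",
                 n_window, length(intensity)))
  if (any(intensity <= 0)) stop("intensities must be > 0")

  if (all(response) || all(!response)) return(carry_forward(previous, n_window))

  hi_neg <- max(intensity[!response])
  lo_pos <- min(intensity[response])
  if (hi_neg < lo_pos) {
    return(threshold_estimate((hi_neg + lo_pos) / 2, NA_real_, n_window,
                              "separable_midpoint"))
  }
  if (max(intensity[response]) < min(intensity[!response])) {
    warning("responses decrease with intensity; carrying previous estimate forward")
    return(carry_forward(previous, n_window))
  }

  fit <- suppressWarnings(glm.fit(cbind(1, intensity), as.numeric(response),
                                  family = binomial()))
  a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
  if (!fit$converged || !is.finite(b) || b <= 0) {
    warning("non-increasing logistic fit; carrying previous estimate forward")
    return(carry_forward(previous, n_window))
  }
  nwrt <- -a / b
  if (nwrt < min(intensity) || nwrt > max(intensity)) {
    ## a near-flat fit can put the 50% point far outside the sampled range;
    ## such a window carries no usable crossing information
    warning("50% point outside the fitted window; carrying previous estimate forward")
    return(carry_forward(previous, n_window))
  }
  threshold_estimate(nwrt, b, n_window, "ml")
}

#' Threshold time series over an ordered stimulus record
#'
#' Replays the estimator over a session: after every valid stimulus, once 12
#' valid records exist, the last 12 are refit and the estimate is stamped
#' with the triggering stimulus time. Invalid (artifact) trials never
#' trigger re-estimation. The first 11 valid trials are the warm-up period
#' and produce no output.
#'
#' @param records data.frame with columns `t_s`, `intensity_ma`, `response`
#'   (`"positive"`/`"negative"`), `valid` (logical), time-ordered.
#' @param n_window estimator window length.
#' @return data.frame with columns `t_s`, `nwrt_ma`, `slope`, `method`; zero
#'   rows during warm-up.
#' @export
nwrt_series <- function(records, n_window = 12) {
  stopifnot(all(c("t_s", "intensity_ma", "response", "valid") %in% names(records)))
  if (is.unsorted(records$t_s)) stop("records must be time-ordered")
  v <- records[records$valid, , drop = FALSE]
  out <- vector("list", max(0, nrow(v) - n_window + 1))
  prev <- NULL
  k <- 0L
  for (i in seq_len(nrow(v))) {
    if (i < n_window) next
    w <- v[(i - n_window + 1):i, ]
    est <- estimate_nwrt(w$intensity_ma, w$response, previous = prev,
                         n_window = n_window)
    if (!is.na(est$nwrt)) prev <- est
    k <- k + 1L
    out[[k]] <- data.frame(t_s = v$t_s[i], nwrt_ma = est$nwrt,
                           slope = est$slope, method = est$method,
                           stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(t_s = numeric(), nwrt_ma = numeric(), slope = numeric(),
                      method = character(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}
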