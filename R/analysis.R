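#' Baseline NWR threshold of a session
#'
#' Arithmetic mean of the threshold estimates falling in the window from 5
#' to 4 minutes before the start of propofol administration (half-open,
#' `[-5, -4)` min relative to the first bolus).
#'
#' @param log a [session_log][run_session()].
#' @param window baseline window, minutes relative to propofol start.
#' @return baseline threshold, mA.
#' @export
baseline_nwrt <- function(log, window = c(-5, -4)) {
  ps <- log$events[["propofol_start"]]
  t_min <- log$nwrt$t_s / 60 - ps
  x <- log$nwrt$nwrt_ma[t_min >= window[1] & t_min < window[2]]
  if (!length(x)) stop("no threshold estimates in the baseline window")
  mean(x)
}

#' Mean NWR threshold during the induction-to-intubation phase
#'
#' Aggregates the threshold estimates recorded between the first propofol
#' bolus and intubation. Reported alongside the baseline and TI rows of the
#' cohort table; the mean (rather than the peak) over the phase is a
#' documented convention.
#'
#' @param log a [session_log][run_session()].
#' @return mean threshold during induction, mA (`NA` if no estimates fall
#'   in the phase).
#' @export
intubation_nwrt <- function(log) {
  ps <- log$events[["propofol_start"]]; iu <- log$events[["intubation"]]
  t_min <- log$nwrt$t_s / 60
  x <- log$nwrt$nwrt_ma[t_min >= ps & t_min < iu]
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' Bin a session into five equal time intervals
#'
#' The span from the end of the stabilization period (15 min after
#' intubation) to the end of the propofol infusion is divided into five
#' equal intervals (TI1–TI5), normalizing sessions of different duration to
#' comparable anesthetic-depth stages. The mean threshold estimate is
#' computed per interval. Bins are half-open `[lo, hi)` with the last bin
#' closed, so the partition is disjoint and exhaustive.
#'
#' @param log a [session_log][run_session()].
#' @param n_bins number of intervals.
#' @return an object of class `ti_summary`: list with `ti_means` (mA, `NA`
#'   where a bin holds no estimate), `bounds` (min, length `n_bins + 1`),
#'   `n_points` per bin, and `ti_length_min`.
#' @export
bin_ti <- function(log, n_bins = 5) {
  ev <- log$events
  lo <- ev[["stabilization_end"]]; hi <- ev[["infusion_end"]]
  if (!(lo < hi)) stop("stabilization_end must precede infusion_end")
  bounds <- seq(lo, hi, length.out = n_bins + 1)
  t_min <- log$nwrt$t_s / 60
  means <- numeric(n_bins); npts <- integer(n_bins)
  for (i in seq_len(n_bins)) {
    inb <- t_min >= bounds[i] &
      (if (i == n_bins) t_min <= bounds[i + 1] else t_min < bounds[i + 1])
    npts[i] <- sum(inb)
    means[i] <- if (npts[i]) mean(log$nwrt$nwrt_ma[inb]) else NA_real_
  }
  if (anyNA(means)) warning("empty time interval(s): mean undefined")
  structure(list(ti_means = means, bounds = bounds, n_points = npts,
                 ti_length_min = (hi - lo) / n_bins),
            class = "ti_summary")
}

#' Per-session linear trend of threshold over time interval
#'
#' Ordinary least squares of the per-interval mean thresholds on the
#' interval index 1..5. The slope `b1` (mA per TI) is the session's
#' dose-dependence summary.
#'
#' @param s a [ti_summary][bin_ti()], or a numeric vector of TI means.
#' @return a list of class `regression_result` with `b0` (intercept, mA),
#'   `b1` (slope, mA/TI), `r2` (`NA` when the means are constant).
#' @export
fit_linear <- function(s) {
  y <- if (inherits(s, "ti_summary")) s$ti_means else as.numeric(s)
  x <- seq_along(y)
  ok <- !is.na(y)
  if (sum(ok) < 2) stop("need at least 2 defined TI means")
  fit <- lm(y[ok] ~ x[ok])
  r2 <- if (var(y[ok]) > 0) summary(fit)$r.squared else NA_real_
  structure(list(b0 = unname(coef(fit)[1]), b1 = unname(coef(fit)[2]), r2 = r2),
            class = "regression_result")
}

#' Relative threshold increase over baseline
#'
#' @param s a [ti_summary][bin_ti()] or numeric vector of TI means, mA.
#' @param baseline baseline threshold, mA (> 0).
#' @return a list with `fold` (ti_mean / baseline) and `pct_change`
#'   (100 * (fold - 1)).
#' @export
relative_increase <- function(s, baseline) {
  y <- if (inherits(s, "ti_summary")) s$ti_means else as.numeric(s)
  if (!is.numeric(baseline) || baseline <= 0) stop("baseline must be > 0")
  fold <- y / baseline
  list(fold = fold, pct_change = 100 * (fold - 1))
}

friedman_numerator <- function(col_rank_sums, n, k) {
  sum((col_rank_sums - n * (k + 1) / 2)^2)
}

#' Friedman repeated-measures rank test
#'
#' Within-subject ranks across `k` repeated conditions; the tie-corrected
#' statistic
#' `12 * sum_j (R_j - n(k+1)/2)^2 / (n k (k+1) - sum(t^3 - t)/(k-1))`
#' is referred to a chi-square distribution with `k - 1` degrees of
#' freedom. Because repeated-measures panels in this design are tiny (4–6
#' subjects), an exact permutation p-value — the proportion of all
#' `(k!)^n` within-subject orderings with a statistic at least as large —
#' is also computed when feasible. Rows containing missing values are
#' dropped with a warning (complete-row deletion is the only missing-data
#' policy). If every row is completely tied the statistic is 0 and p = 1.
#'
#' @param x numeric matrix, subjects in rows, conditions (e.g. days) in
#'   columns.
#' @param exact compute the exact permutation p-value (`NA` entries in the
#'   result when disabled or infeasible).
#' @param max_perm feasibility cap on `(k!)^n` for the exact enumeration.
#' @return an object of class `friedman_result`: `statistic`, `df`,
#'   `p_chisq`, `p_exact`, `n` (complete rows used), `k`.
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
#' friedman_rm(m)
#' @export
friedman_rm <- function(x, exact = TRUE, max_perm = 2e5) {
  x <- as.matrix(x)
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    warning(sprintf("dropping %d incomplete row(s)", sum(!complete)))
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 1 || k < 2) stop("need at least 1 complete row and 2 conditions")
  R <- t(apply(x, 1, rank))
  ties <- sum(apply(x, 1, function(row) {
    tb <- table(row); sum(tb^3 - tb)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  if (denom <= 0) {
    res <- list(statistic = 0, df = k - 1, p_chisq = 1, p_exact = 1, n = n, k = k)
    return(structure(res, class = "friedman_result"))
  }
  num_obs <- friedman_numerator(colSums(R), n, k)
  statistic <- 12 * num_obs / denom
  p_chisq <- pchisq(statistic, df = k - 1, lower.tail = FALSE)

  p_exact <- NA_real_
  n_perm <- factorial(k)^n
  if (exact && n_perm <= max_perm) {
    perms <- all_permutations(k)           # k! x k index matrix
    ## per-row matrix of rank vectors under every within-row ordering
    rowperm <- lapply(seq_len(n), function(i) {
      matrix(R[i, ][t(perms)], ncol = k, byrow = TRUE)
    })
    grid <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), n))
    cs <- matrix(0, nrow(grid), k)
    for (i in seq_len(n)) cs <- cs + rowperm[[i]][grid[[i]], , drop = FALSE]
    nums <- rowSums((cs - n * (k + 1) / 2)^2)
    p_exact <- mean(nums >= num_obs - 1e-9)
  }
  structure(list(statistic = statistic, df = k - 1, p_chisq = p_chisq,
                 p_exact = p_exact, n = n, k = k),
            class = "friedman_result")
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi2(%d) = %.3f, p = %.4f (chi-square)",
              x$df, x$statistic, x$p_chisq))
  if (!is.na(x$p_exact)) cat(sprintf(", p = %.4f (exact, %d subjects)", x$p_exact, x$n))
  cat("\n")
  invisible(x)
}

#' Per-session analysis results
#'
#' Runs the full per-session pipeline over a list of session logs:
#' baseline, induction-phase mean, TI means, linear trend.
#'
#' @param logs list of [session_log][run_session()] objects (optionally
#'   named); each may carry attributes `subject` and `day` (integers) used
#'   to label rows, else logs are numbered.
#' @return data.frame with one row per session: `subject`, `day`,
#'   `baseline_ma`, `ti1_ma`..`ti5_ma`, `intubation_ma`, `b0`, `b1`, `r2`,
#'   `duration_min` (stabilization end to infusion end),
#'   `ti_length_min`, `induction_dose_mg_kg`.
#' @export
session_results <- function(logs) {
  rows <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    ts <- bin_ti(log)
    reg <- fit_linear(ts)
    data.frame(subject = attr(log, "subject") %||% i,
               day = attr(log, "day") %||% 1L,
               baseline_ma = baseline_nwrt(log),
               ti1_ma = ts$ti_means[1], ti2_ma = ts$ti_means[2],
               ti3_ma = ts$ti_means[3], ti4_ma = ts$ti_means[4],
               ti5_ma = ts$ti_means[5],
               intubation_ma = intubation_nwrt(log),
               b0 = reg$b0, b1 = reg$b1, r2 = reg$r2,
               duration_min = unname(log$events[["infusion_end"]] -
                                       log$events[["stabilization_end"]]),
               ti_length_min = ts$ti_length_min,
               induction_dose_mg_kg = log$induction_dose_mg_kg %||% NA_real_)
  })
  do.call(rbind, rows)
}

#' Cohort summary table
#'
#' Median and interquartile range (25th, 75th percentile, linear
#' interpolation between order statistics) of the threshold across
#' sessions, one row per phase: Baseline, TI1–TI5, Intubation.
#'
#' @param results a data.frame from [session_results()].
#' @return data.frame with columns `phase`, `median_ma`, `q25_ma`,
#'   `q75_ma`, `n`.
#' @export
cohort_table <- function(results) {
  cols <- c(Baseline = "baseline_ma", TI1 = "ti1_ma", TI2 = "ti2_ma",
            TI3 = "ti3_ma", TI4 = "ti4_ma", TI5 = "ti5_ma",
            Intubation = "intubation_ma")
  rows <- lapply(names(cols), function(ph) {
    x <- results[[cols[[ph]]]]
    x <- x[!is.na(x)]
    data.frame(phase = ph,
               median_ma = median(x),
               q25_ma = unname(quantile(x, 0.25, type = 7)),
               q75_ma = unname(quantile(x, 0.75, type = 7)),
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full cohort analysis
#'
#' Per-session results, the cohort median/IQR table, per-TI relative
#' increase over the cohort baseline median, and Friedman tests comparing
#' the baseline threshold and the regression slope `b1` across days
#' (subjects with missing days are dropped from the test with a warning).
#'
#' @param logs list of session logs (from [run_session()],
#'   [simulate_cohort()] or [read_session_log()]).
#' @return a list of class `cohort_analysis` with `results`, `summary`,
#'   `relative_increase`, `friedman_baseline`, `friedman_b1` (the Friedman
#'   entries are `NULL` when fewer than 2 days are present).
#' @export
analyze_sessions <- function(logs) {
  results <- session_results(logs)
  summ <- cohort_table(results)
  base_med <- summ$median_ma[summ$phase == "Baseline"]
  rel <- relative_increase(summ$median_ma[summ$phase %in% paste0("TI", 1:5)],
                           base_med)
  fr_base <- fr_b1 <- NULL
  days <- sort(unique(results$day))
  if (length(days) >= 2) {
    to_mat <- function(col) {
      subj <- sort(unique(results$subject))
      m <- matrix(NA_real_, length(subj), length(days),
                  dimnames = list(subj, days))
      for (r in seq_len(nrow(results)))
        m[as.character(results$subject[r]), as.character(results$day[r])] <-
          results[[col]][r]
      m
    }
    fr_base <- friedman_rm(to_mat("baseline_ma"))
    fr_b1 <- friedman_rm(to_mat("b1"))
  }
  structure(list(results = results, summary = summ, relative_increase = rel,
                 friedman_baseline = fr_base, friedman_b1 = fr_b1),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis of %d sessions\n", nrow(x$results)))
  print(x$summary, row.names = FALSE)
  cat(sprintf("mean b1 = %.2f +/- %.2f mA per TI\n",
              mean(x$results$b1), sd(x$results$b1)))
  if (!is.null(x$friedman_baseline)) {
    cat("baseline across days: "); print(x$friedman_baseline)
    cat("b1 across days:       "); print(x$friedman_b1)
  }
  invisible(x)
}
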