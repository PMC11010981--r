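# minimal in-memory session log for analysis-level tests
fake_log <- function(t_min, nwrt, events) {
  list(nwrt = data.frame(t_s = t_min * 60, nwrt_ma = nwrt,
                         method = "ml", stringsAsFactors = FALSE),
       events = events)
}

ev0 <- c(propofol_start = 10, intubation = 16, stabilization_end = 31,
         infusion_end = 81)

test_that("the baseline is the mean over the [-5, -4) min window", {
  # constant series
  log <- fake_log(seq(0, 9.8, by = 0.2), rep(7, 50), ev0)
  expect_equal(baseline_nwrt(log), 7)
  # only points inside the window count; the right edge is open
  log <- fake_log(c(4.0, 5.2, 5.8, 6.0, 6.5), c(99, 6, 8, 42, 17), ev0)
  expect_equal(baseline_nwrt(log), 7)
  log_empty <- fake_log(c(1, 2, 8), c(5, 5, 5), ev0)
  expect_error(baseline_nwrt(log_empty), "baseline")
})

test_that("TI binning divides the span into five equal half-open intervals", {
  log <- fake_log(seq(31, 81, by = 0.5), rep(10, 101), ev0)
  ts <- bin_ti(log)
  expect_equal(ts$bounds, seq(31, 81, by = 10))
  expect_equal(ts$ti_length_min, 10)
  # 72 min span: interval length 14.4 min
  ev72 <- ev0; ev72[["infusion_end"]] <- 31 + 72
  expect_equal(bin_ti(fake_log(c(40, 60, 90), rep(1, 3), ev72))$ti_length_min, 14.4)
  # hand-computed bin means over bounds 31,41,51,61,71,81: internal bounds
  # belong to the right-hand bin, the final bound to the last bin
  log <- fake_log(c(31, 40.9, 41, 55, 61, 70.9, 71, 80, 81),
                  c(1, 2, 10, 20, 30, 30, 40, 40, 100), ev0)
  ts <- bin_ti(log)
  expect_equal(ts$ti_means, c((1 + 2) / 2, 10, 20, (30 + 30) / 2,
                              (40 + 40 + 100) / 3))
  expect_equal(ts$n_points, c(2L, 1L, 1L, 2L, 3L))
  expect_equal(sum(ts$n_points), 9)  # every point lands in exactly one bin
})

test_that("TI binning flags empty intervals", {
  log <- fake_log(c(32, 45), c(5, 6), ev0)
  expect_warning(ts <- bin_ti(log), "empty")
  expect_true(anyNA(ts$ti_means))
})

test_that("per-session trends follow ordinary least squares", {
  expect_equal(fit_linear(c(10, 15, 20, 25, 30))$b1, 5)
  expect_equal(fit_linear(c(10, 15, 20, 25, 30))$r2, 1)
  expect_equal(fit_linear(rep(4, 5))$b1, 0)
  set.seed(51)
  for (i in 1:20) {
    y <- runif(5, 5, 30)
    x <- 1:5
    # closed-form normal equations
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b0 <- mean(y) - b1 * mean(x)
    fit <- fit_linear(y)
    expect_equal(fit$b1, b1, tolerance = 1e-10)
    expect_equal(fit$b0, b0, tolerance = 1e-10)
  }
  expect_error(fit_linear(c(3, NA, NA, NA, NA)), "at least 2")
})

test_that("relative increase is the ratio to baseline", {
  expect_equal(relative_increase(c(7, 7, 7, 7, 7), 7)$fold, rep(1, 5))
  expect_equal(relative_increase(25, 10)$fold, 2.5)
  expect_equal(relative_increase(29.4, 7.2)$fold, 29.4 / 7.2, tolerance = 1e-12)
  expect_equal(relative_increase(25, 10)$pct_change, 150)
  expect_error(relative_increase(c(1, 2), 0), "> 0")
})

test_that("the Friedman statistic matches the reference implementation", {
  set.seed(52)
  for (i in 1:10) {
    m <- matrix(runif(12), 4, 3)
    if (i > 5) m[sample(12, 2)] <- m[1, 1]  # inject ties
    got <- friedman_rm(m, exact = FALSE)
    want <- stats::friedman.test(m)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p_chisq, unname(want$p.value), tolerance = 1e-12)
  }
})

test_that("degenerate and single-subject panels behave as documented", {
  m <- matrix(5, 4, 3)  # identical values everywhere
  got <- friedman_rm(m)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_chisq, 1)
  expect_equal(got$p_exact, 1)
  # one subject, monotone values: statistic 2 for k = 3; every ordering of
  # a single untied row gives the same statistic, so the exact p is 1
  got1 <- friedman_rm(matrix(c(1, 5, 9), 1, 3))
  expect_equal(got1$statistic, 2)
  expect_equal(got1$p_exact, 1)
})

test_that("incomplete subjects are dropped before testing", {
  m <- rbind(c(1, 2, 3), c(NA, 1, 2), c(3, 1, 2), c(2, 3, 1), c(1, 3, 2))
  expect_warning(got <- friedman_rm(m), "incomplete")
  expect_equal(got$n, 4)
})

test_that("exact permutation p agrees with the chi-square approximation loosely", {
  # with 5 subjects and 3 conditions the chi-square reference is only a
  # rough guide: individual matrices can differ by up to ~0.1 in p, which
  # is exactly why the exact permutation p is reported alongside it
  set.seed(53)
  d <- t(replicate(25, {
    m <- matrix(runif(15), 5, 3)
    f <- friedman_rm(m)
    c(exact = f$p_exact, chisq = f$p_chisq)
  }))
  diffs <- abs(d[, "exact"] - d[, "chisq"])
  expect_lt(max(diffs), 0.15)
  # in the decision-relevant range the two references agree closely,
  # and they never disagree about significance at the 5% level
  expect_lt(max(diffs[d[, "exact"] < 0.2]), 0.05)
  expect_equal(d[, "exact"] < 0.05, d[, "chisq"] < 0.05)
})

test_that("cohort summaries use interpolated quartiles over sessions", {
  res <- data.frame(subject = 1:3, day = 1,
                    baseline_ma = c(5, 7, 9),
                    ti1_ma = c(10, 11, 15), ti2_ma = c(12, 13, 14),
                    ti3_ma = c(15, 14, 16), ti4_ma = c(18, 17, 20),
                    ti5_ma = c(20, 25, 30), intubation_ma = c(9, 10, 11),
                    b0 = 0, b1 = c(2, 3, 4), r2 = 1,
                    duration_min = 50, ti_length_min = 10,
                    induction_dose_mg_kg = 12)
  tab <- cohort_table(res)
  expect_equal(tab$phase, c("Baseline", paste0("TI", 1:5), "Intubation"))
  expect_equal(tab$median_ma[tab$phase == "Baseline"], 7)
  # sort-based oracle for the quartiles of TI5 = (20, 25, 30)
  x <- sort(c(20, 25, 30))
  expect_equal(tab$q25_ma[tab$phase == "TI5"], x[1] + 0.5 * (x[2] - x[1]))
  expect_equal(tab$q75_ma[tab$phase == "TI5"], x[2] + 0.5 * (x[3] - x[2]))
  # a single session is its own summary
  tab1 <- cohort_table(res[2, ])
  expect_equal(tab1$median_ma[tab1$phase == "TI3"], 14)
  expect_equal(tab1$q25_ma, tab1$q75_ma)
})

test_that("slope recovery: tracked ramps regress back to the true slope", {
  set.seed(54)
  b1s <- sapply(1:6, function(i) {
    # constant awake threshold for 10 min, then +5 mA per 10-min interval
    thr <- function(t_s) 7.2 + 5 * pmin(pmax((t_s - 600) / 600, 0), 5)
    res <- run_tracking(thr, duration_s = 3600, seed = 540 + i)
    log <- list(nwrt = res$nwrt,
                events = c(propofol_start = 0, intubation = 0,
                           stabilization_end = 10, infusion_end = 60))
    fit_linear(bin_ti(log))$b1
  })
  expect_lt(abs(mean(b1s) - 5), 0.5)
})
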