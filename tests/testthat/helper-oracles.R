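# Independent oracles used across the suite. These deliberately share no
# code with the package: explicit loops, naive formulas, brute-force
# enumeration.

# Brute-force trial classifier: loops over samples, two-pass noise
# statistics, absolute-deviation peak, strict cutoffs.
oracle_classify <- function(samples, fs, onset_index,
                            artifact_uv = 15, z_cut = 10) {
  n <- length(samples)
  noise_sum <- 0; noise_n <- 0L; noise_peak <- 0
  for (i in seq_len(n)) {
    t_ms <- (i - onset_index) * 1000 / fs
    if (t_ms >= -130 && t_ms < -10) {
      noise_sum <- noise_sum + samples[i]
      noise_n <- noise_n + 1L
      a <- abs(samples[i])
      if (a > noise_peak) noise_peak <- a
    }
  }
  noise_mean <- noise_sum / noise_n
  ss <- 0
  for (i in seq_len(n)) {
    t_ms <- (i - onset_index) * 1000 / fs
    if (t_ms >= -130 && t_ms < -10) ss <- ss + (samples[i] - noise_mean)^2
  }
  noise_sd <- sqrt(ss / (noise_n - 1))
  if (noise_peak > artifact_uv || !(noise_sd > 0)) {
    return(list(is_valid = FALSE, response = "undetermined", zscore = NA_real_))
  }
  peak_dev <- 0
  for (i in seq_len(n)) {
    t_ms <- (i - onset_index) * 1000 / fs
    if (t_ms >= 40 && t_ms < 140) {
      d <- abs(samples[i] - noise_mean)
      if (d > peak_dev) peak_dev <- d
    }
  }
  z <- peak_dev / noise_sd
  list(is_valid = TRUE,
       response = if (z > z_cut) "positive" else "negative",
       zscore = z)
}

# Bernoulli log-likelihood of a logistic psychometric function
oracle_loglik <- function(intensity, response, thr, beta) {
  p <- 1 / (1 + exp(-beta * (intensity - thr)))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(ifelse(response, log(p), log(1 - p)))
}

# Coarse grid-search maximizer of the likelihood over (threshold, slope),
# refined once around the best threshold.
oracle_grid_nwrt <- function(intensity, response,
                             betas = exp(seq(log(0.2), log(30), length.out = 60))) {
  ts <- seq(min(intensity), max(intensity), by = 0.05)
  best <- c(t = NA_real_, ll = -Inf)
  for (b in betas) {
    for (tt in ts) {
      ll <- oracle_loglik(intensity, response, tt, b)
      if (ll > best["ll"]) best <- c(t = tt, ll = ll)
    }
  }
  fine <- seq(best[["t"]] - 0.06, best[["t"]] + 0.06, by = 0.005)
  for (b in betas) {
    for (tt in fine) {
      ll <- oracle_loglik(intensity, response, tt, b)
      if (ll > best["ll"]) best <- c(t = tt, ll = ll)
    }
  }
  best[["t"]]
}

# All permutations of 1..k as a (k!) x k matrix (plain recursion).
oracle_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1)))
  }))
}

# Exact permutation p-value for the Friedman statistic, using
# stats::friedman.test as the statistic engine on every one of the (k!)^n
# within-row rearrangements.
oracle_friedman_exact <- function(x) {
  n <- nrow(x); k <- ncol(x)
  obs <- unname(stats::friedman.test(x)$statistic)
  perms <- oracle_perms(k)
  idx <- do.call(expand.grid, rep(list(seq_len(nrow(perms))), n))
  stats_all <- apply(idx, 1, function(row) {
    y <- x
    for (i in seq_len(n)) y[i, ] <- x[i, perms[row[i], ]]
    unname(stats::friedman.test(y)$statistic)
  })
  mean(stats_all >= obs - 1e-9)
}

# A small standard trace grid shared by fixtures (not by the package code).
flat_trace <- function(value = 0, fs = 1000) {
  n <- 301L
  emg_trace(rep(value, n), fs = fs, onset_index = 151L)
}

# Trace with chosen samples written at given times (ms) on a zero baseline
# plus optional noise.
trace_with <- function(at_ms, values, base = NULL, fs = 1000) {
  tr <- if (is.null(base)) flat_trace(fs = fs) else base
  t_ms <- trace_times(tr)
  for (j in seq_along(at_ms)) {
    i <- which.min(abs(t_ms - at_ms[j]))
    tr$samples[i] <- values[j]
  }
  tr
}
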