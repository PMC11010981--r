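test_that("subject parameter invariants are enforced", {
  expect_s3_class(subject_params(), "subject_params")
  expect_error(subject_params(T0 = -1), "T0")
  expect_error(subject_params(k_thr = -0.1), "k_thr")
  expect_error(subject_params(p_artifact = 0.6), "p_artifact")
  expect_error(subject_params(reflex_amp = 15, noise_sd = 2), "detectable")
})

test_that("effect site is zero with no dosing and rejects negative times", {
  p <- subject_params()
  empty <- dosing_schedule()
  expect_equal(effect_site(empty, c(0, 5, 500), p), c(0, 0, 0))
  expect_error(effect_site(empty, -1, p), ">= 0")
})

test_that("constant infusion approaches the closed-form steady state", {
  p <- subject_params()
  sch <- dosing_schedule(infusions = data.frame(start_min = 0, rate_mg_kg_h = 20))
  css <- 20 / (60 * p$V * p$ke)
  expect_equal(effect_site(sch, 1e4, p), css, tolerance = 1e-8)
  # monotone approach from below
  ce <- effect_site(sch, seq(0, 200, by = 1), p)
  expect_true(all(diff(ce) > 0))
  expect_true(all(ce <= css))
})

test_that("closed-form concentrations match numerical ODE integration", {
  skip_if_not_installed("deSolve")
  p <- subject_params()
  sch <- dosing_schedule(
    boli = data.frame(time_min = c(0, 1, 2.2), dose_mg_kg = c(4.5, 0.8, 0.6)),
    infusions = data.frame(start_min = c(0, 20, 30), rate_mg_kg_h = c(20, 26, 32)),
    stop_min = 45)
  rate_at <- function(t) {
    if (t < 0 || t >= 45) return(0)
    if (t >= 30) return(32)
    if (t >= 20) return(26)
    20
  }
  # deSolve with bolus events on the plasma compartment
  deriv <- function(t, y, parms) {
    list(c(rate_at(t) / (60 * p$V) - p$ke * y[1],
           p$ke0 * (y[1] - y[2])))
  }
  ev <- data.frame(var = "Cp", time = c(0, 1, 2.2),
                   value = c(4.5, 0.8, 0.6) / p$V, method = "add")
  times <- sort(unique(c(seq(0, 60, by = 0.25), 1, 2.2, 20, 30, 45)))
  sol <- deSolve::lsoda(c(Cp = 0, Ce = 0), times, deriv, NULL,
                        events = list(data = ev), rtol = 1e-10, atol = 1e-10)
  ce_ode <- sol[, "Ce"]
  ce_cf <- effect_site(sch, times, p)
  expect_lt(max(abs(ce_ode - ce_cf)), 1e-5)
})

test_that("effect site is linear in dose", {
  p <- subject_params()
  sch1 <- dosing_schedule(
    boli = data.frame(time_min = c(0, 2), dose_mg_kg = c(4, 0.5)),
    infusions = data.frame(start_min = c(0, 15), rate_mg_kg_h = c(20, 26)),
    stop_min = 40)
  sch2 <- dosing_schedule(
    boli = data.frame(time_min = c(0, 2), dose_mg_kg = 2 * c(4, 0.5)),
    infusions = data.frame(start_min = c(0, 15), rate_mg_kg_h = 2 * c(20, 26)),
    stop_min = 40)
  tt <- seq(0, 80, by = 0.5)
  expect_equal(effect_site(sch2, tt, p), 2 * effect_site(sch1, tt, p),
               tolerance = 1e-12)
})

test_that("a single bolus gives a unimodal effect-site curve", {
  p <- subject_params()
  sch <- dosing_schedule(boli = data.frame(time_min = 0, dose_mg_kg = 4))
  ce <- effect_site(sch, seq(0.01, 120, by = 0.01), p)
  d <- diff(ce)
  expect_equal(sum(diff(sign(d)) != 0), 1)  # rises to one peak, then decays
  expect_true(ce[length(ce)] < max(ce) / 5)
})

test_that("threshold link is linear and monotone in concentration", {
  p <- subject_params(T0 = 7, k_thr = 2)
  expect_equal(true_threshold(0, p), 7)
  expect_equal(true_threshold(3, p), 13)
  expect_equal(true_threshold(0:10, subject_params(k_thr = 0)),
               rep(subject_params()$T0, 11))
  grid <- seq(0, 12, by = 0.1)
  expect_true(all(diff(true_threshold(grid, p)) >= 0))
  expect_error(true_threshold(-1, p), ">= 0")
})

test_that("psychometric function has the logistic form", {
  expect_equal(response_probability(10, 10, 2), 0.5)
  expect_equal(response_probability(11, 10, 2), 1 / (1 + exp(-2)))
  # steep slope approaches a step at threshold
  expect_lt(response_probability(9.9, 10, 1e4), 1e-10)
  expect_gt(response_probability(10.1, 10, 1e4), 1 - 1e-10)
  x <- seq(0, 20, by = 0.1)
  expect_true(all(diff(response_probability(x, 10, 2)) > 0))
})

test_that("suppression ratio follows its sigmoid and stays in [0, 100]", {
  p <- subject_params(sr50 = 5, sr_slope = 1)
  expect_equal(suppression_ratio(5, p), 50)
  expect_equal(suppression_ratio(7, p), 100 / (1 + exp(-2)))
  expect_lt(suppression_ratio(0, subject_params()), 1)  # awake: SR ~ 0
  grid <- seq(0, 15, by = 0.1)
  sr <- suppression_ratio(grid, p)
  expect_true(all(diff(sr) >= 0) && all(sr >= 0) && all(sr <= 100))
})

test_that("trace generation is reproducible and windows are respected", {
  p <- subject_params()
  set.seed(42); tr1 <- generate_trace(10, 7, p)
  set.seed(42); tr2 <- generate_trace(10, 7, p)
  expect_identical(tr1, tr2)
  expect_lte(min(trace_times(tr1)), -130)
  expect_gte(max(trace_times(tr1)), 140)
  # forced artifact: every trace is rejected
  pa <- subject_params(p_artifact = 0.49)
  set.seed(1)
  res <- replicate(200, {
    ok <- FALSE
    tr <- generate_trace(10, 7, pa)
    if (attr(tr, "artifact")) ok <- !classify_trace(tr)$is_valid else ok <- TRUE
    ok
  })
  expect_true(all(res))
  # far below threshold with a steep slope: never a burst, classified negative
  set.seed(2)
  p0 <- subject_params(beta = 50, p_artifact = 0)
  neg <- replicate(100, classify_trace(generate_trace(1, 20, p0))$response)
  expect_true(all(neg == "negative"))
})

test_that("classification rate converges to the psychometric probability", {
  p <- subject_params(p_artifact = 0)
  for (case in list(list(i = 10, t = 10, want = 0.5),
                    list(i = 11, t = 10, want = response_probability(11, 10, 2)))) {
    set.seed(7)
    n <- 2000
    pos <- replicate(n, classify_trace(generate_trace(case$i, case$t, p))$response == "positive")
    ci <- 3 * sqrt(case$want * (1 - case$want) / n)
    expect_lt(abs(mean(pos) - case$want), ci + 0.005)
  }
})
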