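test_that("log-log regression recovers exact power laws", {
  tt <- c(0.01, 0.02, 0.03, 0.05, 0.08)
  f <- suppressWarnings(fit_loglog_exponent(tt, 0.3 * tt^3))
  expect_equal(f$exponent_n, 3, tolerance = 1e-10)
  expect_equal(f$prefactor_A, 0.3, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # multiplying all means by a constant (extrinsic-noise prefactor) shifts
  # only the intercept
  f2 <- suppressWarnings(fit_loglog_exponent(tt, 7.3 * 0.3 * tt^3))
  expect_equal(f2$exponent_n, f$exponent_n, tolerance = 1e-10)
  expect_error(fit_loglog_exponent(tt, c(0, 1, 2, 3, 4)), "delayed")
  expect_error(fit_loglog_exponent(tt[1:2], c(1, 2)), "3 points")
})

test_that("the delayed power-law fit recovers noiseless parameters to 1e-6", {
  set.seed(61)
  for (i in 1:20) {
    truth <- c(A = stats::runif(1, 0.05, 2), t0 = stats::runif(1, 0.5, 8),
               n = stats::runif(1, 1.2, 4.5), m0 = stats::runif(1, 0, 1))
    tt <- seq(1, 30, length.out = 10)
    y <- delayed_power_law(tt, truth["A"], truth["t0"], truth["n"],
                           truth["m0"])
    fit <- suppressWarnings(fit_delayed_power_law(tt, y))
    est <- c(fit$prefactor_A, fit$delay_t0, fit$exponent_n, fit$baseline_m0)
    expect_lt(max(abs(est - truth) / pmax(truth, 1e-3)), 1e-6)
  }
})

test_that("ignoring a real delay inflates the exponent estimate", {
  tt <- seq(1, 30, length.out = 10)
  y <- delayed_power_law(tt, A = 0.5, t0 = 6, n = 2, m0 = 0)
  delayed <- suppressWarnings(fit_delayed_power_law(tt, y))
  no_delay <- fit_loglog_exponent(tt[y > 0], y[y > 0])
  expect_equal(delayed$exponent_n, 2, tolerance = 1e-6)
  expect_gt(no_delay$exponent_n, delayed$exponent_n + 0.5)
})

test_that("a fitted zero delay is flagged as non-physical", {
  tt <- seq(1, 20, length.out = 8)
  expect_warning(fit_delayed_power_law(tt, 0.2 * tt^2.5), "zero delay")
})

test_that("linear and non-linear fitters agree on zero-delay zero-baseline data", {
  # exact power laws, integer and fractional exponents
  tt <- seq(0.2, 1, length.out = 6)
  for (n in c(2, 3.4)) {
    lin <- fit_loglog_exponent(tt, 0.7 * tt^n)
    nl <- suppressWarnings(fit_delayed_power_law(tt, 0.7 * tt^n))
    expect_lt(abs(lin$exponent_n - nl$exponent_n), 1e-4)
  }
  # mild multiplicative noise leaves the two estimators in agreement
  set.seed(65)
  y <- 0.7 * tt^2.5 * exp(stats::rnorm(length(tt), 0, 0.01))
  lin <- fit_loglog_exponent(tt, y)
  nl <- suppressWarnings(fit_delayed_power_law(tt, y))
  expect_lt(abs(lin$exponent_n - nl$exponent_n), 0.05)
})

test_that("point selection keeps the power-law prefix and drops the plateau", {
  p <- nstate_params(3, c(5, 5, 2), rho = 50, d = 1)
  tt <- c(0.02 * (1:5), 0.5, 1, 2, 4, 8)
  tr <- integrate_moment_odes(p, 1, tt)
  idx <- select_fit_points(tt, tr$mean, method = "loglog_linear")
  expect_lt(max(idx), length(tt))
  plateau <- tr$mean[length(tt)]
  expect_lt(tr$mean[max(idx)], 0.5 * plateau)
  # exactly power-law data keeps every point
  idx_all <- select_fit_points(tt, 0.3 * tt^3, method = "loglog_linear")
  expect_equal(idx_all, seq_along(tt))
  # five points are the identity selection
  expect_equal(select_fit_points(tt[1:5], tr$mean[1:5],
                                 method = "loglog_linear"), 1:5)
  expect_warning(sel <- select_fit_points(tt[1:4], tr$mean[1:4],
                                          method = "loglog_linear"),
                 "using all")
  expect_equal(sel, 1:4)
})

test_that("a single-replicate bootstrap of singleton cohorts returns the point fit", {
  # with one cell per time point, resampling with replacement reproduces the
  # original cohort exactly
  tt <- seq(1, 9, by = 2)
  counts <- round(delayed_power_law(tt, 2, 2, 2, 1))
  ds <- data.frame(cell_id = seq_along(tt), time = tt, count = counts)
  class(ds) <- c("induction_dataset", class(ds))
  br <- bootstrap_exponent(ds, n_replicates = 1, seed = 1, use_sems = FALSE)
  expect_equal(br$samples, br$point_estimate$exponent_n, tolerance = 1e-8)
})

test_that("bootstrap medians track the full-data estimate for large cohorts", {
  p <- nstate_params(5, c(25, 25, 25, 25, 1), rho = 300, d = 1)
  ds <- ssa_simulate(p, 4, n_cells = 2000, times = 0.02 * (1:5), seed = 301)
  br <- bootstrap_exponent(ds, n_replicates = 200, seed = 5,
                           method = "loglog_linear")
  expect_equal(br$n_failed, 0)
  expect_lt(abs(br$median - br$point_estimate$exponent_n), 0.05)
  expect_true(br$ci[1] <= br$median && br$median <= br$ci[2])
  expect_true(br$median >= min(br$samples) && br$median <= max(br$samples))
})

test_that("the inferred exponent is practically independent of capture efficiency", {
  p <- nstate_params(5, c(25, 25, 25, 25, 1), rho = 300, d = 1)
  meds <- lapply(c(0.05, 0.2, 0.8), function(cp) {
    ds <- ssa_simulate(p, 4, n_cells = 1000, times = 0.02 * (1:5),
                       capture_p = cp, seed = 400 + round(100 * cp))
    bootstrap_exponent(ds, n_replicates = 100, seed = 9,
                       method = "loglog_linear")
  })
  # bootstrap intervals for all capture efficiencies overlap
  lo <- max(vapply(meds, function(b) b$ci[1], numeric(1)))
  hi <- min(vapply(meds, function(b) b$ci[2], numeric(1)))
  expect_lt(lo, hi)
})

test_that("fitted exponents never exceed the theoretical state count bound", {
  set.seed(71)
  combos <- list(c(2L, 1L), c(3L, 2L), c(4L, 1L), c(5L, 3L))
  for (cb in combos) {
    bp <- sample_benchmark_params(cb[1], cb[2])
    f <- fit_loglog_exponent(bp$times, bp$means)
    expect_lt(f$exponent_n, cb[1] - cb[2] + 1)
    expect_gt(f$r_squared, 0.95)
  }
})

test_that("state-bound reports round up the exponent and read processing shifts", {
  fit <- genestates:::new_power_law_fit(1.95, 1, 2, 0, 0, 5, 0, NA,
                                        "nonlinear_delayed")
  rep <- report_state_bound(fit)
  expect_equal(rep$states_visited_bound, 2L)
  expect_equal(rep$n_states_lower_bound, 2L)
  cyto <- genestates:::new_power_law_fit(2.9, 1, 2, 0, 0, 5, 0, NA,
                                         "nonlinear_delayed")
  rep2 <- report_state_bound(fit, other = cyto, other_label = "cytoplasmic")
  expect_match(rep2$processing_interpretation, "first-order")
  same <- genestates:::new_power_law_fit(2.05, 1, 2, 0, 0, 5, 0, NA,
                                         "nonlinear_delayed")
  rep3 <- report_state_bound(fit, other = same)
  expect_match(rep3$processing_interpretation, "fixed-delay")
})

test_that("the exponent calibration table brackets observed exponents", {
  set.seed(81)
  cal <- build_exponent_calibration(n_sets = 25, seed = 81, Ns = 2:3)
  expect_equal(nrow(cal), 3)
  expect_true(all(cal$fit_max < cal$exponent_theory))
  fit <- genestates:::new_power_law_fit(1.95, 1, 2, 0, 0, 5, 0, NA,
                                        "nonlinear_delayed")
  rep <- report_state_bound(fit, calibration = cal)
  # an exponent just under 2 is consistent with the 3-state model induced
  # from its first state (theoretical exponent 3, finite-window fits below)
  expect_true(3 %in% rep$consistent_models$N)
})
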