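test_that("constitutive induction follows the birth-death closed form", {
  p <- nstate_params(1, numeric(0), rho = 5, d = 2)
  tr <- integrate_moment_odes(p, 1, c(0, 0.1, 0.5, 1, 3))
  expect_rel_equal(tr$mean[-1], 5 / 2 * (1 - exp(-2 * tr$time[-1])), 1e-10)
  # Poisson at all times: Fano stays 1
  expect_lt(max(abs(tr$fano - 1)), 1e-8)
})

test_that("state probabilities stay normalised and mean reaches rho*P_on/d", {
  p <- canonical_params()$n5
  tr <- integrate_moment_odes(p, 1, c(0.01, 0.1, 1, 10, 60))
  expect_lt(max(abs(rowSums(attr(tr, "state_probs")) - 1)), 1e-8)
  w <- waiting_time_stats(p)
  expect_rel_equal(tr$mean[length(tr$mean)], p$rho * w$p_on / p$d, 1e-6)
})

test_that("moment trajectories agree with SSA ensembles", {
  p <- canonical_params()$n5
  ds <- ssa_simulate(p, 1, n_cells = 2e4, times = c(0.3, 0.6, 1, 2),
                     seed = 31)
  sm <- dataset_means(ds)
  tr <- integrate_moment_odes(p, 1, sm$time)
  expect_true(all(abs(sm$mean - tr$mean) < 3 * sm$sem + 1e-12))
})

test_that("short-time expansion coefficients match the chain formulas", {
  p5 <- nstate_params(5, rep(1, 5), rho = 10, d = 1)
  ex <- short_time_expansion(p5, 1)
  expect_equal(ex$exponent, 5L)
  expect_equal(ex$prefactor, 10 / factorial(5), tolerance = 1e-14)
  # truncated series reproduces the exact mean at t = 0.01
  tr <- integrate_moment_odes(p5, 1, 0.01)
  ser <- ex$prefactor * 0.01^5 + ex$next_order_coeff * 0.01^6
  expect_rel_equal(tr$mean, ser, 1e-3)
  # telegraph induced from its inactive state has exponent 2
  expect_equal(short_time_expansion(canonical_params()$n2, 1)$exponent, 2L)
  expect_error(short_time_expansion(p5, 5), "inactive")
})

test_that("series coefficients match the exact solution for all chain sizes", {
  set.seed(13)
  for (N in 2:5) for (rep in 1:5) {
    p <- random_params(N)
    j <- sample(N - 1, 1)
    ex <- short_time_expansion(p, j)
    n <- ex$exponent
    # pick t so the t^{n+2} remainder is negligible relative to the t^{n+1}
    # term but both stay above double-precision noise
    t <- min(1e-3, ex$validity_time / 100)
    exact <- integrate_moment_odes(p, j, t)$mean
    two_terms <- ex$prefactor * t^n + ex$next_order_coeff * t^(n + 1)
    expect_lt(abs(exact - two_terms),
              0.05 * abs(ex$next_order_coeff) * t^(n + 1))
  }
})

test_that("the next-order term is negative so the power law bounds the mean", {
  set.seed(14)
  for (i in 1:100) {
    p <- random_params()
    j <- sample(p$N - 1, 1)
    ex <- short_time_expansion(p, j)
    expect_lt(ex$next_order_coeff, 0)
    ts <- ex$validity_time * c(0.05, 0.2, 0.5)
    tr <- integrate_moment_odes(p, j, ts)
    expect_true(all(tr$mean < ex$prefactor * ts^ex$exponent))
  }
})

test_that("the validity window never exceeds N + 1 degradation times", {
  set.seed(15)
  vt <- replicate(1000, {
    p <- random_params()
    j <- sample(p$N - 1, 1)
    c(short_time_expansion(p, j)$validity_time, p$N)
  })
  expect_true(all(vt[1, ] <= vt[2, ] + 1))
})

test_that("minimal-path rule gives the exponent for general networks", {
  p5 <- nstate_params(5, rep(1, 5), rho = 10, d = 1)
  net <- chain_network(p5)
  attr(net, "chain") <- NULL
  net$rates[2, 5] <- 0.7          # shortcut: path 1 -> 2 -> 5 visits 3 states
  ex <- short_time_expansion(net, 1)
  expect_equal(ex$exponent, 3L)
  expect_equal(ex$prefactor, 10 * 1 * 0.7 / factorial(3), tolerance = 1e-12)
  # two parallel shortest paths both feed the prefactor
  net2 <- net
  net2$rates[2, 5] <- 0
  net2$rates[1, 4] <- 0.5         # 1->4->5 ties with nothing shorter
  ex2 <- short_time_expansion(net2, 1)
  expect_equal(ex2$exponent, 3L)
  expect_equal(ex2$n_paths, 1L)
  expect_equal(ex2$prefactor, 10 * 0.5 * 1 / factorial(3), tolerance = 1e-12)
  # reversible extension with reset on synthesis still integrates exactly
  net3 <- chain_network(p5)
  attr(net3, "chain") <- NULL
  net3$rates[2, 1] <- 0.5
  net3$reset_state <- 2L
  tr <- integrate_moment_odes(net3, 1, c(0.001, 0.01))
  expect_true(all(tr$mean > 0))
  expect_lt(max(abs(rowSums(attr(tr, "state_probs")) - 1)), 1e-8)
  # disconnected initial state can never activate
  net4 <- gene_network(3, matrix(c(0, 0, 0, 0, 0, 1, 0, 0, 0), 3, 3,
                                 byrow = TRUE), rho = 5, d = 1)
  expect_error(short_time_expansion(net4, 1), "never activate")
})

test_that("downstream exponent matches the ODE slope for the shifted species", {
  p2 <- nstate_params(2, c(1, 1), rho = 10, d = 1)
  tt <- 10^seq(-4, -3, length.out = 8)
  tr <- integrate_moment_odes(p2, 1, tt,
                              downstream = list(list(rate = 2,
                                                     type = "conversion")))
  base_slope <- unname(stats::coef(stats::lm(log(tr$mean) ~ log(tt)))[2])
  ds_slope <- unname(stats::coef(stats::lm(log(tr$s1) ~ log(tt)))[2])
  expect_lt(abs(ds_slope - base_slope - 1), 0.02)
})

test_that("processing steps shift the exponent by one per first-order step", {
  expect_equal(processing_exponent_shift(2, "first_order"), 3L)
  expect_equal(processing_exponent_shift(4, "fixed_delay"), 4L)
  expect_equal(processing_exponent_shift(2, c("first_order", "first_order")),
               4L)
  expect_equal(processing_exponent_shift(3), 3L)
  expect_error(processing_exponent_shift(1), ">= 2")
})

test_that("short-time Fano factor has slope 2*rho/(N-j+2)", {
  p <- nstate_params(3, c(1, 2, 3), rho = 5, d = 1)
  expect_equal(short_time_fano(p, 1, 0), 1)
  expect_equal((short_time_fano(p, 1, 1e-4) - 1) / 1e-4, 2 * 5 / 4,
               tolerance = 1e-12)
  tr <- integrate_moment_odes(p, 1, 1e-3)
  expect_rel_equal(tr$fano, 1 + 2 * 5 * 1e-3 / 4, 1e-2)
})

test_that("rho and the rate product are recovered from short-time slopes", {
  p <- nstate_params(3, c(2, 3, 1), rho = 4, d = 1)
  ex <- short_time_expansion(p, 1)
  est <- estimate_rho_and_rate_product(
    list(slope = 3, intercept = log(ex$prefactor)), fano_slope = 2 * 4 / 4)
  expect_equal(est$rho, 4, tolerance = 1e-12)
  expect_equal(est$rate_product, 2 * 3, tolerance = 1e-12)
  # slopes measured from ODE trajectories over an early window
  tt <- seq(1e-3, 1e-2, length.out = 6)
  tr <- integrate_moment_odes(p, 1, tt)
  mf <- fit_loglog_exponent(tt, tr$mean)
  ff_slope <- unname(stats::coef(stats::lm(tr$fano ~ tt))[2])
  est2 <- estimate_rho_and_rate_product(mf, ff_slope)
  expect_lt(abs(est2$rho - 4) / 4, 0.05)
  expect_error(estimate_rho_and_rate_product(list(slope = 3, intercept = 0),
                                             fano_slope = 0), "degenerate")
})

test_that("static extrinsic noise changes the prefactor but not the fitted slope", {
  p <- nstate_params(3, c(8, 8, 1), rho = 100, d = 1)
  tt <- seq(0.004, 0.02, length.out = 5)
  fixed_slope <- fit_loglog_exponent(
    tt, integrate_moment_odes(p, 1, tt)$mean)$exponent_n
  # mixture over gamma-distributed rates (CV 0.3 on every parameter)
  set.seed(77)
  mix <- rowMeans(replicate(300, {
    kk <- vapply(p$k, function(m) genestates:::rgamma_cv(1, m, 0.3),
                 numeric(1))
    rr <- genestates:::rgamma_cv(1, p$rho, 0.3)
    integrate_moment_odes(nstate_params(3, kk, rr, 1), 1, tt)$mean
  }))
  mix_slope <- fit_loglog_exponent(tt, mix)$exponent_n
  expect_lt(abs(mix_slope - fixed_slope), 0.05)
  # the prefactor does shift
  expect_gt(abs(log(mix[1] / integrate_moment_odes(p, 1, tt)$mean[1])), 0.001)
})
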