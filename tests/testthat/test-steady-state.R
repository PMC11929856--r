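test_that("the constitutive model is Poisson with mean rho/d", {
  dist <- steady_state_distribution(nstate_params(1, numeric(0), rho = 5,
                                                  d = 1))
  ref <- stats::dpois(0:dist$m_max, 5)
  expect_lt(max(abs(dist$probs - ref / sum(ref))), 1e-10)
  expect_equal(dist_mean(dist), 5, tolerance = 1e-8)
  expect_equal(fano_factor(dist), 1, tolerance = 1e-6)
})

test_that("the stationary distribution is invariant to permutations of k_1..k_{N-1}", {
  a <- steady_state_distribution(nstate_params(3, c(1, 4, 2), rho = 20, d = 1))
  b <- steady_state_distribution(nstate_params(3, c(4, 1, 2), rho = 20, d = 1))
  expect_lt(max(abs(a$probs - b$probs)), 1e-10)
  # but not invariant to permuting the inactivation rate k_N into the cycle
  c3 <- steady_state_distribution(nstate_params(3, c(2, 4, 1), rho = 20,
                                                d = 1))
  expect_gt(wasserstein_distance(a, c3), 1e-3)
})

test_that("the stationary distribution depends only on rates normalised by d", {
  a <- steady_state_distribution(nstate_params(4, c(1, 2, 3, 4), rho = 20,
                                               d = 1))
  b <- steady_state_distribution(nstate_params(4, 10 * c(1, 2, 3, 4),
                                               rho = 200, d = 10))
  expect_lt(max(abs(a$probs - b$probs)), 1e-10)
})

test_that("stationary mean equals rho * P_on / d and the mapping preserves it", {
  for (p in canonical_params()[c("n3", "n5")]) {
    dist <- steady_state_distribution(p)
    w <- waiting_time_stats(p)
    expect_rel_equal(dist_mean(dist), p$rho * w$p_on / p$d, 1e-6)
    # waiting-time matching also matches the mean mRNA number
    tg_dist <- steady_state_distribution(map_to_telegraph(p))
    expect_rel_equal(dist_mean(tg_dist), dist_mean(dist), 1e-6)
  }
})

test_that("Wasserstein distance is the cumulative-difference metric", {
  pois <- function(lam, M = 100) {
    pr <- stats::dpois(0:M, lam)
    count_distribution(pr / sum(pr))
  }
  p5 <- pois(5); p7 <- pois(7)
  expect_equal(wasserstein_distance(p5, p5), 0)
  # unit transport over unit distance
  expect_equal(wasserstein_distance(count_distribution(c(1, 0)),
                                    count_distribution(c(0, 1))), 1)
  # brute-force cumulative-sum oracle; equals the mean difference for
  # stochastically ordered Poisson pairs
  oracle <- sum(abs(cumsum(p5$probs) - cumsum(p7$probs)))
  expect_equal(wasserstein_distance(p5, p7), oracle, tolerance = 1e-12)
  expect_equal(wasserstein_distance(p5, p7), 2, tolerance = 1e-6)
  # metric properties on a triple
  p6 <- pois(6)
  expect_equal(wasserstein_distance(p5, p7), wasserstein_distance(p7, p5))
  expect_lte(wasserstein_distance(p5, p7),
             wasserstein_distance(p5, p6) + wasserstein_distance(p6, p7))
})

test_that("shape classification follows the mode/Fano rule", {
  pois5 <- steady_state_distribution(nstate_params(1, numeric(0), 5, 1))
  expect_equal(classify_shape(pois5)$label, "I")
  # slow-switching telegraph: bimodal with a zero mode
  s3 <- classify_shape(steady_state_distribution(
    telegraph_params(0.1, 0.1, 40, 1)))
  expect_equal(s3$label, "III")
  expect_equal(min(s3$modes), 0)
  # intermediate switching: k_N/d < 1, k_i/d >= 1, large rho gives two
  # non-zero modes
  s4 <- classify_shape(steady_state_distribution(
    nstate_params(5, c(2, 2, 2, 2, 0.3), rho = 40, d = 1)))
  expect_equal(s4$label, "IV")
  expect_true(all(s4$modes > 0))
  # unimodal with Fano >= 2
  s2 <- classify_shape(steady_state_distribution(
    nstate_params(3, c(1, 1, 8), rho = 60, d = 1)))
  expect_equal(s2$label, "II")
  expect_gte(s2$fano, 2)
  # three retained modes are reported as unclassifiable
  tri <- c(0.3, 0.05, 0.2, 0.05, 0.25, 0.05, 0.1)
  expect_equal(classify_shape(count_distribution(tri))$label,
               "unclassifiable")
  # low-prominence ripples are ignored
  ripple <- c(0.5, 0.3, 0.12, 0.04, 0.04003, 0.03997)
  ripple <- ripple / sum(ripple)
  expect_equal(classify_shape(count_distribution(ripple))$label, "I")
})

test_that("a degenerate sweep reproduces the direct computation", {
  ranges <- list(k = c(2, 2), rho = c(30, 30))
  sw <- run_parameter_sweep(1, 3, ranges = ranges, seed = 1)
  p <- nstate_params(3, c(2, 2, 2), rho = 30, d = 1)
  tg <- map_to_telegraph(p)
  expect_equal(sw$k1_star, tg$k[1], tolerance = 1e-12)
  wd <- wasserstein_distance(steady_state_distribution(p),
                             steady_state_distribution(tg))
  expect_equal(sw$wd, wd, tolerance = 1e-10)
  expect_equal(sw$shape, classify_shape(steady_state_distribution(p))$label)
})

test_that("effective telegraph distributions are never bimodal with two non-zero modes", {
  sw <- run_parameter_sweep(150, 4, seed = 11)
  expect_true(all(sw$telegraph_shape != "IV"))
  expect_true(all(sw$wd >= 0))
  meta <- attr(sw, "meta")
  expect_equal(meta$n_requested, 150)
})

test_that("models with equal inactive rates stay close to their telegraph fit", {
  set.seed(5)
  wds <- replicate(20, {
    a <- exp(stats::runif(1, log(10^-1), log(10^1)))
    kN <- exp(stats::runif(1, log(10^-1), log(10^1)))
    rho <- exp(stats::runif(1, log(1), log(10^2)))
    p <- nstate_params(4, c(a, a, a, kN), rho, 1)
    wasserstein_distance(steady_state_distribution(p),
                         steady_state_distribution(map_to_telegraph(p)))
  })
  expect_lt(stats::median(wds), 0.1)
})

test_that("sweep results round-trip to CSV with JSON metadata", {
  sw <- run_parameter_sweep(5, 3, seed = 2)
  f <- file.path(tempdir(), "sweep.csv")
  write_sweep(sw, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(sw))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 2)
  s <- sweep_summary(sw)
  expect_equal(sum(s$shape_percent), 100)
})
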