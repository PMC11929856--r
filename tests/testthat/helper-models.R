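# Shared fixtures: canonical parameter sets and random-model samplers.

canonical_params <- function() {
  list(
    n2 = nstate_params(2, c(1.3, 0.7), rho = 4, d = 1),
    n3 = nstate_params(3, c(1, 2, 3), rho = 5, d = 1),
    n4 = nstate_params(4, c(1, 2, 3, 4), rho = 10, d = 1),
    n5 = nstate_params(5, c(2, 3, 1, 5, 0.5), rho = 30, d = 1)
  )
}

# Log-uniform random chain over the eukaryotic sweep ranges.
random_params <- function(N = sample(2:5, 1), ranges = default_sweep_ranges()) {
  k <- exp(stats::runif(N, log(ranges$k[1]), log(ranges$k[2])))
  rho <- exp(stats::runif(1, log(ranges$rho[1]), log(ranges$rho[2])))
  nstate_params(N, k, rho, 1)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected),
                                              .Machine$double.eps)), tol)
}
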