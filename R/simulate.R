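#' Static extrinsic noise specification
#'
#' Cell-to-cell variability in rate parameters: each listed parameter is drawn
#' once per cell from a gamma distribution whose mean is the model's rate and
#' whose coefficient of variation is given here; parameters with CV 0 (or not
#' listed) stay fixed. Parameters are drawn independently of each other.
#'
#' @param k CV of the gene-state transition rates: a scalar (shared by all
#'   `k_i`) or a vector of per-rate CVs.
#' @param rho CV of the transcription rate.
#' @param d CV of the degradation rate.
#' @return Object of class `extrinsic_noise`.
#' @export
extrinsic_noise <- function(k = 0, rho = 0, d = 0) {
  if (any(c(k, rho, d) < 0)) stop("CVs must be >= 0", call. = FALSE)
  structure(list(k = k, rho = rho, d = d), class = "extrinsic_noise")
}

# Gamma draws with given mean and CV; CV = 0 degenerates to the mean.
rgamma_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Per-cell static rate draws. Returns the rate-matrix columns (shared or one
# per cell) plus rho and d vectors for the SSA kernel.
draw_cell_rates <- function(net, noise, total) {
  n <- net$n_states
  rates_cols <- matrix(as.numeric(net$rates), ncol = 1L)
  rho <- net$rho; d <- net$d
  if (!is.null(noise)) {
    ch <- attr(net, "chain")
    if (is.null(ch))
      stop("extrinsic noise requires a chain model", call. = FALSE)
    kcv <- rep(noise$k, length.out = n)
    if (any(kcv > 0)) {
      kdraw <- vapply(seq_len(n), function(i)
        rgamma_cv(total, ch$k[i], kcv[i]), numeric(total))
      rates_cols <- matrix(0, n * n, total)
      for (i in seq_len(n - 1L))
        rates_cols[i * n + i, ] <- kdraw[, i]    # column-major (i, i+1)
      rates_cols[n, ] <- kdraw[, n]              # column-major (N, 1)
    }
    if (noise$rho > 0) rho <- rgamma_cv(total, ch$rho, noise$rho)
    if (noise$d > 0) d <- rgamma_cv(total, ch$d, noise$d)
  }
  list(rates_cols = rates_cols, rho = rho, d = d)
}

#' Dirac-delta initial gene-state distribution
#'
#' @param j State holding all probability mass.
#' @param n_states Total number of gene states.
#' @return Probability vector over states.
#' @export
delta_state <- function(j, n_states) replace(numeric(n_states), j, 1)

#' Simulate an induction experiment with the stochastic simulation algorithm
#'
#' Each cell independently draws its static rate parameters (extrinsic noise)
#' and its initial gene state, evolves by exact SSA from zero mRNA, is
#' observed at exactly one assigned time point (independent cohorts per time
#' point, matching destructive smFISH/scRNA-seq measurement), and its count is
#' binomially thinned with detection probability `capture_p`.
#'
#' @param model An [nstate_params()] (irreversible chain) or [gene_network()].
#' @param j Initial gene state: an index or a probability vector over states.
#' @param n_cells Cells per time point.
#' @param times Strictly increasing observation times.
#' @param capture_p Detection probability in (0, 1].
#' @param noise Optional [extrinsic_noise()]; chain models only.
#' @param seed Mandatory integer seed.
#' @return Object of class `induction_dataset`: a data frame with columns
#'   `cell_id`, `time`, `count`, with simulation metadata in attribute
#'   `"meta"`.
#' @export
ssa_simulate <- function(model, j, n_cells, times, capture_p = 1,
                         noise = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_cells < 1L) stop("`n_cells` must be >= 1", call. = FALSE)
  if (capture_p <= 0 || capture_p > 1)
    stop("`capture_p` must be in (0, 1]", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("`times` must be strictly increasing and non-negative", call. = FALSE)
  if (!is.null(noise) && !is_nstate_params(model))
    stop("extrinsic noise is supported for chain (nstate_params) models only",
         call. = FALSE)
  net <- as_gene_network(model)
  n <- net$n_states
  total <- n_cells * length(times)
  set.seed(seed)
  obs_time <- rep(times, each = n_cells)
  init <- if (length(j) == 1L) rep(as.integer(j), total)
          else sample.int(n, total, replace = TRUE, prob = j)
  rt <- draw_cell_rates(net, noise, total)
  counts <- ssa_counts_cpp(n, rt$rates_cols, rt$rho, rt$d,
                           net$active_state, net$reset_state, init, obs_time)
  if (capture_p < 1) counts <- stats::rbinom(total, counts, capture_p)
  out <- data.frame(cell_id = seq_len(total), time = obs_time, count = counts)
  attr(out, "meta") <- list(model = model, j = j, n_cells = n_cells,
                            capture_p = capture_p, noise = noise, seed = seed)
  class(out) <- c("induction_dataset", class(out))
  out
}

#' Per-time-point summary of an induction dataset
#'
#' @param dataset An `induction_dataset` (or any data frame with `time` and
#'   `count` columns).
#' @return Data frame with columns `time`, `mean`, `sem`, `n_cells`.
#' @export
dataset_means <- function(dataset) {
  sp <- split(dataset$count, dataset$time)
  data.frame(time = as.numeric(names(sp)),
             mean = vapply(sp, mean, numeric(1)),
             sem = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)),
                          numeric(1)),
             n_cells = vapply(sp, length, numeric(1)),
             row.names = NULL)
}

#' Default rate ranges for the induction benchmark
#'
#' Log-uniform bounds (in units of `d`) for the benchmark of finite-window
#' exponent fits. Compared with the steady-state sweep ranges, the upper
#' bounds are higher: with a mammalian mRNA half-life of many hours, strongly
#' induced genes reach transcription rates of hundreds to a thousand per
#' degradation time, and only such sets can reach a measurable mean within a
#' final time well below one degradation time.
#'
#' @return List with elements `k` and `rho`, each `c(lower, upper)`.
#' @export
benchmark_ranges <- function() {
  list(k = 10^c(-1.5, 1.5), rho = 10^c(-0.5, 3))
}

#' Sample a biologically constrained benchmark parameter set
#'
#' Draws chain rates log-uniformly and accepts them if the induction mean at
#' the last of 5 regularly spaced time points can fall inside `mean_band`
#' (default 1-25 molecules per cell, the realistic expression range) with the
#' final time at most `t_max`, well below one degradation time. The final
#' time solves `mean(T) = target` for a target drawn uniformly from the
#' attainable part of the band.
#'
#' @param N,j Chain size and initial state (`1 <= j < N`).
#' @param ranges Log-uniform sampling ranges, as [benchmark_ranges()].
#' @param mean_band Acceptance band for the final-time mean.
#' @param t_max Upper bound on the final time (units of `1/d`).
#' @param n_times Number of regularly spaced time points.
#' @param max_attempts Rejection-sampling budget.
#' @return List with `params`, `j`, `times`, `means` (ODE means at `times`).
#' @export
sample_benchmark_params <- function(N, j, ranges = benchmark_ranges(),
                                    mean_band = c(1, 25), t_max = 0.15,
                                    n_times = 5L, max_attempts = 10000L) {
  for (att in seq_len(max_attempts)) {
    k <- sample_log_uniform(N, ranges$k)
    rho <- sample_log_uniform(1L, ranges$rho)
    p <- nstate_params(N, k, rho, 1)
    m_end <- integrate_moment_odes(p, j, t_max)$mean
    if (m_end < mean_band[1]) next
    target <- stats::runif(1, mean_band[1], min(mean_band[2], m_end))
    Tf <- stats::uniroot(function(t) integrate_moment_odes(p, j, t)$mean - target,
                         interval = c(t_max * 1e-6, t_max),
                         tol = t_max * 1e-6)$root
    times <- Tf * seq_len(n_times) / n_times
    means <- integrate_moment_odes(p, j, times)$mean
    return(list(params = p, j = as.integer(j), times = times, means = means))
  }
  stop(sprintf("no parameter set accepted in %d attempts", max_attempts),
       call. = FALSE)
}

#' Simulate an induction dataset with delay and pre-existing mRNA
#'
#' Models the experimental protocol where the stimulus takes a deterministic
#' time `t0` to reach the nucleus and a small mean `m0` of pre-existing mRNA
#' is present at stimulus time. Pre-existing molecules are Poisson(`m0`) per
#' cell and each survives to observation time `t` with probability
#' `exp(-d t)`; the induced process starts at `t0` from zero mRNA.
#'
#' @inheritParams ssa_simulate
#' @param obs_times Observation times measured from the stimulus; may include
#'   times before `t0`.
#' @param t0 Deterministic delay between stimulus and initiation.
#' @param m0 Mean pre-existing mRNA count at stimulus time.
#' @return An `induction_dataset` whose `"meta"` attribute records `t0`, `m0`.
#' @export
simulate_delayed_dataset <- function(model, j, n_cells, obs_times, t0 = 0,
                                     m0 = 0, capture_p = 1, noise = NULL,
                                     seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  net <- as_gene_network(model)
  durations <- pmax(obs_times - t0, 0)
  total <- n_cells * length(obs_times)
  # induced counts: cells with duration 0 have not initiated
  init <- rep(as.integer(j), total)
  dur_by_cell <- rep(durations, each = n_cells)
  rt <- draw_cell_rates(net, noise, total)
  induced <- ssa_counts_cpp(net$n_states, rt$rates_cols, rt$rho, rt$d,
                            net$active_state, net$reset_state,
                            init, dur_by_cell)
  # pre-existing mRNA decays exponentially from stimulus time
  t_by_cell <- rep(obs_times, each = n_cells)
  base0 <- stats::rpois(total, m0)
  baseline <- stats::rbinom(total, base0, exp(-net$d * t_by_cell))
  counts <- induced + baseline
  if (capture_p < 1) counts <- stats::rbinom(total, counts, capture_p)
  out <- data.frame(cell_id = seq_len(total), time = t_by_cell, count = counts)
  attr(out, "meta") <- list(model = model, j = j, n_cells = n_cells,
                            capture_p = capture_p, noise = noise, seed = seed,
                            t0 = t0, m0 = m0)
  class(out) <- c("induction_dataset", class(out))
  out
}

#' Generate a suite of benchmark induction datasets with known ground truth
#'
#' For each dataset, a chain parameter set is accepted by
#' [sample_benchmark_params()] (final-time mean inside `mean_band`, final time
#' at most `t_max`), then a finite-cell dataset is simulated by exact SSA with
#' optional extrinsic noise, capture thinning, deterministic delay `t0` and
#' baseline mean `m0`. Each dataset carries its generating ground truth.
#'
#' @inheritParams sample_benchmark_params
#' @param n_datasets Number of datasets to generate.
#' @param n_cells Cells per time point.
#' @param capture_p Detection probability.
#' @param noise Optional [extrinsic_noise()].
#' @param t0,m0 Deterministic delay and baseline mean (see
#'   [simulate_delayed_dataset()]).
#' @param seed Integer seed for the whole suite.
#' @return List of `induction_dataset` objects; each has attribute
#'   `"ground_truth"`: list with `params`, `j`, `exponent` (`N - j + 1`),
#'   `times`, `ode_means`, `t0`, `m0`, `capture_p`.
#' @export
generate_benchmark_suite <- function(n_datasets, N, j, n_cells = 1000L,
                                     capture_p = 1, noise = NULL,
                                     t0 = 0, m0 = 0,
                                     ranges = benchmark_ranges(),
                                     mean_band = c(1, 25), t_max = 0.15,
                                     n_times = 5L, max_attempts = 10000L,
                                     seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_datasets), function(i) {
    bp <- sample_benchmark_params(N, j, ranges, mean_band, t_max, n_times,
                                  max_attempts)
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    ds <- if (t0 > 0 || m0 > 0) {
      simulate_delayed_dataset(bp$params, j, n_cells,
                               obs_times = bp$times + t0, t0 = t0, m0 = m0,
                               capture_p = capture_p, noise = noise,
                               seed = sub_seed)
    } else {
      ssa_simulate(bp$params, j, n_cells, bp$times, capture_p = capture_p,
                   noise = noise, seed = sub_seed)
    }
    attr(ds, "ground_truth") <- list(params = bp$params, j = bp$j,
                                     exponent = bp$params$N - bp$j + 1L,
                                     times = bp$times, ode_means = bp$means,
                                     t0 = t0, m0 = m0, capture_p = capture_p)
    ds
  })
}
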