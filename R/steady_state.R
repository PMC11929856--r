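#' mRNA copy-number distribution container
#'
#' A probability vector over copy numbers `m = 0 .. m_max`. Entries must be
#' non-negative and sum to 1 within `1e-8`.
#'
#' @param probs Numeric vector of probabilities for `m = 0, 1, ..`.
#' @return Object of class `count_distribution` with fields `probs`, `m_max`.
#' @export
count_distribution <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) < 1L || any(!is.finite(probs)) || any(probs < -1e-12))
    stop("`probs` must be a non-negative numeric vector", call. = FALSE)
  probs[probs < 0] <- 0
  if (abs(sum(probs) - 1) > 1e-8)
    stop(sprintf("probabilities sum to %.10f, not 1", sum(probs)),
         call. = FALSE)
  structure(list(probs = probs, m_max = length(probs) - 1L),
            class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("mRNA count distribution on 0..%d  (mean %.3f, Fano %.3f)\n",
              x$m_max, dist_mean(x), fano_factor(x)))
  invisible(x)
}

#' Mean, variance and Fano factor of a count distribution
#' @param dist A [count_distribution()].
#' @return A single numeric value.
#' @export
dist_mean <- function(dist) {
  m <- seq_along(dist$probs) - 1
  sum(m * dist$probs)
}

#' @rdname dist_mean
#' @export
dist_variance <- function(dist) {
  m <- seq_along(dist$probs) - 1
  mu <- sum(m * dist$probs)
  sum(m^2 * dist$probs) - mu^2
}

#' @rdname dist_mean
#' @export
fano_factor <- function(dist) dist_variance(dist) / dist_mean(dist)

# Sparse generator of the truncated CME on (gene state, copy number).
# Rates must already be normalised by d (d = 1). Column j holds outflow from
# state j on the diagonal; dP/dt = A P. Synthesis out of the top copy-number
# level is suppressed so probability mass is conserved on the truncation.
chain_generator <- function(N, k, rho, M) {
  n <- N * (M + 1L)
  idx <- function(s, m) s + N * m                   # m = 0..M
  ii <- jj <- xx <- vector("list", 4L)
  diag_acc <- numeric(n)
  # gene-state cycle, all copy-number levels
  m_all <- 0:M
  if (N > 1L) {
    for (s in seq_len(N)) {
      tgt <- if (s == N) 1L else s + 1L
      j <- idx(s, m_all)
      ii[[1L]] <- c(ii[[1L]], idx(tgt, m_all))
      jj[[1L]] <- c(jj[[1L]], j)
      xx[[1L]] <- c(xx[[1L]], rep(k[s], M + 1L))
      diag_acc[j] <- diag_acc[j] - k[s]
    }
  }
  # synthesis from active state N (not at m = M)
  m_syn <- 0:(M - 1L)
  j <- idx(N, m_syn)
  ii[[2L]] <- idx(N, m_syn + 1L)
  jj[[2L]] <- j
  xx[[2L]] <- rep(rho, M)
  diag_acc[j] <- diag_acc[j] - rho
  # degradation, rate m (d = 1)
  m_deg <- 1:M
  for (s in seq_len(N)) {
    j <- idx(s, m_deg)
    ii[[3L]] <- c(ii[[3L]], idx(s, m_deg - 1L))
    jj[[3L]] <- c(jj[[3L]], j)
    xx[[3L]] <- c(xx[[3L]], as.numeric(m_deg))
    diag_acc[j] <- diag_acc[j] - m_deg
  }
  ii[[4L]] <- jj[[4L]] <- seq_len(n)
  xx[[4L]] <- diag_acc
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

solve_stationary <- function(A) {
  n <- nrow(A)
  # replace the first balance equation with the normalisation constraint
  A[1L, ] <- 1
  rhs <- c(1, rep(0, n - 1L))
  pi <- as.numeric(Matrix::solve(A, rhs))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Steady-state mRNA count distribution of the N-state model
#'
#' Computes the stationary distribution of the chemical master equation of the
#' N-state model, marginalised over gene states, as the null space of the
#' sparse truncated generator over (gene state, copy number). The truncation
#' is grown adaptively (doubling) until the tail mass beyond it falls below
#' `tol`. The result depends only on `k/d` and `rho/d` and is invariant under
#' any permutation of the inactive-exit rates `k[1..N-1]`.
#'
#' @param params An [nstate_params()] with `d > 0`.
#' @param tol Tail-mass tolerance for the adaptive truncation.
#' @param m_cap Hard cap on the truncation level.
#' @return A [count_distribution()].
#' @export
steady_state_distribution <- function(params, tol = 1e-8, m_cap = 2^15) {
  stopifnot(is_nstate_params(params))
  if (params$d <= 0)
    stop("steady_state_distribution requires d > 0", call. = FALSE)
  p <- nondimensionalise(params)
  if (p$N == 1L) {                     # constitutive: Poisson(rho/d)
    lam <- p$rho
    M <- max(10L, stats::qpois(1 - tol / 10, lam) + 5L)
    probs <- stats::dpois(0:M, lam)
    return(count_distribution(probs / sum(probs)))
  }
  # the conditional mean given the active state is rho/d, so start just above
  M <- as.integer(max(20, ceiling(p$rho + 10 * sqrt(p$rho + 1))))
  tail_mass <- NA_real_
  repeat {
    if (M > m_cap) {
      stop(sprintf(
        "truncation failure: tail mass %.3e above tolerance %.1e at m_max = %d",
        tail_mass, tol, as.integer(M / 2)), call. = FALSE)
    }
    A <- chain_generator(p$N, p$k, p$rho, M)
    pi <- solve_stationary(A)
    marg <- colSums(matrix(pi, nrow = p$N))
    tail_mass <- sum(marg[(length(marg) - 4L):length(marg)])
    if (tail_mass < tol) break
    M <- M * 2L
  }
  # trim the numerically empty tail, keeping a small margin
  keep <- which(cumsum(marg) >= 1 - tol / 10)[1L]
  keep <- min(length(marg), keep + 10L)
  probs <- marg[seq_len(keep)]
  count_distribution(probs / sum(probs))
}

#' Wasserstein distance between two count distributions
#'
#' The discrete 1-Wasserstein distance, `sum_i |P^c_i - Q^c_i|` over the
#' cumulative distributions with zero-padding to a common support. It measures
#' how much probability mass must be moved, and how far, to reshape one
#' histogram into the other.
#'
#' @param p,q [count_distribution()] objects.
#' @return Non-negative numeric; zero iff the distributions are identical.
#' @export
wasserstein_distance <- function(p, q) {
  a <- p$probs; b <- q$probs
  n <- max(length(a), length(b))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  sum(abs(cumsum(a) - cumsum(b)))
}

# Topographic prominence of strict local maxima of a probability vector.
find_modes <- function(p, prominence = 1e-4) {
  n <- length(p)
  if (n == 1L)
    return(data.frame(m = 0, height = p, prominence = p))
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  peak_at <- which(p > left & p > right)
  if (length(peak_at) == 0L) return(data.frame(m = integer(0),
                                               height = numeric(0),
                                               prominence = numeric(0)))
  prom <- vapply(peak_at, function(i) {
    side <- function(idx_seq) {
      lo <- p[i]
      for (j in idx_seq) {
        if (p[j] > p[i]) return(lo)   # reached a higher point: key saddle
        lo <- min(lo, p[j])
      }
      -Inf                            # no higher point on this side
    }
    base <- max(side(rev(seq_len(i - 1L))), side(seq.int(i + 1L, length.out = n - i)))
    if (is.infinite(base)) p[i] else p[i] - base
  }, numeric(1))
  keep <- prom >= prominence
  data.frame(m = peak_at[keep] - 1L, height = p[peak_at[keep]],
             prominence = prom[keep])
}

#' Classify the shape of a steady-state count distribution
#'
#' Shape classes: I, unimodal with Fano factor < 2; II, unimodal with Fano
#' factor >= 2; III, bimodal with one mode at zero; IV, bimodal with both
#' modes at non-zero counts. A mode is a copy number whose probability strictly
#' exceeds both neighbours (zero is a mode if `p(0) > p(1)`); modes with
#' topographic prominence below `prominence` are ignored. Distributions with
#' three or more retained modes are labelled "unclassifiable".
#'
#' @param dist A [count_distribution()].
#' @param prominence Minimum absolute-probability prominence of a mode.
#' @return Object of class `shape_class`: list with `label`
#'   (one of "I", "II", "III", "IV", "unclassifiable"), `fano`, `modes`.
#' @export
classify_shape <- function(dist, prominence = 1e-4) {
  stopifnot(inherits(dist, "count_distribution"))
  modes <- find_modes(dist$probs, prominence = prominence)
  fano <- fano_factor(dist)
  n_modes <- nrow(modes)
  label <-
    if (n_modes == 1L) {
      if (fano < 2) "I" else "II"
    } else if (n_modes == 2L) {
      if (min(modes$m) == 0L) "III" else "IV"
    } else {
      "unclassifiable"
    }
  structure(list(label = label, fano = fano, modes = modes$m,
                 mode_heights = modes$height),
            class = "shape_class")
}

#' @export
print.shape_class <- function(x, ...) {
  cat(sprintf("shape %s  (Fano %.3f; modes at %s)\n", x$label, x$fano,
              paste(x$modes, collapse = ", ")))
  invisible(x)
}

#' Default log-uniform sampling ranges for the parameter sweep
#'
#' Ranges of `k_i/d` and `rho/d` covering telegraph-model rate estimates for
#' eukaryotic genes reported across published studies. Bounds are in units of
#' the degradation rate and are overridable in [run_parameter_sweep()].
#'
#' @return List with elements `k` and `rho`, each `c(lower, upper)`.
#' @export
default_sweep_ranges <- function() {
  list(k = 10^c(-1.5, 1.5), rho = 10^c(-0.5, 2.5))
}

sample_log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Sweep the N-state parameter space against the effective telegraph model
#'
#' Samples `n_sets` rate parameter sets log-uniformly, maps each onto its
#' effective telegraph model, computes both steady-state distributions, their
#' Wasserstein distance, and the shape class of each. Truncation failures are
#' excluded and counted in the metadata.
#'
#' @param n_sets Number of parameter sets (>= 1).
#' @param N Number of gene states of the swept model (>= 2).
#' @param ranges List with elements `k` and `rho` giving `c(lower, upper)`
#'   bounds (in units of `d`); see [default_sweep_ranges()].
#' @param seed Optional integer seed.
#' @param tol Truncation tolerance passed to [steady_state_distribution()].
#' @param keep_distributions Keep the computed distributions (list columns);
#'   off by default to bound memory in large sweeps.
#' @return A data frame with one row per accepted set: the sampled rates
#'   `k1..kN`, `rho`, starred telegraph rates, `wd`, shape labels and Fano
#'   factors of both models, and mode locations. Metadata (seed, ranges,
#'   truncation policy, failure count) is attached as attribute `"meta"`.
#' @export
run_parameter_sweep <- function(n_sets, N, ranges = default_sweep_ranges(),
                                seed = NULL, tol = 1e-8,
                                keep_distributions = FALSE) {
  stopifnot(n_sets >= 1, N >= 2)
  if (any(unlist(ranges) <= 0)) stop("ranges must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_sets)
  dists <- if (keep_distributions) vector("list", n_sets) else NULL
  n_failed <- 0L
  for (i in seq_len(n_sets)) {
    k <- sample_log_uniform(N, ranges$k)
    rho <- sample_log_uniform(1L, ranges$rho)
    p <- nstate_params(N, k, rho, 1)
    tg <- map_to_telegraph(p)
    rec <- tryCatch({
      dn <- steady_state_distribution(p, tol = tol)
      dt <- steady_state_distribution(tg, tol = tol)
      sn <- classify_shape(dn)
      st <- classify_shape(dt)
      if (keep_distributions) dists[[i]] <- list(nstate = dn, telegraph = dt)
      c(as.list(stats::setNames(k, paste0("k", seq_len(N)))),
        list(rho = rho,
             k1_star = tg$k[1], k2_star = tg$k[2],
             wd = wasserstein_distance(dn, dt),
             shape = sn$label, fano = sn$fano,
             n_modes = length(sn$modes),
             mode1 = sn$modes[1],
             mode2 = if (length(sn$modes) >= 2L) sn$modes[2] else NA_integer_,
             telegraph_shape = st$label))
    }, error = function(e) NULL)
    if (is.null(rec)) n_failed <- n_failed + 1L else rows[[i]] <- rec
  }
  out <- do.call(rbind, lapply(rows[!vapply(rows, is.null, logical(1))],
                               function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "meta") <- list(seed = seed, N = N, ranges = ranges, tol = tol,
                            n_requested = n_sets, n_failed = n_failed)
  if (keep_distributions)
    attr(out, "distributions") <- dists[!vapply(dists, is.null, logical(1))]
  out
}

#' Summarise a parameter sweep
#'
#' Shape-class frequencies (percent) and Wasserstein-distance quantiles per
#' shape class.
#'
#' @param sweep Result of [run_parameter_sweep()].
#' @return List with `shape_percent` (named numeric) and `wd_quantiles`
#'   (data frame of 10/25/50/75/90th percentiles per shape).
#' @export
sweep_summary <- function(sweep) {
  pct <- 100 * table(factor(sweep$shape,
                            levels = c("I", "II", "III", "IV",
                                       "unclassifiable"))) / nrow(sweep)
  qs <- do.call(rbind, lapply(split(sweep$wd, sweep$shape), function(w) {
    stats::quantile(w, c(0.1, 0.25, 0.5, 0.75, 0.9))
  }))
  list(shape_percent = c(pct), wd_quantiles = as.data.frame(qs))
}

#' Paired CDF values for probability-probability plots
#'
#' Exports paired cumulative probabilities of two count distributions over the
#' union support, for P-P plot rendering.
#'
#' @param p,q [count_distribution()] objects.
#' @return Data frame with columns `m`, `cdf_p`, `cdf_q`.
#' @export
pp_plot_data <- function(p, q) {
  a <- p$probs; b <- q$probs
  n <- max(length(a), length(b))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  data.frame(m = seq_len(n) - 1L, cdf_p = cumsum(a), cdf_q = cumsum(b))
}

#' Draw a probability-probability plot of two count distributions
#'
#' Thin base-graphics renderer over [pp_plot_data()]: paired cumulative
#' probabilities against the identity line. Deviations from the diagonal
#' show where the distributions disagree.
#'
#' @param p,q [count_distribution()] objects.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot_pp <- function(p, q, ...) {
  dat <- pp_plot_data(p, q)
  graphics::plot(dat$cdf_p, dat$cdf_q, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "CDF, first model", ylab = "CDF, second model",
                 pch = 16, cex = 0.6, ...)
  graphics::abline(0, 1, col = "red", lty = 2)
  invisible(dat)
}

#' Write sweep results and metadata to disk
#'
#' One row per record as CSV plus a JSON metadata block (seed, ranges,
#' truncation policy, failure count).
#'
#' @param sweep Result of [run_parameter_sweep()].
#' @param csv_path,meta_path Output file paths.
#' @return Invisibly, `csv_path`.
#' @export
write_sweep <- function(sweep, csv_path,
                        meta_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(sweep, csv_path, row.names = FALSE)
  jsonlite::write_json(attr(sweep, "meta"), meta_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(csv_path)
}
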