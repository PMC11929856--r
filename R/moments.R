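# Moment dynamics of the chemical master equation and the short-time
# power-law theory. The first- and second-moment equations of any first-order
# gene network close exactly, so the trajectory is propagated with a dense
# matrix exponential rather than a numerical ODE solver; this retains full
# relative accuracy at the very short times where the mean scales like t^n
# and lies far below any absolute integrator tolerance.

# Assemble the (3n + L) x (3n + L) coefficient matrix of the closed linear
# system for [state probs; conditional first moments; conditional second
# moments; downstream species means].
moment_matrix <- function(network, downstream = NULL) {
  n <- network$n_states
  L <- length(downstream)
  D <- 3L * n + L
  A <- matrix(0, D, D)
  P <- seq_len(n); M1 <- n + P; M2 <- 2L * n + P
  S <- if (L > 0L) 3L * n + seq_len(L) else integer(0)
  # gene-state transitions move probability and both conditional moments
  nz <- which(network$rates > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1L]; j <- nz[r, 2L]; kap <- network$rates[i, j]
    for (blk in list(P, M1, M2)) {
      A[blk[j], blk[i]] <- A[blk[j], blk[i]] + kap
      A[blk[i], blk[i]] <- A[blk[i], blk[i]] - kap
    }
  }
  # synthesis: G_a -> G_K + M at rate rho
  a <- network$active_state; K <- network$reset_state; rho <- network$rho
  if (K != a) {
    A[P[K], P[a]] <- A[P[K], P[a]] + rho
    A[P[a], P[a]] <- A[P[a], P[a]] - rho
    A[M1[K], M1[a]] <- A[M1[K], M1[a]] + rho
    A[M1[a], M1[a]] <- A[M1[a], M1[a]] - rho
    A[M1[K], P[a]] <- A[M1[K], P[a]] + rho
    A[M2[K], M2[a]] <- A[M2[K], M2[a]] + rho
    A[M2[a], M2[a]] <- A[M2[a], M2[a]] - rho
    A[M2[K], M1[a]] <- A[M2[K], M1[a]] + 2 * rho
    A[M2[K], P[a]] <- A[M2[K], P[a]] + rho
  } else {
    A[M1[a], P[a]] <- A[M1[a], P[a]] + rho
    A[M2[a], M1[a]] <- A[M2[a], M1[a]] + 2 * rho
    A[M2[a], P[a]] <- A[M2[a], P[a]] + rho
  }
  # degradation M -> 0 at rate d per molecule
  d <- network$d
  A[cbind(M1, M1)] <- A[cbind(M1, M1)] - d
  A[cbind(M2, M2)] <- A[cbind(M2, M2)] - 2 * d
  A[cbind(M2, M1)] <- A[cbind(M2, M1)] + d
  # downstream processing chain
  for (l in seq_len(L)) {
    st <- downstream[[l]]
    r <- st$rate
    conv <- identical(st$type %||% "conversion", "conversion")
    if (l == 1L) {
      A[S[1L], M1] <- A[S[1L], M1] + r
      if (conv) {
        A[cbind(M1, M1)] <- A[cbind(M1, M1)] - r
        A[cbind(M2, M2)] <- A[cbind(M2, M2)] - 2 * r
        A[cbind(M2, M1)] <- A[cbind(M2, M1)] + r
      }
    } else {
      A[S[l], S[l - 1L]] <- A[S[l], S[l - 1L]] + r
      if (conv) A[S[l - 1L], S[l - 1L]] <- A[S[l - 1L], S[l - 1L]] - r
    }
    A[S[l], S[l]] <- A[S[l], S[l]] - (st$deg %||% 0)
  }
  A
}

#' Integrate the moment equations of the chemical master equation
#'
#' Computes the exact time evolution of the gene-state probabilities and the
#' first two moments of the mRNA count for any first-order gene network.
#' Because all reactions are first order, the moment equations close and form
#' a linear ODE system that is propagated exactly via the matrix exponential
#' at each requested time, so very small short-time values (of order `t^n`)
#' are obtained at full relative precision.
#'
#' @param network A [gene_network()] or [nstate_params()] (treated as the
#'   irreversible chain).
#' @param j Initial gene state (integer), or a probability vector over states.
#' @param times Numeric vector of non-negative output times.
#' @param initial_mean,initial_second_moment Initial mRNA moments (default
#'   zero mRNA); assigned proportionally to the initial state probabilities.
#' @param downstream Optional list of downstream processing steps applied to
#'   the mRNA in sequence; each element is `list(rate =, type = "conversion"`
#'   (the mRNA is consumed, e.g. splicing or export) `or "catalytic"` (it is
#'   not, e.g. translation), `deg =)` giving the species' own first-order
#'   decay. Means of the downstream species are returned as columns
#'   `s1, s2, ...`.
#' @return A data frame of class `moment_trajectory` with columns `time`,
#'   `mean`, `second_moment`, `variance`, `fano` (defined as 1 at zero mean,
#'   its induction limit), and one column per downstream species. The matrix
#'   of gene-state probabilities is attached as attribute `"state_probs"`.
#' @export
integrate_moment_odes <- function(network, j, times,
                                  initial_mean = 0,
                                  initial_second_moment = initial_mean,
                                  downstream = NULL) {
  network <- as_gene_network(network)
  n <- network$n_states
  p0 <- if (length(j) == 1L) {
    if (j < 1L || j > n) stop("`j` must be a valid state index", call. = FALSE)
    replace(numeric(n), as.integer(j), 1)
  } else {
    if (length(j) != n || any(j < 0) || abs(sum(j) - 1) > 1e-8)
      stop("initial state distribution must be a probability vector over states",
           call. = FALSE)
    as.numeric(j)
  }
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  A <- moment_matrix(network, downstream)
  L <- length(downstream)
  x0 <- c(p0, initial_mean * p0, initial_second_moment * p0, rep(0, L))
  P <- seq_len(n); M1 <- n + P; M2 <- 2L * n + P
  out <- matrix(0, length(times), 3L * n + L)
  for (ti in seq_along(times)) {
    out[ti, ] <- if (times[ti] == 0) x0 else
      as.numeric(Matrix::expm(Matrix::Matrix(A * times[ti])) %*% x0)
  }
  mean_m <- rowSums(out[, M1, drop = FALSE])
  sec_m <- rowSums(out[, M2, drop = FALSE])
  var_m <- pmax(sec_m - mean_m^2, 0)
  traj <- data.frame(time = times, mean = mean_m, second_moment = sec_m,
                     variance = var_m,
                     fano = ifelse(mean_m > 0, var_m / mean_m, 1))
  if (L > 0L) {
    sp <- out[, 3L * n + seq_len(L), drop = FALSE]
    colnames(sp) <- paste0("s", seq_len(L))
    traj <- cbind(traj, sp)
  }
  attr(traj, "state_probs") <- out[, P, drop = FALSE]
  class(traj) <- c("moment_trajectory", class(traj))
  traj
}

#' Short-time power-law expansion of the post-induction mean
#'
#' For the irreversible chain started in inactive state `j`, the mean mRNA
#' count after induction grows as
#' `<m(t)> = A t^n + B t^(n+1) + O(t^(n+2))` with exponent `n = N - j + 1`,
#' prefactor `A = rho * prod(k[j:(N-1)]) / n!` and next-order coefficient
#' `B = -rho * prod(k[j:(N-1)]) * (d + sum(k[j:N])) / (n+1)!`, which is
#' negative for all positive rates, so the leading power law always
#' overestimates the true mean. The leading term is accurate for
#' `t << validity_time = (N - j + 2) / (d + sum(k[j:N]))`. In units of the
#' degradation rate (`d = 1`) the validity time is bounded by `N + 1`.
#'
#' For a general network the exponent equals the minimal number of states
#' visited on a directed path from `j` to the active state (inclusive), and
#' the leading prefactor sums `rho * prod(edge rates) / n!` over all minimal
#' paths; the next-order coefficient and validity window are chain-only
#' results and are returned as `NA`.
#'
#' @param x An [nstate_params()] (chain) or [gene_network()].
#' @param j Initial inactive state; must differ from the active state.
#' @return Object of class `short_time_expansion`: list with `exponent`,
#'   `prefactor`, `next_order_coeff`, `validity_time`, `j`, `n_paths`.
#' @export
short_time_expansion <- function(x, j) {
  chain <- if (is_nstate_params(x)) x else attr(x, "chain")
  if (!is.null(chain)) {
    N <- chain$N
    if (j < 1L || j >= N)
      stop("`j` must be an inactive state (1 <= j < N)", call. = FALSE)
    n <- N - j + 1L
    kprod <- prod(chain$k[j:(N - 1L)])
    ksum <- sum(chain$k[j:N])
    out <- list(exponent = n,
                prefactor = chain$rho * kprod / factorial(n),
                next_order_coeff = -chain$rho * kprod * (chain$d + ksum) /
                  factorial(n + 1L),
                validity_time = (N - j + 2L) / (chain$d + ksum),
                j = as.integer(j), n_paths = 1L)
    return(structure(out, class = "short_time_expansion"))
  }
  net <- as_gene_network(x)
  if (j == net$active_state)
    stop("`j` must differ from the active state", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(net$rates, mode = "directed",
                                           weighted = TRUE)
  paths <- suppressWarnings(
    igraph::all_shortest_paths(g, from = j, to = net$active_state,
                               mode = "out", weights = NA)$res)
  if (length(paths) == 0L)
    stop("no directed path from the initial state to the active state: the gene can never activate",
         call. = FALSE)
  n <- length(paths[[1L]])               # states visited, inclusive
  pref <- sum(vapply(paths, function(pth) {
    v <- as.integer(pth)
    prod(net$rates[cbind(v[-length(v)], v[-1L])])
  }, numeric(1))) * net$rho / factorial(n)
  structure(list(exponent = n, prefactor = pref,
                 next_order_coeff = NA_real_, validity_time = NA_real_,
                 j = as.integer(j), n_paths = length(paths)),
            class = "short_time_expansion")
}

#' @export
print.short_time_expansion <- function(x, ...) {
  cat(sprintf("short-time expansion: <m(t)> ~ %g * t^%d\n", x$prefactor,
              x$exponent))
  if (is.finite(x$next_order_coeff))
    cat(sprintf("  next order: %+g * t^%d; leading term valid for t << %g\n",
                x$next_order_coeff, x$exponent + 1L, x$validity_time))
  invisible(x)
}

#' Short-time Fano factor after induction
#'
#' The variance shares the mean's leading power law, so the Fano factor obeys
#' `FF(t) = 1 + 2 rho t / (N - j + 2) + O(t^2)`: Poissonian at induction with
#' a slope that involves only the transcription rate and the number of states
#' visited (the degradation rate cancels from the linear term).
#'
#' @param params An [nstate_params()] object.
#' @param j Initial inactive state.
#' @param t Time (vectorised); should be small relative to the validity
#'   window of the expansion.
#' @return The leading-order Fano factor at `t`.
#' @export
short_time_fano <- function(params, j, t) {
  stopifnot(is_nstate_params(params))
  if (j < 1L || j >= params$N)
    stop("`j` must be an inactive state (1 <= j < N)", call. = FALSE)
  1 + 2 * params$rho * t / (params$N - j + 2)
}

#' Exponent shift from post-transcriptional processing
#'
#' Each first-order processing step (splicing, nuclear export, translation)
#' raises the short-time power-law exponent of the downstream species by one;
#' a fixed-delay step leaves it unchanged (the downstream mean is the upstream
#' mean shifted in time).
#'
#' @param base_exponent Exponent of the upstream species (integer >= 2).
#' @param steps Character vector of processing steps, each `"first_order"` or
#'   `"fixed_delay"`.
#' @return Integer exponent of the final species.
#' @export
processing_exponent_shift <- function(base_exponent, steps = character(0)) {
  base_exponent <- as.integer(base_exponent)
  if (is.na(base_exponent) || base_exponent < 2L)
    stop("`base_exponent` must be an integer >= 2", call. = FALSE)
  if (length(steps) == 0L) return(base_exponent)
  steps <- match.arg(as.character(steps), c("first_order", "fixed_delay"),
                     several.ok = TRUE)
  base_exponent + sum(steps == "first_order")
}

#' Estimate rho and the product of activation rates from short-time slopes
#'
#' Inverts the short-time laws: the log-log slope of the mean identifies
#' `n = N - j + 1`; the initial slope of the Fano factor, `2 rho / (n + 1)`,
#' then gives the transcription rate; and the log-log intercept of the mean
#' (natural log), `log(rho * prod(k) / n!)`, gives the product of the
#' traversed activation rates.
#'
#' @param mean_fit List with elements `slope` and `intercept` of the straight
#'   line fitted to (log t, log mean) in natural logarithms, or a
#'   `power_law_fit` from [fit_loglog_exponent()].
#' @param fano_slope Initial slope of the Fano factor versus time (> 0).
#' @return List with `rho`, `rate_product` and the integer exponent `n` used.
#' @export
estimate_rho_and_rate_product <- function(mean_fit, fano_slope) {
  if (inherits(mean_fit, "power_law_fit"))
    mean_fit <- list(slope = mean_fit$exponent_n,
                     intercept = log(mean_fit$prefactor_A))
  if (!is.finite(mean_fit$slope) || mean_fit$slope <= 0)
    stop("mean-fit slope must be positive", call. = FALSE)
  if (!is.finite(fano_slope) || fano_slope <= 0)
    stop("`fano_slope` must be positive; a zero slope gives the degenerate rho = 0",
         call. = FALSE)
  n <- max(2L, as.integer(round(mean_fit$slope)))
  rho <- fano_slope * (n + 1) / 2
  list(rho = rho,
       rate_product = exp(mean_fit$intercept) * factorial(n) / rho,
       n = n)
}
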