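#' Parameters of the irreversible N-state promoter model
#'
#' The model has `N` gene states arranged in an irreversible cycle
#' `G1 -> G2 -> ... -> GN -> G1` with transition rates `k[1], ..., k[N]`.
#' States `G1 ... G(N-1)` are transcriptionally inactive; mRNA is synthesised
#' only from the active state `GN` at rate `rho` and degrades at rate `d`.
#' `k[N]` is the inactivation rate out of the active state. For `N = 1` the
#' model is constitutive (no gene-state cycle) and `k` is empty.
#'
#' @param N Integer number of gene states (>= 1).
#' @param k Numeric vector of `N` strictly positive transition rates (1/time);
#'   empty for `N = 1`.
#' @param rho Transcription rate (1/time), strictly positive.
#' @param d mRNA degradation rate (1/time). Must be positive except in fitting
#'   contexts where a zero degradation rate is assumed explicitly.
#' @param allow_zero_d Permit `d = 0` (used when fitting induction data over
#'   windows much shorter than the mRNA lifetime).
#' @return An object of class `nstate_params`.
#' @examples
#' p <- nstate_params(3, k = c(1, 2, 3), rho = 5, d = 1)
#' waiting_time_stats(p)
#' @export
nstate_params <- function(N, k = numeric(0), rho, d, allow_zero_d = FALSE) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("`N` must be a single integer >= 1", call. = FALSE)
  k <- as.numeric(k)
  len_expected <- if (N == 1L) 0L else N
  if (length(k) != len_expected)
    stop(sprintf("`k` must have length %d for N = %d (got %d)",
                 len_expected, N, length(k)), call. = FALSE)
  for (i in seq_along(k))
    if (!is.finite(k[i]) || k[i] <= 0)
      stop(sprintf("rate k[%d] must be strictly positive (got %g)", i, k[i]),
           call. = FALSE)
  if (!is.finite(rho) || rho <= 0)
    stop(sprintf("rate rho must be strictly positive (got %g)", rho),
         call. = FALSE)
  d_min_ok <- if (allow_zero_d) d >= 0 else d > 0
  if (!is.finite(d) || !d_min_ok)
    stop(sprintf("rate d must be %s (got %g)",
                 if (allow_zero_d) "non-negative" else "strictly positive", d),
         call. = FALSE)
  structure(list(N = N, k = k, rho = as.numeric(rho), d = as.numeric(d)),
            class = "nstate_params")
}

#' Parameters of the (effective) telegraph model
#'
#' Two-state model with activation rate `k1`, inactivation rate `k2`,
#' transcription rate `rho` and degradation rate `d`. A telegraph model is an
#' `nstate_params` with `N = 2`, so all N-state operations apply to it.
#' Starred accessors follow the effective-model convention.
#'
#' @param k1 Activation rate (inactive -> active), > 0.
#' @param k2 Inactivation rate (active -> inactive), > 0.
#' @param rho Transcription rate, > 0.
#' @param d Degradation rate.
#' @param allow_zero_d See [nstate_params()].
#' @return Object of classes `telegraph_params` and `nstate_params`.
#' @export
telegraph_params <- function(k1, k2, rho, d, allow_zero_d = FALSE) {
  p <- nstate_params(2L, c(k1, k2), rho, d, allow_zero_d = allow_zero_d)
  class(p) <- c("telegraph_params", class(p))
  p
}

#' @export
print.nstate_params <- function(x, ...) {
  cat(sprintf("%d-state promoter model\n", x$N))
  if (x$N > 1L)
    cat("  k:  ", paste(signif(x$k, 4), collapse = ", "), "\n")
  cat(sprintf("  rho: %g   d: %g\n", x$rho, x$d))
  invisible(x)
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat("telegraph (2-state) model\n")
  cat(sprintf("  k1*: %g   k2*: %g   rho*: %g   d: %g\n",
              x$k[1], x$k[2], x$rho, x$d))
  invisible(x)
}

#' Non-dimensionalise rates by the degradation rate
#'
#' Rescales time by the mRNA lifetime: `t -> t*d`, `k -> k/d`, `rho -> rho/d`,
#' `d -> 1`. The steady-state count distribution and all shape/Wasserstein
#' statistics are invariant under this rescaling.
#'
#' @param x An `nstate_params` or `gene_network` object with `d > 0`.
#' @return Object of the same class with unit degradation rate.
#' @export
nondimensionalise <- function(x) UseMethod("nondimensionalise")

#' @export
nondimensionalise.nstate_params <- function(x) {
  if (x$d <= 0)
    stop("cannot non-dimensionalise a model with d = 0", call. = FALSE)
  x$k <- x$k / x$d
  x$rho <- x$rho / x$d
  x$d <- 1
  x
}

is_nstate_params <- function(x) inherits(x, "nstate_params")
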