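#' Laplace transform of the inter-transcription waiting-time density
#'
#' For the irreversible N-state model (`N >= 2`), the waiting time tau between
#' two successive transcription events has Laplace transform
#' \deqn{f^*_N(s) = \frac{\rho \prod_{i<N}(s + k_i)}
#'   {(s + k_N + \rho)\prod_{i<N}(s + k_i) - \prod_{i\le N} k_i}.}
#' `f*_N(0) = 1` (normalisation) and `s f*_N(s) -> rho` as `s -> Inf`, i.e. the
#' density at zero equals the transcription rate.
#'
#' @param params An [nstate_params()] object with `N >= 2`.
#' @param s Non-negative Laplace variable (vectorised).
#' @return `f*_N(s)`, in (0, 1] for `s >= 0`.
#' @export
waiting_time_laplace <- function(params, s) {
  stopifnot(is_nstate_params(params))
  if (params$N < 2L)
    stop(paste("waiting_time_laplace requires N >= 2: for N = 1 there is no",
               "gene-state cycle and the waiting time is exponential with",
               "rate rho (Laplace transform rho/(s + rho))"), call. = FALSE)
  if (any(s < 0)) stop("`s` must be non-negative", call. = FALSE)
  k <- params$k; N <- params$N; rho <- params$rho
  vapply(s, function(si) {
    inact <- prod(si + k[-N])
    rho * inact / ((si + k[N] + rho) * inact - prod(k))
  }, numeric(1))
}

#' Waiting-time statistics of the N-state model
#'
#' Closed-form moments of the inter-transcription waiting time, the gene
#' activation time `tau_{1->N}` (sum of `N - 1` independent exponentials), and
#' the steady-state active-state probability. With `S1 = sum(1/k)` and
#' `S2 = sum(1/k^2)` over all N rates:
#' `mean = (k_N/rho) * S1`, `variance = (k_N/rho) S2 +
#' (k_N/rho)(1 + k_N/rho) S1^2 - (2/rho) S1`, `p_on = 1/(k_N S1)`, and the
#' activation time has mean `sum(1/k[1:(N-1)])` and squared coefficient of
#' variation `sum(1/k[1:(N-1)]^2) / sum(1/k[1:(N-1)])^2`.
#'
#' The effective transcription rate is `1/mean = rho * p_on`, and
#' `variance > mean^2` always holds, which keeps the telegraph mapping
#' positive.
#'
#' @param params An [nstate_params()] object with `N >= 2`.
#' @return Object of class `waiting_time_stats`: list with `f0`, `mean`,
#'   `second_moment`, `variance`, `mean_activation`, `cv2_activation`, `p_on`.
#' @export
waiting_time_stats <- function(params) {
  stopifnot(is_nstate_params(params))
  if (params$N < 2L)
    stop("waiting_time_stats requires N >= 2", call. = FALSE)
  k <- params$k; N <- params$N; rho <- params$rho
  S1 <- sum(1 / k)
  S2 <- sum(1 / k^2)
  kN <- k[N]
  m1 <- kN / rho * S1
  m2 <- 2 * ((1 + kN / rho) * S1 - 1 / kN) * kN / rho * S1 -
    kN / rho * (S1^2 - S2)
  v <- kN / rho * S2 + kN / rho * (1 + kN / rho) * S1^2 - 2 / rho * S1
  ta <- sum(1 / k[-N])
  cv2 <- sum(1 / k[-N]^2) / ta^2
  structure(list(
    f0 = rho,
    mean = m1,
    second_moment = m2,
    variance = v,
    mean_activation = ta,
    cv2_activation = cv2,
    p_on = 1 / (kN * S1)
  ), class = "waiting_time_stats")
}

#' @export
print.waiting_time_stats <- function(x, ...) {
  cat("inter-transcription waiting-time statistics\n")
  cat(sprintf("  f(0) = %g   <tau> = %g   var = %g\n", x$f0, x$mean, x$variance))
  cat(sprintf("  <tau_act> = %g   CV^2_act = %g   P_on = %g\n",
              x$mean_activation, x$cv2_activation, x$p_on))
  invisible(x)
}

#' Map an N-state model onto an effective telegraph model
#'
#' Matches the density at zero and the first two moments of the
#' inter-transcription waiting time between the two models, which yields
#' \deqn{\rho^* = \rho, \quad k_1^* = \frac{1}{\langle\tau_{1\to N}\rangle}
#'   \frac{2}{CV^2_{1\to N} + 1}, \quad
#'   k_2^* = k_N \frac{2}{CV^2_{1\to N} + 1}.}
#' The correction factor `2/(CV^2 + 1)` lies in [1, 2], so the inverse starred
#' switching rates underestimate the mean inactive-period duration
#' `<tau_{1->N}>` and active-period duration `1/k_N` by at most 50%. Both
#' starred rates are guaranteed positive, and the mapping preserves the mean
#' mRNA number (the effective transcription rate `1/<tau>` is matched).
#'
#' @param params An [nstate_params()] object with `N >= 2`.
#' @return A [telegraph_params()] object (degradation rate carried over).
#' @export
map_to_telegraph <- function(params) {
  stopifnot(is_nstate_params(params))
  if (params$N < 2L)
    stop("map_to_telegraph requires N >= 2", call. = FALSE)
  w <- waiting_time_stats(params)
  corr <- 2 / (w$cv2_activation + 1)
  telegraph_params(k1 = corr / w$mean_activation,
                   k2 = corr * params$k[params$N],
                   rho = params$rho, d = params$d,
                   allow_zero_d = params$d == 0)
}
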