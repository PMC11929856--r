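#' Delayed power-law model of the post-induction mean
#'
#' `m(t) = m0 * exp(-d t) + A * (t - t0)^n` for `t >= t0` (and the baseline
#' term alone before `t0`): pre-existing mRNA decays from the stimulus time
#' while the induced transcripts follow the short-time power law shifted by a
#' deterministic delay `t0`.
#'
#' @param t Time since the stimulus.
#' @param A Power-law prefactor (> 0).
#' @param t0 Deterministic delay (>= 0).
#' @param n Power-law exponent (> 0).
#' @param m0 Mean mRNA at stimulus time (>= 0).
#' @param d Degradation rate (default 0, appropriate for fitting windows much
#'   shorter than the mRNA lifetime).
#' @return The model mean at `t`.
#' @export
delayed_power_law <- function(t, A, t0, n, m0, d = 0) {
  m0 * exp(-d * t) + A * pmax(t - t0, 0)^n
}

new_power_law_fit <- function(exponent_n, prefactor_A, delay_t0, baseline_m0,
                              degradation_d, n_points_used, rss, r_squared,
                              method, fitted = NULL) {
  structure(list(exponent_n = exponent_n, prefactor_A = prefactor_A,
                 delay_t0 = delay_t0, baseline_m0 = baseline_m0,
                 degradation_d = degradation_d,
                 n_points_used = n_points_used, rss = rss,
                 r_squared = r_squared, method = method, fitted = fitted),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit (%s): n = %.4g, A = %.4g, t0 = %.4g, m0 = %.4g\n",
              x$method, x$exponent_n, x$prefactor_A, x$delay_t0,
              x$baseline_m0))
  cat(sprintf("  %d points, RSS %.4g%s\n", x$n_points_used, x$rss,
              if (is.finite(x$r_squared))
                sprintf(", r^2 %.5f", x$r_squared) else ""))
  invisible(x)
}

#' Estimate the power-law exponent by log-log linear regression
#'
#' Ordinary least squares on (log t, log mean); the slope is the exponent and
#' the intercept the log prefactor (natural logarithms). Applicable only when
#' the delay and baseline are known to be zero; any non-positive mean is an
#' error (use [fit_delayed_power_law()] instead).
#'
#' @param times Observation times (> 0), at least 3.
#' @param means Mean mRNA counts at `times`.
#' @return A `power_law_fit` (method `"loglog_linear"`); `rss` is in log
#'   space.
#' @export
fit_loglog_exponent <- function(times, means) {
  if (length(times) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(means) != length(times))
    stop("`times` and `means` lengths differ", call. = FALSE)
  if (any(means <= 0))
    stop(paste("all means must be positive for the log-log fit; use",
               "fit_delayed_power_law() for data with zero counts, a delay",
               "or a baseline"), call. = FALSE)
  if (any(times <= 0)) stop("`times` must be positive", call. = FALSE)
  fit <- stats::lm(log(means) ~ log(times))
  co <- stats::coef(fit)
  new_power_law_fit(exponent_n = unname(co[2L]),
                    prefactor_A = exp(unname(co[1L])),
                    delay_t0 = 0, baseline_m0 = 0, degradation_d = 0,
                    n_points_used = length(times),
                    rss = sum(stats::residuals(fit)^2),
                    # summary.lm warns on zero-residual fits; r^2 = 1 is fine
                    r_squared = suppressWarnings(summary(fit)$r.squared),
                    method = "loglog_linear",
                    fitted = exp(stats::fitted(fit)))
}

# One Levenberg-Marquardt run of the delayed power law from a given start.
run_delayed_fit <- function(times, means, w, start, fix_d, t_upper) {
  lower <- c(A = 1e-12, t0 = 0, n = 1e-6, m0 = 0)
  upper <- c(A = Inf, t0 = t_upper, n = 20, m0 = Inf)
  if (!fix_d) { lower <- c(lower, d = 0); upper <- c(upper, d = Inf) }
  df <- data.frame(t = times, y = means)
  form <- if (fix_d) y ~ m0 + A * pmax(t - t0, 0)^n
          else y ~ m0 * exp(-d * t) + A * pmax(t - t0, 0)^n
  args <- list(form, data = df, start = start, lower = lower, upper = upper,
               control = minpack.lm::nls.lm.control(maxiter = 500,
                                                    ftol = 1e-15,
                                                    ptol = 1e-15))
  if (!is.null(w)) args$weights <- w
  tryCatch(suppressWarnings(do.call(minpack.lm::nlsLM, args)),
           error = function(e) NULL)
}

delayed_start_grid <- function(times, means, fix_d, t0_points = 10L,
                               n_grid = 1:5) {
  t0s <- seq(0, 0.95 * max(times), length.out = t0_points)
  starts <- list()
  for (t0 in t0s) for (n in n_grid) {
    # conditional linear least squares for (m0, A) at this (t0, n), d = 0
    X <- cbind(1, pmax(times - t0, 0)^n)
    co <- tryCatch(stats::lm.fit(X, means)$coefficients,
                   error = function(e) c(0, 1))
    m0 <- max(co[1L], 0)
    A <- max(co[2L], 1e-6)
    st <- list(A = A, t0 = t0, n = n, m0 = m0)
    if (!fix_d) st$d <- 0
    starts[[length(starts) + 1L]] <- st
  }
  starts
}

#' Fit the delayed power law to mean mRNA induction curves
#'
#' Non-linear least squares fit of [delayed_power_law()] with the degradation
#' rate fixed at zero by default (appropriate when the observation window is
#' much shorter than the mRNA lifetime). The residual-sum-of-squares surface
#' is multi-modal in the delay, so the fit is multi-started over a grid of
#' delays and integer exponents, with the prefactor and baseline initialised
#' by conditional linear least squares; the best-RSS solution is returned.
#' Inverse-variance weights are used when SEMs are supplied.
#'
#' @param times Observation times (>= 0); at least 5 points recommended.
#' @param means Mean mRNA counts at `times`.
#' @param sems Optional standard errors of the means (weights `1/sem^2`).
#' @param fix_d_to_zero Fix the degradation rate at zero (default) rather
#'   than fitting it.
#' @param t0_points,n_grid Multi-start grid: number of delay values spread
#'   over the observed time range, and candidate integer exponents.
#' @param start Optional single named start (`A`, `t0`, `n`, `m0`, and `d`
#'   when fitted); replaces the grid, with the grid as fallback on failure.
#' @return A `power_law_fit` (method `"nonlinear_delayed"`). A delay fitted
#'   at zero triggers a warning (non-physical for a real induction
#'   experiment).
#' @export
fit_delayed_power_law <- function(times, means, sems = NULL,
                                  fix_d_to_zero = TRUE, t0_points = 10L,
                                  n_grid = 1:5, start = NULL) {
  if (length(times) < 4L)
    stop("need at least 4 points to fit the delayed power law", call. = FALSE)
  if (length(means) != length(times))
    stop("`times` and `means` lengths differ", call. = FALSE)
  w <- if (is.null(sems)) NULL else {
    if (any(sems <= 0)) stop("`sems` must be positive", call. = FALSE)
    1 / sems^2
  }
  starts <- if (is.null(start)) delayed_start_grid(times, means, fix_d_to_zero,
                                                   t0_points, n_grid)
            else c(list(start),
                   delayed_start_grid(times, means, fix_d_to_zero,
                                      t0_points, n_grid))
  best <- NULL; best_rss <- Inf; n_fail <- 0L
  t_upper <- max(times)
  for (st in starts) {
    fit <- run_delayed_fit(times, means, w, st, fix_d_to_zero, t_upper)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best_rss <- rss; best <- fit }
    if (!is.null(start) && !is.null(best)) break  # warm start succeeded
  }
  if (is.null(best))
    stop(sprintf("all %d optimisation starts failed to converge; consider rescaling times or supplying `start`",
                 n_fail), call. = FALSE)
  co <- as.list(stats::coef(best))
  if (co$t0 <= 1e-6 * max(times))
    warning("fitted delay t0 is zero: non-physical result of zero delay",
            call. = FALSE)
  new_power_law_fit(exponent_n = co$n, prefactor_A = co$A, delay_t0 = co$t0,
                    baseline_m0 = co$m0,
                    degradation_d = if (fix_d_to_zero) 0 else co$d,
                    n_points_used = length(times), rss = best_rss,
                    r_squared = NA_real_, method = "nonlinear_delayed",
                    fitted = stats::fitted(best))
}

#' Select the number of early time points to fit
#'
#' The power law holds only at short times, so fits should use an early
#' prefix of the time series. Fits are evaluated on each prefix (the earliest
#' 5, 6, ..., all points) and the longest prefix whose per-point residual sum
#' of squares stays within `rss_factor` of the best per-point RSS is
#' selected. Deterministic given its inputs.
#'
#' @param times,means,sems As in the fitters (assumed time-ordered).
#' @param method Which fitter scores the prefixes.
#' @param rss_factor Allowed per-point RSS inflation over the best prefix.
#' @param min_points Smallest prefix considered.
#' @return Integer vector of selected point indices (a prefix). With fewer
#'   than `min_points` points, all points are returned with a warning.
#' @export
select_fit_points <- function(times, means, sems = NULL,
                              method = c("nonlinear_delayed", "loglog_linear"),
                              rss_factor = 2, min_points = 5L) {
  method <- match.arg(method)
  np <- length(times)
  if (np < min_points) {
    warning(sprintf("fewer than %d points: using all of them", min_points),
            call. = FALSE)
    return(seq_len(np))
  }
  ks <- min_points:np
  per_point <- vapply(ks, function(k) {
    idx <- seq_len(k)
    fit <- tryCatch(switch(method,
      loglog_linear = fit_loglog_exponent(times[idx], means[idx]),
      nonlinear_delayed = suppressWarnings(
        fit_delayed_power_law(times[idx], means[idx], sems[idx]))),
      error = function(e) NULL)
    if (is.null(fit)) Inf else fit$rss / k
  }, numeric(1))
  best <- min(per_point)
  k_sel <- ks[max(which(per_point <= rss_factor * best))]
  seq_len(k_sel)
}

#' Bootstrap the power-law exponent from single-cell counts
#'
#' Resamples cells with replacement within each time point (the cohorts are
#' independent sub-populations), recomputes the per-time means and SEMs, and
#' refits the exponent for each replicate. Replicates after the first are
#' warm-started from the full-data point estimate. Replicate fit failures are
#' skipped and counted; more than `max_failure_frac` failures is an error.
#'
#' @param dataset An `induction_dataset` (per-cell counts).
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @param method Fitting method (see [fit_delayed_power_law()] and
#'   [fit_loglog_exponent()]).
#' @param use_sems Weight the non-linear fits by the replicate SEMs.
#' @param select_points Apply [select_fit_points()] once, on the full data,
#'   and reuse that prefix in every replicate.
#' @param rss_factor Passed to [select_fit_points()].
#' @param max_failure_frac Tolerated fraction of failed replicates.
#' @return Object of class `bootstrap_result`: list with `samples` (fitted
#'   exponents), `median`, `ci` (2.5-97.5 percentile interval),
#'   `n_replicates`, `n_failed`, `seed`, `point_estimate` (the full-data
#'   `power_law_fit`), `points_used`.
#' @export
bootstrap_exponent <- function(dataset, n_replicates = 10000L, seed,
                               method = c("nonlinear_delayed",
                                          "loglog_linear"),
                               use_sems = TRUE, select_points = FALSE,
                               rss_factor = 2, max_failure_frac = 0.2) {
  method <- match.arg(method)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  sm <- dataset_means(dataset)
  idx <- if (select_points)
    select_fit_points(sm$time, sm$mean, sm$sem, method = method,
                      rss_factor = rss_factor)
  else seq_len(nrow(sm))
  fit_once <- function(means, sems, warm) {
    if (method == "loglog_linear")
      fit_loglog_exponent(sm$time[idx], means[idx])
    else
      suppressWarnings(fit_delayed_power_law(
        sm$time[idx], means[idx], if (use_sems) sems[idx],
        start = warm))
  }
  point <- fit_once(sm$mean, pmax(sm$sem, 1e-12), warm = NULL)
  warm <- list(A = point$prefactor_A, t0 = point$delay_t0,
               n = point$exponent_n, m0 = point$baseline_m0)
  groups <- split(dataset$count, dataset$time)
  samples <- numeric(n_replicates); n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    means <- sems <- numeric(length(groups))
    for (g in seq_along(groups)) {
      x <- groups[[g]][sample.int(length(groups[[g]]),
                                  length(groups[[g]]), replace = TRUE)]
      means[g] <- mean(x)
      sems[g] <- stats::sd(x) / sqrt(length(x))
    }
    fit <- tryCatch(fit_once(means, pmax(sems, 1e-12), warm = warm),
                    error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      samples[r] <- NA_real_
    } else samples[r] <- fit$exponent_n
  }
  if (n_failed > max_failure_frac * n_replicates)
    stop(sprintf("%d of %d bootstrap replicates failed to fit", n_failed,
                 n_replicates), call. = FALSE)
  samples <- samples[!is.na(samples)]
  structure(list(samples = samples, median = stats::median(samples),
                 ci = stats::quantile(samples, c(0.025, 0.975), names = FALSE),
                 n_replicates = n_replicates, n_failed = n_failed,
                 seed = seed, point_estimate = point, points_used = idx),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap exponent: median %.3f, 95%% CI [%.3f, %.3f] (%d replicates, %d failed)\n",
              x$median, x$ci[1], x$ci[2], x$n_replicates, x$n_failed))
  invisible(x)
}

#' Benchmark calibration of fitted exponents per model
#'
#' Reruns the biologically constrained benchmark (5 regularly spaced points,
#' final mean in the realistic band) for each `(N, j)` chain model, fits the
#' log-log exponent to the exact ODE means, and records the distribution of
#' fitted exponents. The table maps an observed exponent back to the set of
#' models whose finite-window fits are consistent with it.
#'
#' @param n_sets Parameter sets per `(N, j)` model.
#' @param seed Integer seed.
#' @param Ns Chain sizes to calibrate.
#' @param ranges,mean_band,t_max As in [sample_benchmark_params()].
#' @return Data frame with one row per `(N, j)`: theoretical exponent and the
#'   min, 2.5/50/97.5 percentiles and max of the fitted exponents.
#' @export
build_exponent_calibration <- function(n_sets = 200L, seed, Ns = 2:5,
                                       ranges = benchmark_ranges(),
                                       mean_band = c(1, 25), t_max = 0.15) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (N in Ns) for (j in seq_len(N - 1L)) {
    fitted <- vapply(seq_len(n_sets), function(i) {
      bp <- sample_benchmark_params(N, j, ranges, mean_band, t_max)
      fit_loglog_exponent(bp$times, bp$means)$exponent_n
    }, numeric(1))
    q <- stats::quantile(fitted, c(0.025, 0.5, 0.975), names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(N = N, j = j, exponent_theory = N - j + 1L,
                 fit_min = min(fitted), fit_q025 = q[1], fit_median = q[2],
                 fit_q975 = q[3], fit_max = max(fitted))
  }
  do.call(rbind, rows)
}

#' Report the gene-state lower bound implied by a fitted exponent
#'
#' The theoretical exponent equals the number of gene states visited from the
#' initial inactive state to the active state, and finite-window fits always
#' come out below it, so the number of states visited is at least the fitted
#' exponent rounded up; this is in turn a lower bound on the total number of
#' gene states N. If a calibration table (see
#' [build_exponent_calibration()]) is given, the report also lists the chain
#' models whose finite-window fitted-exponent range covers the observed
#' value. When a second species' fit is supplied (e.g. cytoplasmic vs
#' nuclear, spliced vs unspliced), the exponent difference is interpreted: a
#' difference near one indicates a first-order processing step, near zero a
#' fixed-delay step.
#'
#' @param fit A `power_law_fit` or `bootstrap_result`.
#' @param other Optional second `power_law_fit`/`bootstrap_result` for a
#'   downstream species.
#' @param other_label Label for the second species.
#' @param calibration Optional calibration data frame.
#' @return Object of class `state_bound_report`.
#' @export
report_state_bound <- function(fit, other = NULL,
                               other_label = "downstream species",
                               calibration = NULL) {
  get_exp <- function(f) {
    if (inherits(f, "bootstrap_result"))
      list(exponent = f$median, ci = f$ci)
    else if (inherits(f, "power_law_fit"))
      list(exponent = f$exponent_n, ci = c(NA_real_, NA_real_))
    else stop("expected a power_law_fit or bootstrap_result", call. = FALSE)
  }
  e <- get_exp(fit)
  visited <- as.integer(ceiling(e$exponent - sqrt(.Machine$double.eps)))
  rep <- list(exponent = e$exponent, ci = e$ci,
              states_visited_bound = visited,
              n_states_lower_bound = visited,
              statement = sprintf(
                "number of gene states visited >= %d, hence N >= %d",
                visited, visited))
  if (!is.null(calibration)) {
    cons <- calibration[calibration$fit_min <= e$exponent &
                          e$exponent <= calibration$exponent_theory, ,
                        drop = FALSE]
    rep$consistent_models <- cons[, c("N", "j", "exponent_theory")]
    rep$min_consistent_N <- if (nrow(cons)) min(cons$N) else NA_integer_
  }
  if (!is.null(other)) {
    eo <- get_exp(other)
    diff <- eo$exponent - e$exponent
    rep$other_label <- other_label
    rep$exponent_difference <- diff
    rep$processing_interpretation <-
      if (abs(diff - 1) <= 0.5) "consistent with a first-order processing step"
      else if (abs(diff) < 0.5) "consistent with fixed-delay processing"
      else "indeterminate processing kinetics"
  }
  structure(rep, class = "state_bound_report")
}

#' @export
print.state_bound_report <- function(x, ...) {
  cat(sprintf("fitted exponent %.3f", x$exponent))
  if (all(is.finite(x$ci)))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci[1], x$ci[2]))
  cat("\n", x$statement, "\n", sep = "")
  if (!is.null(x$min_consistent_N))
    cat(sprintf("calibration-consistent models: smallest N = %s\n",
                x$min_consistent_N))
  if (!is.null(x$exponent_difference))
    cat(sprintf("%s exponent difference %.3f: %s\n", x$other_label,
                x$exponent_difference, x$processing_interpretation))
  invisible(x)
}
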