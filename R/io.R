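#' Read and write induction datasets as CSV with a JSON sidecar
#'
#' The CSV holds one row per cell (`cell_id, time, count[, species]`); the
#' JSON sidecar carries the generating ground truth and seed, when known.
#'
#' @param dataset An `induction_dataset`.
#' @param path CSV output path.
#' @param sidecar_path JSON sidecar path (default: `path` with `.json`).
#' @return Invisibly, `path`.
#' @export
write_induction_csv <- function(dataset, path,
                                sidecar_path = sub("\\.csv$", ".json", path)) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  meta <- attr(dataset, "meta")
  gt <- attr(dataset, "ground_truth")
  side <- list(seed = meta$seed, capture_p = meta$capture_p)
  if (!is.null(meta$model) && is_nstate_params(meta$model))
    side$model <- list(N = meta$model$N, k = meta$model$k,
                       rho = meta$model$rho, d = meta$model$d)
  side$j <- meta$j
  side$t0 <- meta$t0
  side$m0 <- meta$m0
  if (!is.null(gt))
    side$ground_truth <- list(exponent = gt$exponent, times = gt$times,
                              ode_means = gt$ode_means)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_induction_csv
#' @export
read_induction_csv <- function(path,
                               sidecar_path = sub("\\.csv$", ".json", path)) {
  out <- utils::read.csv(path)
  need <- c("cell_id", "time", "count")
  if (!all(need %in% names(out)))
    stop("induction CSV needs columns cell_id, time, count", call. = FALSE)
  if (any(out$count < 0)) stop("counts must be >= 0", call. = FALSE)
  if (file.exists(sidecar_path))
    attr(out, "meta") <- jsonlite::read_json(sidecar_path,
                                             simplifyVector = TRUE)
  class(out) <- c("induction_dataset", class(out))
  out
}

#' Read a mean-and-SEM summary table
#'
#' Accepts the summary format `time, mean, sem, n_cells` (SEM and cell
#' numbers optional) used when per-cell counts are unavailable.
#'
#' @param path CSV path.
#' @return Data frame with columns `time`, `mean` and, when present, `sem`,
#'   `n_cells`, sorted by time.
#' @export
read_mean_sem_csv <- function(path) {
  out <- utils::read.csv(path)
  if (!all(c("time", "mean") %in% names(out)))
    stop("summary CSV needs columns time and mean", call. = FALSE)
  out[order(out$time), , drop = FALSE]
}

#' Write a moment trajectory as tidy CSV
#'
#' Long format with columns `time`, `quantity`, `value`, covering the mean,
#' second moment, variance, Fano factor and any downstream-species means.
#'
#' @param traj A trajectory from [integrate_moment_odes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  qty <- setdiff(names(traj), "time")
  long <- do.call(rbind, lapply(qty, function(q)
    data.frame(time = traj$time, quantity = q, value = traj[[q]])))
  utils::write.csv(long[order(long$time), ], path, row.names = FALSE)
  invisible(path)
}

#' Write a count distribution as two-column CSV
#'
#' @param dist A [count_distribution()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distribution_csv <- function(dist, path) {
  utils::write.csv(data.frame(count = seq_along(dist$probs) - 1L,
                              probability = dist$probs),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  df <- utils::read.csv(path)
  count_distribution(df$probability / sum(df$probability))
}
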