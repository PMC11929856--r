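# Deterministic fixture generation: small, versioned test inputs covering the
# four steady-state shape classes, finite-cell induction datasets with known
# ground truth, and a delayed yeast-like dataset on a minutes time base.

# Parameter sets whose stationary distributions realise the four shape
# classes (rates in units of d). Shape IV uses the intermediate-switching
# regime: slow exit from the active state (k_N/d < 1) with fast inactive
# transitions (k_i/d >= 1) and high transcription.
shape_class_params <- function() {
  list(
    I = nstate_params(3, k = c(5, 5, 2), rho = 8, d = 1),
    II = nstate_params(3, k = c(1, 1, 8), rho = 60, d = 1),
    III = telegraph_params(k1 = 0.1, k2 = 0.1, rho = 40, d = 1),
    IV = nstate_params(5, k = c(2, 2, 2, 2, 0.3), rho = 40, d = 1)
  )
}

# Delayed power-law generator mimicking an osmotic-stress response gene in
# budding yeast: minutes time base, ~3 min stimulus-to-initiation delay,
# small pre-existing mRNA, exponent 2 (as fitted for nuclear mRNA of
# osmotic-stress genes) and a mean reaching the high teens within the hour.
# Per-cell counts are Poisson around the delayed-power-law mean, so the
# configured delay is exactly the fitted model's estimand; full chain
# kinetics (where finite-window fits are deliberately biased) are covered by
# the induction fixtures instead.
yeast_like_config <- function() {
  list(A = 0.005, t0 = 3, n = 2, m0 = 0.5,
       obs_times = c(2, 4, 6, 8, 11, 15, 20, 30, 45, 60),
       n_cells = 2000L)
}

#' Build the deterministic fixture collection
#'
#' Writes (a) one steady-state count distribution per shape class with its
#' classifier label; (b) SSA induction datasets with known ground truth for
#' chain models `(N, j)` in (2,1), (3,1), (5,1), (5,4) at 100 and 1000 cells
#' per time point, each under the realistic final-mean constraint; and (c) a
#' delayed dataset on a minutes time base mimicking a yeast induction
#' protocol (`t0 > 0`, `m0 > 0`, mRNA half-life about 11 min). All outputs
#' are plain CSV/JSON; a manifest records the generating config, seed, ground
#' truth and an md5 checksum per file, and regeneration from the same seed is
#' bit-identical.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param seed Integer seed.
#' @param n_cells Cohort sizes for the induction fixtures.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
build_fixtures <- function(out_dir, seed, n_cells = c(100L, 1000L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(name, file, ground_truth) {
    manifest[[length(manifest) + 1L]] <<- list(
      name = name, file = basename(file), seed = seed,
      ground_truth = ground_truth,
      md5 = unname(tools::md5sum(file)))
  }
  # (a) shape-class distributions
  for (lab in names(shape_class_params())) {
    p <- shape_class_params()[[lab]]
    dist <- steady_state_distribution(p)
    sh <- classify_shape(dist)
    f <- file.path(out_dir, sprintf("shape_%s.csv", lab))
    write_distribution_csv(dist, f)
    add(sprintf("shape_%s", lab), f,
        list(label = sh$label, fano = sh$fano, modes = sh$modes,
             N = p$N, k = p$k, rho = p$rho, d = p$d))
  }
  # (b) induction datasets with known ground truth
  combos <- list(c(2L, 1L), c(3L, 1L), c(5L, 1L), c(5L, 4L))
  set.seed(seed)
  for (cb in combos) for (nc in n_cells) {
    N <- cb[1L]; j <- cb[2L]
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    suite <- generate_benchmark_suite(1L, N, j, n_cells = nc, seed = sub_seed)
    ds <- suite[[1L]]
    f <- file.path(out_dir, sprintf("induction_N%d_j%d_n%d.csv", N, j, nc))
    write_induction_csv(ds, f)
    gt <- attr(ds, "ground_truth")
    add(sprintf("induction_N%d_j%d_n%d", N, j, nc), f,
        list(N = N, j = j, exponent = gt$exponent, k = gt$params$k,
             rho = gt$params$rho, d = gt$params$d, times = gt$times,
             ode_means = gt$ode_means, n_cells = nc))
  }
  # (c) delayed yeast-like dataset (minutes time base)
  yc <- yeast_like_config()
  sub_seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(sub_seed)
  lam <- delayed_power_law(rep(yc$obs_times, each = yc$n_cells),
                           yc$A, yc$t0, yc$n, yc$m0)
  ds <- data.frame(cell_id = seq_along(lam),
                   time = rep(yc$obs_times, each = yc$n_cells),
                   count = stats::rpois(length(lam), lam))
  attr(ds, "meta") <- list(model = NULL, j = NULL, n_cells = yc$n_cells,
                           capture_p = 1, noise = NULL, seed = sub_seed,
                           t0 = yc$t0, m0 = yc$m0)
  class(ds) <- c("induction_dataset", class(ds))
  f <- file.path(out_dir, "yeast_like_delayed.csv")
  write_induction_csv(ds, f)
  add("yeast_like_delayed", f,
      list(A = yc$A, t0 = yc$t0, n = yc$n, m0 = yc$m0,
           time_unit = "minutes", n_cells = yc$n_cells))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
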