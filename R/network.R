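#' General gene-state network with synthesis and reset
#'
#' A model with `n_states` gene states connected by arbitrary (possibly
#' reversible) first-order transitions `rates[i, j]` (state i -> j), a single
#' active state from which mRNA is synthesised at rate `rho`, a reset state
#' entered upon synthesis (`reset_state == active_state` means no state change,
#' as in the irreversible chain), and degradation at rate `d`. Reset to a state
#' other than the active one models transcriptional reinitiation or
#' promoter-proximal pausing.
#'
#' @param n_states Number of gene states.
#' @param rates `n_states x n_states` matrix of non-negative transition rates
#'   with zero diagonal.
#' @param rho Synthesis rate from the active state (> 0).
#' @param d mRNA degradation rate (>= 0).
#' @param active_state Index of the active state (default: last state).
#' @param reset_state Gene state entered when a transcript is made
#'   (default: `active_state`, i.e. no change).
#' @return Object of class `gene_network`.
#' @export
gene_network <- function(n_states, rates, rho, d,
                         active_state = n_states, reset_state = active_state) {
  n_states <- as.integer(n_states)
  rates <- as.matrix(rates)
  if (!all(dim(rates) == n_states))
    stop("`rates` must be an n_states x n_states matrix", call. = FALSE)
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("transition rates must be finite and non-negative", call. = FALSE)
  if (any(diag(rates) != 0))
    stop("`rates` must have a zero diagonal", call. = FALSE)
  if (active_state < 1L || active_state > n_states ||
      reset_state < 1L || reset_state > n_states)
    stop("active_state and reset_state must be valid state indices",
         call. = FALSE)
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (!is.finite(d) || d < 0) stop("d must be >= 0", call. = FALSE)
  structure(list(n_states = n_states, rates = rates,
                 active_state = as.integer(active_state),
                 reset_state = as.integer(reset_state),
                 rho = as.numeric(rho), d = as.numeric(d)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  ne <- sum(x$rates > 0)
  cat(sprintf("gene network: %d states, %d transitions, active %d, reset %d\n",
              x$n_states, ne, x$active_state, x$reset_state))
  cat(sprintf("  rho: %g   d: %g\n", x$rho, x$d))
  invisible(x)
}

#' Represent the irreversible N-state chain as a gene network
#'
#' Builds the network with edges `i -> i+1` at rate `k[i]` and `N -> 1` at
#' rate `k[N]`, active state `N` and no reset on synthesis.
#'
#' @param params An [nstate_params()] object.
#' @return A [gene_network()] carrying attribute `"chain"` (the source
#'   parameters), used where closed-form chain results apply.
#' @export
chain_network <- function(params) {
  stopifnot(is_nstate_params(params))
  N <- params$N
  rates <- matrix(0, N, N)
  if (N > 1L) {
    for (i in seq_len(N - 1L)) rates[i, i + 1L] <- params$k[i]
    rates[N, 1L] <- params$k[N]
  }
  net <- gene_network(N, rates, rho = params$rho, d = params$d,
                      active_state = N, reset_state = N)
  attr(net, "chain") <- params
  net
}

#' @export
nondimensionalise.gene_network <- function(x) {
  if (x$d <= 0)
    stop("cannot non-dimensionalise a model with d = 0", call. = FALSE)
  ch <- attr(x, "chain")
  x$rates <- x$rates / x$d
  x$rho <- x$rho / x$d
  x$d <- 1
  if (!is.null(ch)) attr(x, "chain") <- nondimensionalise(ch)
  x
}

as_gene_network <- function(x) {
  if (inherits(x, "gene_network")) x
  else if (is_nstate_params(x)) chain_network(x)
  else stop("expected an nstate_params or gene_network object", call. = FALSE)
}

#' Read or write a model configuration file
#'
#' Flat key-value schema shared by all modules:
#' `{N, k, rho, d, j, initial_state_distribution}` for chain models, or
#' `{n_states, edges: [{from, to, rate}, ...], active_state, reset_state,
#' rho, d}` for general networks. Format chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path Config file path.
#' @return For `read_model_config`: a list with elements `model`
#'   (an [nstate_params()] or [gene_network()]), `j` (initial state, possibly
#'   `NULL`) and `initial_state_distribution` (possibly `NULL`).
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$edges)) {
    ed <- as.data.frame(cfg$edges)
    rates <- matrix(0, cfg$n_states, cfg$n_states)
    rates[cbind(ed$from, ed$to)] <- ed$rate
    model <- gene_network(cfg$n_states, rates, rho = cfg$rho, d = cfg$d,
                          active_state = cfg$active_state %||% cfg$n_states,
                          reset_state = cfg$reset_state %||%
                            (cfg$active_state %||% cfg$n_states))
  } else {
    model <- nstate_params(cfg$N, unlist(cfg$k), rho = cfg$rho, d = cfg$d,
                           allow_zero_d = isTRUE(cfg$d == 0))
  }
  list(model = model, j = cfg$j,
       initial_state_distribution = cfg$initial_state_distribution)
}

#' @rdname read_model_config
#' @param model An [nstate_params()] or [gene_network()].
#' @param j Optional initial inactive state recorded alongside the rates.
#' @param initial_state_distribution Optional probability vector over states.
#' @export
write_model_config <- function(model, path, j = NULL,
                               initial_state_distribution = NULL) {
  cfg <- if (is_nstate_params(model)) {
    list(N = model$N, k = model$k, rho = model$rho, d = model$d)
  } else {
    nz <- which(model$rates > 0, arr.ind = TRUE)
    list(n_states = model$n_states,
         edges = data.frame(from = nz[, 1], to = nz[, 2],
                            rate = model$rates[nz]),
         active_state = model$active_state, reset_state = model$reset_state,
         rho = model$rho, d = model$d)
  }
  cfg$j <- j
  cfg$initial_state_distribution <- initial_state_distribution
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
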