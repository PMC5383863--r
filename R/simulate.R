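#' Simulation configuration
#'
#' Describes a full experiment: the substrate network, the game parameters,
#' the relaxation/measurement schedule and the ensemble size. Defaults follow
#' the reference protocol: scale-free substrate from the uncorrelated
#' configuration model with `gamma = 2.5`, `kmin = 2`, `kmax = sqrt(N)`,
#' `N = 10^4` players, 5x10^4 relaxation rounds, 10^3 measurement rounds and
#' 500 replicates — scale `N`, the schedule and `n_runs` down for desk work.
#'
#' The substrate is resolved per run: a fresh configuration-model graph is
#' drawn for every replicate unless a fixed `graph` object or an `edge_list`
#' path is supplied.
#'
#' @param N,gamma,kmin,kmax degree-sequence parameters (see
#'   [sample_degree_sequence()]); `kmax = NULL` means `floor(sqrt(N))`.
#' @param graph optional fixed `igraph` substrate reused by every run.
#' @param edge_list optional path to a plain-text edge list, read once and
#'   reused by every run.
#' @param r,c,alpha,scheme,update_rule,beta see [game_params()].
#' @param coop_prob initial cooperation probability.
#' @param t_relax relaxation rounds (>= 0) discarded before measuring.
#' @param t_measure measurement rounds (>= 1) over which observables are
#'   time-averaged.
#' @param n_runs independent replicates (>= 1).
#' @param master_seed integer seed from which per-run seeds are derived.
#' @param keep_snapshots keep each run's steady-state snapshot (needed for
#'   the investment/production/link analyses).
#' @return An object of class `pgg_config`.
#' @export
sim_config <- function(N = 10000L, gamma = 2.5, kmin = 2L, kmax = NULL,
                       graph = NULL, edge_list = NULL,
                       r = 4, c = 1, alpha = 0, scheme = "FCP",
                       update_rule = "replicator", beta = 1,
                       coop_prob = 0.5,
                       t_relax = 50000L, t_measure = 1000L,
                       n_runs = 500L, master_seed = 1L,
                       keep_snapshots = TRUE) {
  params <- game_params(r = r, c = c, alpha = alpha, scheme = scheme,
                        update_rule = update_rule, beta = beta)
  if (t_relax < 0L) stop("t_relax must be >= 0")
  if (t_measure < 1L) stop("t_measure must be >= 1")
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (coop_prob < 0 || coop_prob > 1) stop("coop_prob must be in [0, 1]")
  if (!is.null(graph) && !igraph::is_igraph(graph))
    stop("graph must be an igraph object")
  if (is.null(graph) && is.null(edge_list)) {
    if (is.null(kmax)) kmax <- floor(sqrt(N))
    # validated here so a bad network spec fails before any run starts
    if (N < 3L) stop("N must be >= 3")
    if (gamma <= 1) stop("gamma must be > 1")
    if (kmin < 1L || kmin > kmax || kmax >= N) stop("invalid kmin/kmax bounds")
  }
  structure(list(N = as.integer(N), gamma = gamma, kmin = as.integer(kmin),
                 kmax = if (is.null(kmax)) NULL else as.integer(kmax),
                 graph = graph, edge_list = edge_list,
                 params = params, coop_prob = coop_prob,
                 t_relax = as.integer(t_relax),
                 t_measure = as.integer(t_measure),
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 keep_snapshots = isTRUE(keep_snapshots)),
            class = "pgg_config")
}

#' Per-run seed derivation
#'
#' Fixed counter-based rule `seed_k = (master + k * 100003) mod (2^31 - 20) + 1`
#' mapping the master seed and the 1-based run index to independent run seeds.
#'
#' @param master_seed integer master seed.
#' @param run_index 1-based replicate index.
#' @return An integer seed.
#' @export
derive_run_seed <- function(master_seed, run_index) {
  as.integer((as.numeric(master_seed) + as.numeric(run_index) * 100003) %%
               2147483627) + 1L
}

.resolve_graph <- function(config) {
  if (!is.null(config$graph)) return(config$graph)
  if (!is.null(config$edge_list)) return(read_edge_list(config$edge_list))
  ds <- sample_degree_sequence(config$N, config$gamma, config$kmin,
                               if (is.null(config$kmax)) floor(sqrt(config$N))
                               else config$kmax)
  build_ucm_graph(ds)
}

#' Run one replicate to its steady state
#'
#' Seeds the RNG with `run_seed`, draws the substrate (fresh per run unless
#' the config pins one), initializes the state, relaxes for `t_relax` rounds
#' and then measures for `t_measure` rounds, accumulating time averages of
#' the investments, the contributions `I * s`, the per-pair payoffs and the
#' per-node payoff totals, plus the cooperator-fraction trajectory.
#'
#' @param config a [sim_config()] object.
#' @param run_seed integer seed for this replicate.
#' @return An object of class `pgg_run`: `fc` (per-measured-round cooperator
#'   fraction), `fc_mean`, `absorbed`/`t_absorbed` (uniform-strategy
#'   detection), `M`, `run_seed` and `snapshot` (class `pgg_snapshot`) holding
#'   the window averages, the final instantaneous `s`/`I`, the pair geometry
#'   and the graph.
#' @export
run_single <- function(config, run_seed) {
  set.seed(run_seed)
  g <- .resolve_graph(config)
  params <- config$params
  state <- initial_state(g, params, seed = NULL, coop_prob = config$coop_prob)
  M <- normalization_constant(g, params)
  st <- state$struct
  res <- cpp_run(st$inv - 1L, st$focal - 1L, st$inv_ptr,
                 st$adj - 1L, st$adj_ptr, st$deg, state$cap,
                 state$s, state$I,
                 params$r, params$alpha, .rule_code(params$update_rule),
                 params$beta, M,
                 config$t_relax, config$t_measure)
  snapshot <- structure(list(avg_I = res$avg_I, avg_C = res$avg_C,
                             avg_Pi_pair = res$avg_pi_pair,
                             avg_Pi_tot = res$avg_pi_tot,
                             s = res$s_final, I = res$I_final,
                             cap = state$cap, struct = st, graph = g,
                             params = params),
                        class = "pgg_snapshot")
  structure(list(fc = res$fc, fc_mean = mean(res$fc),
                 absorbed = res$t_absorbed >= 0L,
                 t_absorbed = res$t_absorbed,
                 M = M, run_seed = run_seed, snapshot = snapshot),
            class = "pgg_run")
}

#' Run an ensemble of independent replicates
#'
#' Replicate seeds are derived from `master_seed` by [derive_run_seed()], so
#' two ensembles with the same configuration and master seed are identical.
#'
#' @param config a [sim_config()] object.
#' @param progress optional function called as `progress(k, n_runs)` after
#'   each completed replicate.
#' @return An object of class `pgg_ensemble`: per-run steady-state cooperator
#'   fractions `fc_runs` with their mean and standard error, the run seeds,
#'   and (when `keep_snapshots`) the list of `pgg_run` results.
#' @export
run_ensemble <- function(config, progress = NULL) {
  seeds <- vapply(seq_len(config$n_runs), derive_run_seed,
                  integer(1L), master_seed = config$master_seed)
  runs <- lapply(seq_along(seeds), function(k) {
    out <- run_single(config, seeds[[k]])
    if (!is.null(progress)) progress(k, length(seeds))
    out
  })
  fc_runs <- vapply(runs, function(x) x$fc_mean, numeric(1L))
  fc_se <- if (length(fc_runs) > 1L) sd(fc_runs) / sqrt(length(fc_runs)) else NA_real_
  structure(list(config = config, seeds = seeds,
                 fc_runs = fc_runs, fc_mean = mean(fc_runs), fc_se = fc_se,
                 M = runs[[1L]]$M,
                 runs = if (config$keep_snapshots) runs else NULL),
            class = "pgg_ensemble")
}

#' Sweep the synergy factor or the allocation intensity
#'
#' Runs one ensemble per value of `r` or `alpha`, all other settings fixed.
#'
#' @param config a [sim_config()] object (its `master_seed` is reused for
#'   every value, so sweeps differ only through the swept parameter).
#' @param parameter `"r"` or `"alpha"`.
#' @param values non-empty numeric vector of parameter values.
#' @param keep_ensembles attach the full ensembles as attribute
#'   `"ensembles"` (default `FALSE`).
#' @return A `data.frame` with columns `value`, `fc_mean`, `fc_se`, `n_runs`,
#'   sorted by `value`.
#' @export
sweep_parameter <- function(config, parameter = c("r", "alpha"), values,
                            keep_ensembles = FALSE) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop("values must be non-empty")
  values <- sort(as.numeric(values))
  ensembles <- lapply(values, function(v) {
    cfg <- config
    cfg$params[[parameter]] <- v
    # re-validate through the constructor invariants
    cfg$params <- do.call(game_params, unclass(cfg$params))
    if (!keep_ensembles) cfg$keep_snapshots <- FALSE
    run_ensemble(cfg)
  })
  out <- data.frame(value = values,
                    fc_mean = vapply(ensembles, function(e) e$fc_mean, numeric(1L)),
                    fc_se = vapply(ensembles, function(e) e$fc_se, numeric(1L)),
                    n_runs = config$n_runs)
  if (keep_ensembles) attr(out, "ensembles") <- ensembles
  out
}
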