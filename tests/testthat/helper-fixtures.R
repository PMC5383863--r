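# Shared fixtures and independent oracles for the test suite.

# Analytic mean of the truncated power law P(k) ~ k^-gamma on kmin..kmax.
powerlaw_mean_degree <- function(gamma, kmin, kmax) {
  k <- kmin:kmax
  sum(k * k^(-gamma)) / sum(k^(-gamma))
}

# Brute-force oracle for the ranked-share statistic: the smallest subset of
# games (of any composition, found by exhaustive enumeration) whose summed
# production reaches the share q. For non-negative values this minimum is
# attained by top-ranked subsets, which is what pareto_q exploits.
pareto_brute <- function(w, q) {
  total <- sum(w)
  n <- length(w)
  for (m in seq_len(n)) {
    sums <- combn(w, m, sum)
    if (any(sums >= q * total - 1e-12)) return(m / n)
  }
  1
}

# A 2x3 grid graph: degrees {2, 3}, small enough for hand inspection.
make_grid23 <- function() {
  igraph::make_lattice(c(2, 3))
}

# Build a state with prescribed strategies and per-pair investments.
state_with <- function(g, params, s, I = NULL) {
  st <- initial_state(g, params, coop_prob = 1)
  st$s <- as.integer(s)
  if (!is.null(I)) st$I <- I
  st
}

# Memoised scaled-down steady-state ensembles reused across acceptance
# checks (N = 2000, gamma = 2.5, kmin = 2, kmax = 44, 10^4 relaxation and
# 10^3 measurement rounds, 10 replicates).
.acc_cache <- new.env(parent = emptyenv())

acceptance_ensemble <- function(alpha, r) {
  key <- paste0("a", alpha, "_r", r)
  if (is.null(.acc_cache[[key]])) {
    cfg <- sim_config(N = 2000, gamma = 2.5, kmin = 2, kmax = 44,
                      r = r, alpha = alpha,
                      t_relax = 10000, t_measure = 1000,
                      n_runs = 10, master_seed = 101)
    .acc_cache[[key]] <- run_ensemble(cfg)
  }
  .acc_cache[[key]]
}

ensemble_stat <- function(ens, fn) {
  vals <- vapply(ens$runs, function(run) fn(run$snapshot), numeric(1L))
  list(values = vals, mean = mean(vals), se = sd(vals) / sqrt(length(vals)))
}
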