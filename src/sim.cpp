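#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pair layout: every ordered participation (investor i, focal j) with j in
// nu_i = {i} + neighbors(i), grouped contiguously by investor (inv_ptr is the
// CSR boundary vector, length N+1). All indices 0-based on the C++ side.

static void pot_kernel(const int P, const int* inv, const int* focal,
                       const double* I, const int* s, const int N, double* pot) {
  std::fill(pot, pot + N, 0.0);
  for (int p = 0; p < P; ++p) pot[focal[p]] += I[p] * s[inv[p]];
}

// Per-game payoff: Pi[i,j] = r/(k_j+1) * pot_j - I[i,j]*s_i; totals by investor.
static void payoff_kernel(const int P, const int N, const int* inv, const int* focal,
                          const double* I, const int* s, const int* deg, double r,
                          double* pot, double* share, double* pi_pair, double* pi_tot) {
  pot_kernel(P, inv, focal, I, s, N, pot);
  for (int j = 0; j < N; ++j) share[j] = r / (deg[j] + 1.0) * pot[j];
  std::fill(pi_tot, pi_tot + N, 0.0);
  for (int p = 0; p < P; ++p) {
    const double pi = share[focal[p]] - I[p] * s[inv[p]];
    pi_pair[p] = pi;
    pi_tot[inv[p]] += pi;
  }
}

// Softmax reallocation: I[i,j] <- cap_i * exp(a*Pi[i,j]) / sum_l exp(a*Pi[i,l]),
// shifted by the row maximum for numerical stability.
static void allocate_kernel(const int N, const int* inv_ptr, const double* pi_pair,
                            const double* cap, double alpha, double* I) {
  for (int i = 0; i < N; ++i) {
    const int a = inv_ptr[i], b = inv_ptr[i + 1];
    if (b <= a) continue;
    double m = pi_pair[a];
    for (int p = a + 1; p < b; ++p) if (pi_pair[p] > m) m = pi_pair[p];
    double tot = 0.0;
    for (int p = a; p < b; ++p) {
      const double w = std::exp(alpha * (pi_pair[p] - m));
      I[p] = w;
      tot += w;
    }
    const double f = cap[i] / tot;
    for (int p = a; p < b; ++p) I[p] *= f;
  }
}

static inline int pick_neighbor(const int* adj, int off, int k) {
  int idx = (int)(unif_rand() * k);
  if (idx >= k) idx = k - 1;
  return adj[off + idx];
}

// rule: 0 replicator (normalized by M), 1 unconditional imitation, 2 Fermi.
// Synchronous: s_new computed from the frozen s/payoffs; RNG consumed in node
// order 0..N-1 for reproducibility.
static void update_kernel(const int N, const int* adj, const int* adj_ptr,
                          const int* s, const double* pi_tot,
                          int rule, double M, double beta, int* s_new) {
  for (int i = 0; i < N; ++i) {
    const int off = adj_ptr[i], k = adj_ptr[i + 1] - off;
    s_new[i] = s[i];
    if (k == 0) continue;  // isolated node keeps its strategy
    if (rule == 0) {       // replicator-like, P = (Pi_j - Pi_i)/M
      const int j = pick_neighbor(adj, off, k);
      const double d = pi_tot[j] - pi_tot[i];
      if (d > 0.0 && unif_rand() < d / M) s_new[i] = s[j];
    } else if (rule == 1) { // imitate the best of nu_i (self included)
      double best = pi_tot[i];
      for (int p = off; p < off + k; ++p)
        if (pi_tot[adj[p]] > best) best = pi_tot[adj[p]];
      if (pi_tot[i] >= best) continue; // keep on ties involving self
      int nbest = 0;
      for (int p = off; p < off + k; ++p) if (pi_tot[adj[p]] == best) ++nbest;
      int pickv = 0;
      if (nbest > 1) {
        pickv = (int)(unif_rand() * nbest);
        if (pickv >= nbest) pickv = nbest - 1;
      }
      for (int p = off; p < off + k; ++p) {
        if (pi_tot[adj[p]] == best) {
          if (pickv == 0) { s_new[i] = s[adj[p]]; break; }
          --pickv;
        }
      }
    } else {               // Fermi: P = 1/(1 + exp(-beta (Pi_j - Pi_i)))
      const int j = pick_neighbor(adj, off, k);
      const double pr = 1.0 / (1.0 + std::exp(-beta * (pi_tot[j] - pi_tot[i])));
      if (unif_rand() < pr) s_new[i] = s[j];
    }
  }
}

// [[Rcpp::export]]
List cpp_payoffs(IntegerVector inv, IntegerVector focal, NumericVector I,
                 IntegerVector s, IntegerVector deg, double r) {
  const int P = inv.size(), N = deg.size();
  NumericVector pot(N), share(N), pi_pair(P), pi_tot(N);
  payoff_kernel(P, N, inv.begin(), focal.begin(), I.begin(), s.begin(),
                deg.begin(), r, pot.begin(), share.begin(),
                pi_pair.begin(), pi_tot.begin());
  return List::create(_["pot"] = pot, _["pi_pair"] = pi_pair, _["pi_tot"] = pi_tot);
}

// [[Rcpp::export]]
NumericVector cpp_allocate(NumericVector pi_pair, IntegerVector inv_ptr,
                           NumericVector cap, double alpha) {
  const int N = cap.size();
  NumericVector I(pi_pair.size());
  allocate_kernel(N, inv_ptr.begin(), pi_pair.begin(), cap.begin(), alpha, I.begin());
  return I;
}

// [[Rcpp::export]]
IntegerVector cpp_update(IntegerVector s, NumericVector pi_tot, IntegerVector adj,
                         IntegerVector adj_ptr, int rule, double M, double beta) {
  const int N = s.size();
  IntegerVector s_new(N);
  update_kernel(N, adj.begin(), adj_ptr.begin(), s.begin(), pi_tot.begin(),
                rule, M, beta, s_new.begin());
  return s_new;
}

// Fused round loop: per step (1) payoffs from current I, s; (2) synchronous
// strategy update from payoff totals; (3) reallocation for t+1 from this
// round's per-game payoffs. Steps t_relax..t_relax+t_measure-1 accumulate
// time averages of I, contributions I*s, per-pair and per-node payoffs, and
// record the cooperator fraction at payoff time.
// [[Rcpp::export]]
List cpp_run(IntegerVector inv, IntegerVector focal, IntegerVector inv_ptr,
             IntegerVector adj, IntegerVector adj_ptr, IntegerVector deg,
             NumericVector cap, IntegerVector s0, NumericVector I0,
             double r, double alpha, int rule, double beta, double M,
             int t_relax, int t_measure) {
  const int P = inv.size(), N = deg.size();
  std::vector<int> s(s0.begin(), s0.end()), s_new(N);
  std::vector<double> I(I0.begin(), I0.end());
  std::vector<double> pot(N), share(N), pi_pair(P), pi_tot(N);
  NumericVector fc(t_measure);
  NumericVector avg_I(P), avg_C(P), avg_pp(P), avg_pt(N);
  int t_absorbed = -1;
  const int T = t_relax + t_measure;

  for (int t = 0; t < T; ++t) {
    payoff_kernel(P, N, inv.begin(), focal.begin(), I.data(), s.data(),
                  deg.begin(), r, pot.data(), share.data(),
                  pi_pair.data(), pi_tot.data());
    int ns = 0;
    for (int i = 0; i < N; ++i) ns += s[i];
    if (t_absorbed < 0 && (ns == 0 || ns == N)) t_absorbed = t;
    if (t >= t_relax) {
      const int m = t - t_relax;
      fc[m] = (double)ns / N;
      for (int p = 0; p < P; ++p) {
        avg_I[p] += I[p];
        avg_C[p] += I[p] * s[inv[p]];
        avg_pp[p] += pi_pair[p];
      }
      for (int i = 0; i < N; ++i) avg_pt[i] += pi_tot[i];
    }
    update_kernel(N, adj.begin(), adj_ptr.begin(), s.data(), pi_tot.data(),
                  rule, M, beta, s_new.data());
    s.swap(s_new);
    allocate_kernel(N, inv_ptr.begin(), pi_pair.data(), cap.begin(), alpha, I.data());
  }
  const double inv_m = 1.0 / t_measure;
  for (int p = 0; p < P; ++p) {
    avg_I[p] *= inv_m; avg_C[p] *= inv_m; avg_pp[p] *= inv_m;
  }
  for (int i = 0; i < N; ++i) avg_pt[i] *= inv_m;

  return List::create(
    _["fc"] = fc,
    _["avg_I"] = avg_I, _["avg_C"] = avg_C,
    _["avg_pi_pair"] = avg_pp, _["avg_pi_tot"] = avg_pt,
    _["s_final"] = IntegerVector(s.begin(), s.end()),
    _["I_final"] = NumericVector(I.begin(), I.end()),
    _["pi_pair_last"] = NumericVector(pi_pair.begin(), pi_pair.end()),
    _["pi_tot_last"] = NumericVector(pi_tot.begin(), pi_tot.end()),
    _["t_absorbed"] = t_absorbed);
}
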