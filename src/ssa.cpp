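#include <Rcpp.h>
using namespace Rcpp;

// Exact (direct-method) stochastic simulation of a gene-state network with
// mRNA synthesis from one active state (with optional state reset) and
// first-order degradation. Each cell is simulated independently from zero
// mRNA and observed at a single assigned time. Rate matrices may be shared
// (one column) or per-cell (one column per cell, for static extrinsic
// noise). Propensities are summed in a fixed order so seeded runs are
// bit-reproducible across platforms. Uses R's RNG.

// [[Rcpp::export]]
IntegerVector ssa_counts_cpp(int n_states,
                             NumericMatrix rates,   // n_states^2 x (1 | n_cells), column-major k[i,j] at (j-1)*n+(i-1)
                             NumericVector rho,     // length 1 or n_cells
                             NumericVector d,       // length 1 or n_cells
                             int active, int reset, // 1-based
                             IntegerVector init_state, // 1-based, length n_cells
                             NumericVector obs_time) { // length n_cells
  const int n_cells = init_state.size();
  const bool per_cell_rates = rates.ncol() > 1;
  const bool per_cell_rho = rho.size() > 1;
  const bool per_cell_d = d.size() > 1;
  const int a = active - 1, K = reset - 1;
  IntegerVector counts(n_cells);
  std::vector<double> kk(n_states * n_states);

  for (int c = 0; c < n_cells; ++c) {
    const int col = per_cell_rates ? c : 0;
    for (int e = 0; e < n_states * n_states; ++e) kk[e] = rates(e, col);
    const double rh = per_cell_rho ? rho[c] : rho[0];
    const double dd = per_cell_d ? d[c] : d[0];
    const double T = obs_time[c];
    int state = init_state[c] - 1;
    long m = 0;
    double t = 0.0;
    for (;;) {
      double a0 = 0.0;
      for (int j = 0; j < n_states; ++j) a0 += kk[j * n_states + state];
      if (state == a) a0 += rh;
      a0 += dd * m;
      if (a0 <= 0.0) break;           // absorbing: nothing more can happen
      t += R::exp_rand() / a0;
      if (t > T) break;
      double u = unif_rand() * a0;
      double cum = 0.0;
      int fired = -1;
      for (int j = 0; j < n_states; ++j) {
        cum += kk[j * n_states + state];
        if (u < cum) { fired = j; break; }
      }
      if (fired >= 0) {
        state = fired;
      } else if (state == a && u < cum + rh) {
        ++m;
        state = K;
      } else {
        if (m > 0) --m;
      }
    }
    counts[c] = (int)m;
  }
  return counts;
}

// Inter-transcription waiting times of the irreversible N-state chain,
// sampled by simulating the embedded jump process starting from the active
// state immediately after a synthesis event.

// [[Rcpp::export]]
NumericVector ssa_waiting_times_cpp(NumericVector k, double rho, int n) {
  const int N = k.size();
  NumericVector tau(n);
  for (int s = 0; s < n; ++s) {
    double t = 0.0;
    int state = N - 1;                 // active state
    for (;;) {
      if (state == N - 1) {
        const double tot = k[N - 1] + rho;
        t += R::exp_rand() / tot;
        if (unif_rand() * tot < rho) break;  // transcription event
        state = 0;
      } else {
        t += R::exp_rand() / k[state];
        ++state;
      }
    }
    tau[s] = t;
  }
  return tau;
}
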