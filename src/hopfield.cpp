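#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Asynchronous dynamics of a two-state Hopfield network with symmetric
// nonnegative couplings W (zero diagonal), neuron states in {vpos, vneg}
// (vpos = sin(alpha) > 0 > vneg = -cos(alpha)) and common threshold q.
// Clamped neurons (the labeled proteins) never update. Each sweep visits
// free neurons in ascending index order and sets
//   x_i <- vpos if sum_j W_ij x_j - q > 0 else vneg,
// flipping only when the rule demands a different state. The run stops at
// the first sweep with zero flips, or after maxSweeps sweeps (flagged
// non-converged).
//
// The energy E = -1/2 * sum_{i != j} W_ij x_i x_j + q * sum_i x_i changes by
// dE = -(x_new - x_old) * (sum_j W_ij x_j - q) at each flip, which the
// update rule makes non-positive; the trace of E after every flip is
// returned so callers can assert monotonicity.
//
// The adjacency is passed in compressed sparse column form (full symmetric
// pattern, both triangles stored): colptr (length n+1), rowind, vals.

// [[Rcpp::export]]
List cpp_hopfield(int n, IntegerVector colptr, IntegerVector rowind,
                  NumericVector vals, NumericVector state0,
                  LogicalVector clamped, double vpos, double vneg, double q,
                  int maxSweeps) {
  NumericVector state = clone(state0);

  double E = 0.0;
  for (int j = 0; j < n; ++j) {
    for (int idx = colptr[j]; idx < colptr[j + 1]; ++idx)
      E += -0.5 * vals[idx] * state[rowind[idx]] * state[j];
    E += q * state[j];
  }
  std::vector<double> energies;
  energies.push_back(E);

  int sweeps = 0, totalFlips = 0;
  bool converged = false;
  while (sweeps < maxSweeps) {
    ++sweeps;
    int flips = 0;
    for (int v = 0; v < n; ++v) {
      if (clamped[v]) continue;
      double h = 0.0;
      for (int idx = colptr[v]; idx < colptr[v + 1]; ++idx)
        h += vals[idx] * state[rowind[idx]];
      double A = h - q;
      double desired = (A > 0.0) ? vpos : vneg;
      if (desired != state[v]) {
        E += -(desired - state[v]) * A;
        state[v] = desired;
        ++flips;
        energies.push_back(E);
      }
    }
    totalFlips += flips;
    if (flips == 0) { converged = true; break; }
  }

  return List::create(_["state"] = state, _["sweeps"] = sweeps,
                      _["converged"] = converged,
                      _["energies"] = NumericVector(energies.begin(),
                                                    energies.end()),
                      _["flips"] = totalFlips);
}
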