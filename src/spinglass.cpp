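#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Simulated-annealing maximization of the local cohesion score
//   q(C) = l_in(C) - gamma * (S(C)^2 - sum_{i in C} k_i^2) / (4m)
// over node sets C constrained to contain `focal`, where l_in is the number
// of internal edges, S the summed degree of C, k_i node degree and m the
// edge count.  The second term is the configuration-model expectation of
// l_in.  Toggling one node changes the score by an O(deg) quantity, so each
// Metropolis proposal is cheap.
//
// Uses R's RNG (unif_rand) so set.seed() on the R side gives full
// reproducibility.  Returns the 0-based indices of the best set seen.
// [[Rcpp::export]]
IntegerVector sa_local_module_cpp(List adj, IntegerVector deg, double m,
                                  int focal, double gamma,
                                  double t_start, double t_stop,
                                  double cooling) {
  const int n = deg.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    nb[i].assign(a.begin(), a.end());
  }

  std::vector<char> member(n, 0);
  member[focal] = 1;
  double S = deg[focal];
  double lin = 0.0;
  const double inv2m = (m > 0) ? 1.0 / (2.0 * m) : 0.0;
  double q = 0.0;  // q({focal}) = 0: no internal edges, zero expectation

  std::vector<char> best = member;
  double best_q = q;

  RNGScope scope;
  if (n > 1) {
    const double eps = 1e-12;
    for (double t = t_start; t > t_stop; t *= cooling) {
      for (int sweep = 0; sweep < n - 1; ++sweep) {
        // uniform non-focal node
        int v = (int)std::floor(unif_rand() * (n - 1));
        if (v >= n - 1) v = n - 2;
        if (v >= focal) ++v;

        int kv = deg[v];
        int to_members = 0;
        for (int u : nb[v]) if (member[u]) ++to_members;

        double dq;
        if (!member[v]) {
          // add v: Delta E[l_in] = S * kv / (2m)
          dq = (double)to_members - gamma * S * kv * inv2m;
        } else {
          // remove v: Delta E[l_in] = -kv * (S - kv) / (2m)
          dq = -(double)to_members + gamma * kv * (S - kv) * inv2m;
        }

        if (dq >= 0.0 || unif_rand() < std::exp(dq / t)) {
          if (!member[v]) { member[v] = 1; S += kv; lin += to_members; }
          else            { member[v] = 0; S -= kv; lin -= to_members; }
          q += dq;
          if (q > best_q + eps) { best_q = q; best = member; }
        }
      }
    }
  }

  std::vector<int> out;
  for (int i = 0; i < n; ++i) if (best[i]) out.push_back(i);
  return wrap(out);
}
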