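#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Moran birth-death engine.
//
// State layout (column-major, one column per individual):
//   A: n_a x N weight-gene alleles
//   C: (n_traits * n_a) x N contribution alleles; entry (trait i, gene j) of
//      individual k sits at row (j * n_traits + i), i.e. the column-major
//      flattening of the n_traits x n_a contribution matrix.
//
// The optimum trajectory is pre-drawn in R (one row per generation, a
// generation being N events), so the cached and naive engines consume
// exactly the same random stream: per event one uniform per parent, the
// recombination coins (sexual only), one uniform per gene for mutation
// (plus one normal when a mutation fires), and one uniform for the death
// slot.  Fitness evaluation consumes no randomness, so recomputing it
// per-event (naive = true) or caching it gives bit-identical runs.

namespace {

struct Engine {
  int N, n_a, n_traits, nc;
  double mu_a, mu_c, mut_sd, inv2sv;
  bool sexual;
  std::vector<double> A, C, Z, W;
  const double* opt;

  void phen_fit_one(int k) {
    const double* a = &A[(size_t)k * n_a];
    const double* c = &C[(size_t)k * nc];
    double ss = 0.0;
    for (int i = 0; i < n_traits; ++i) {
      double z = 0.0;
      for (int j = 0; j < n_a; ++j) z += c[j * n_traits + i] * a[j];
      Z[(size_t)k * n_traits + i] = z;
      double d = z - opt[i];
      ss += d * d;
    }
    W[k] = std::exp(-ss * inv2sv);
  }

  void recompute_all() {
    for (int k = 0; k < N; ++k) phen_fit_one(k);
  }

  // fitness-proportional draw; uniform fallback when all weights vanish
  int draw_parent() {
    double tot = 0.0;
    for (int k = 0; k < N; ++k) tot += W[k];
    double u = unif_rand();
    if (!(tot > 0.0) || !R_finite(tot)) {
      int idx = (int)(u * N);
      return idx >= N ? N - 1 : idx;
    }
    double target = u * tot, cum = 0.0;
    for (int k = 0; k < N; ++k) {
      cum += W[k];
      if (cum >= target) return k;
    }
    return N - 1;
  }
};

} // namespace

// [[Rcpp::export(name = ".moran_engine_cpp")]]
List moran_engine_cpp(NumericMatrix a0, NumericMatrix c0, NumericMatrix traj,
                      double n_events_d, double mu_a, double mu_c,
                      double mut_var, double selection_var, bool sexual,
                      IntegerVector snapshot_gens, int fitness_every,
                      bool naive) {
  Engine E;
  E.N = a0.ncol();
  E.n_a = a0.nrow();
  E.nc = c0.nrow();
  E.n_traits = traj.ncol();
  E.mu_a = mu_a;
  E.mu_c = mu_c;
  E.mut_sd = std::sqrt(mut_var);
  E.inv2sv = 1.0 / (2.0 * selection_var);
  E.sexual = sexual;
  if (c0.ncol() != E.N) stop("a and c have different numbers of individuals");
  if (E.nc != E.n_traits * E.n_a) stop("c row count is not n_traits * n_a");

  long long n_events = (long long)n_events_d;
  long long n_gen_needed = (n_events + E.N - 1) / E.N;
  if (traj.nrow() < n_gen_needed) stop("optimum trajectory shorter than the run");

  E.A.assign(a0.begin(), a0.end());
  E.C.assign(c0.begin(), c0.end());
  E.Z.assign((size_t)E.n_traits * E.N, 0.0);
  E.W.assign(E.N, 0.0);

  // per-generation optimum rows, contiguous
  std::vector<double> trajv((size_t)traj.nrow() * E.n_traits);
  for (int g = 0; g < traj.nrow(); ++g)
    for (int i = 0; i < E.n_traits; ++i)
      trajv[(size_t)g * E.n_traits + i] = traj(g, i);

  std::vector<bool> snap_flag((size_t)n_gen_needed + 1, false);
  for (int s = 0; s < snapshot_gens.size(); ++s) {
    int g = snapshot_gens[s];
    if (g >= 1 && g <= n_gen_needed) snap_flag[g] = true;
  }

  List snapshots;
  std::vector<double> fit_gen, fit_mean;
  std::vector<double> oa(E.n_a), oc(E.nc);

  E.opt = &trajv[0];
  E.recompute_all();

  for (long long e = 0; e < n_events; ++e) {
    long long g = e / E.N;
    if (e % E.N == 0 && g > 0) {
      const double* row = &trajv[(size_t)g * E.n_traits];
      bool moved = false;
      for (int i = 0; i < E.n_traits; ++i)
        if (row[i] != E.opt[i]) { moved = true; break; }
      E.opt = row;
      if (moved) E.recompute_all();
    }
    if (naive) E.recompute_all();

    int p1 = E.draw_parent();
    if (E.sexual) {
      int p2 = E.draw_parent();
      const double *a1 = &E.A[(size_t)p1 * E.n_a], *a2 = &E.A[(size_t)p2 * E.n_a];
      const double *c1 = &E.C[(size_t)p1 * E.nc], *c2 = &E.C[(size_t)p2 * E.nc];
      for (int j = 0; j < E.n_a; ++j) oa[j] = (unif_rand() < 0.5) ? a1[j] : a2[j];
      for (int m = 0; m < E.nc; ++m) oc[m] = (unif_rand() < 0.5) ? c1[m] : c2[m];
    } else {
      std::copy(&E.A[(size_t)p1 * E.n_a], &E.A[(size_t)p1 * E.n_a] + E.n_a, oa.begin());
      std::copy(&E.C[(size_t)p1 * E.nc], &E.C[(size_t)p1 * E.nc] + E.nc, oc.begin());
    }
    for (int j = 0; j < E.n_a; ++j)
      if (unif_rand() < E.mu_a) oa[j] += norm_rand() * E.mut_sd;
    for (int m = 0; m < E.nc; ++m)
      if (unif_rand() < E.mu_c) oc[m] += norm_rand() * E.mut_sd;

    int d = (int)(unif_rand() * E.N);
    if (d >= E.N) d = E.N - 1;
    std::copy(oa.begin(), oa.end(), &E.A[(size_t)d * E.n_a]);
    std::copy(oc.begin(), oc.end(), &E.C[(size_t)d * E.nc]);
    E.phen_fit_one(d);

    if ((e + 1) % E.N == 0) {
      long long gen = (e + 1) / E.N; // completed generations, 1-based
      if (fitness_every > 0 && gen % fitness_every == 0) {
        double mw = 0.0;
        for (int k = 0; k < E.N; ++k) mw += E.W[k];
        fit_gen.push_back((double)gen);
        fit_mean.push_back(mw / E.N);
      }
      if (snap_flag[gen]) {
        NumericMatrix sa(E.n_a, E.N), sc(E.nc, E.N);
        std::copy(E.A.begin(), E.A.end(), sa.begin());
        std::copy(E.C.begin(), E.C.end(), sc.begin());
        NumericVector so(E.n_traits);
        for (int i = 0; i < E.n_traits; ++i) so[i] = E.opt[i];
        snapshots.push_back(List::create(_["generation"] = (double)gen,
                                         _["a"] = sa, _["c"] = sc,
                                         _["optimum"] = so));
      }
    }
  }

  NumericMatrix af(E.n_a, E.N), cf(E.nc, E.N);
  std::copy(E.A.begin(), E.A.end(), af.begin());
  std::copy(E.C.begin(), E.C.end(), cf.begin());
  return List::create(_["a"] = af, _["c"] = cf, _["snapshots"] = snapshots,
                      _["fitness_generation"] = wrap(fit_gen),
                      _["mean_fitness"] = wrap(fit_mean));
}
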