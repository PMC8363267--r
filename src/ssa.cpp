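#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sparse reaction representation compiled from the stoichiometry matrices.
// Propensity a_j = c_j * h_j(x) with h_j the combinatorial factor of the
// reactant multiset (1, x, x*y, or x*(x-1)/2). Rate constants are per
// segment (column) so clamp reactions can be time-gated.
struct ReactionSet {
  int nr, ns;
  std::vector<std::vector<std::pair<int,int>>> reactants; // (species, count)
  std::vector<std::vector<std::pair<int,int>>> delta;     // (species, net)
  std::vector<std::vector<int>> dep; // reactions to refresh after j fires

  ReactionSet(const IntegerMatrix &rs, const IntegerMatrix &nsm) {
    nr = rs.nrow(); ns = rs.ncol();
    reactants.resize(nr); delta.resize(nr); dep.resize(nr);
    for (int j = 0; j < nr; ++j)
      for (int i = 0; i < ns; ++i) {
        if (rs(j, i) > 0) reactants[j].push_back({i, rs(j, i)});
        if (nsm(j, i) != 0) delta[j].push_back({i, nsm(j, i)});
      }
    for (int j = 0; j < nr; ++j) {
      std::vector<bool> touched(ns, false);
      for (auto &d : delta[j]) touched[d.first] = true;
      for (int k = 0; k < nr; ++k)
        for (auto &r : reactants[k])
          if (touched[r.first]) { dep[j].push_back(k); break; }
    }
  }

  inline double prop(const std::vector<int> &x, int j, double c) const {
    if (c <= 0.0) return 0.0;
    double h = 1.0;
    for (auto &r : reactants[j]) {
      if (r.second == 1) h *= x[r.first];
      else h *= 0.5 * x[r.first] * (x[r.first] - 1.0);
    }
    return c * h;
  }
};

static void record_until(const std::vector<int> &x, double tlimit,
                         const NumericVector &out_times, IntegerMatrix &out,
                         int &oi, bool inclusive) {
  int nout = out_times.size(), ns = x.size();
  while (oi < nout &&
         (inclusive ? out_times[oi] <= tlimit + 1e-9 : out_times[oi] < tlimit - 1e-12)) {
    for (int i = 0; i < ns; ++i) out(oi, i) = x[i];
    ++oi;
  }
}

// Exact SSA (Gillespie direct method) with cached propensities refreshed
// through the reaction dependency graph.
// [[Rcpp::export]]
IntegerMatrix sim_ssa_cpp(IntegerVector x0, IntegerMatrix reactant_stoich,
                          IntegerMatrix net_stoich, NumericMatrix rate_const,
                          NumericVector breaks, NumericVector out_times) {
  ReactionSet R(reactant_stoich, net_stoich);
  int ns = R.ns, nr = R.nr, nseg = breaks.size() - 1;
  std::vector<int> x(x0.begin(), x0.end());
  IntegerMatrix out(out_times.size(), ns);
  std::vector<double> a(nr);
  double t = 0.0;
  int oi = 0;
  for (int seg = 0; seg < nseg; ++seg) {
    double seg_end = breaks[seg + 1];
    const double *c = &rate_const(0, seg);
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) { a[j] = R.prop(x, j, c[j]); a0 += a[j]; }
    long steps = 0;
    while (t < seg_end) {
      if (a0 <= 1e-12) { // quiescent: frozen until segment end
        record_until(x, seg_end, out_times, out, oi, false);
        t = seg_end;
        break;
      }
      double dt = R::exp_rand() / a0;
      if (t + dt >= seg_end) {
        record_until(x, seg_end, out_times, out, oi, false);
        t = seg_end;
        break;
      }
      t += dt;
      record_until(x, t, out_times, out, oi, false);
      double u = R::unif_rand() * a0, cum = 0.0;
      int jf = nr - 1;
      for (int j = 0; j < nr; ++j) { cum += a[j]; if (u <= cum) { jf = j; break; } }
      for (auto &d : R.delta[jf]) x[d.first] += d.second;
      for (int k : R.dep[jf]) {
        a0 -= a[k];
        a[k] = R.prop(x, k, c[k]);
        a0 += a[k];
      }
      if (((++steps) & 0xFFFF) == 0) { // refresh a0 against float drift
        a0 = 0.0;
        for (int j = 0; j < nr; ++j) a0 += a[j];
      }
    }
  }
  record_until(x, breaks[nseg], out_times, out, oi, true);
  return out;
}

// Adaptive tau-leap (Cao-Gillespie style selection). Reactions within a few
// firings of exhausting a reactant are "critical" and fire one at a time via
// the exact algorithm, so no population goes negative; leaps apply integer
// firing counts through the stoichiometry, keeping conserved totals exact.
// [[Rcpp::export]]
IntegerMatrix sim_tau_cpp(IntegerVector x0, IntegerMatrix reactant_stoich,
                          IntegerMatrix net_stoich, NumericMatrix rate_const,
                          NumericVector breaks, NumericVector out_times,
                          double eps, int n_crit) {
  ReactionSet R(reactant_stoich, net_stoich);
  int ns = R.ns, nr = R.nr, nseg = breaks.size() - 1;
  std::vector<int> x(x0.begin(), x0.end()), xn(ns);
  IntegerMatrix out(out_times.size(), ns);
  std::vector<double> a(nr);
  std::vector<bool> crit(nr);
  // g_i: highest reactant order among reactions consuming species i
  std::vector<int> g(ns, 1);
  for (int j = 0; j < nr; ++j) {
    int order = 0;
    for (auto &r : R.reactants[j]) order += r.second;
    for (auto &r : R.reactants[j]) if (order > g[r.first]) g[r.first] = order;
  }
  double t = 0.0;
  int oi = 0;
  for (int seg = 0; seg < nseg; ++seg) {
    double seg_end = breaks[seg + 1];
    const double *c = &rate_const(0, seg);
    while (t < seg_end) {
      double a0 = 0.0;
      for (int j = 0; j < nr; ++j) { a[j] = R.prop(x, j, c[j]); a0 += a[j]; }
      if (a0 <= 1e-12) {
        record_until(x, seg_end, out_times, out, oi, false);
        t = seg_end;
        break;
      }
      double a0c = 0.0;
      for (int j = 0; j < nr; ++j) {
        crit[j] = false;
        if (a[j] <= 0.0) continue;
        for (auto &r : R.reactants[j])
          if (x[r.first] < n_crit * r.second) { crit[j] = true; break; }
        if (crit[j]) a0c += a[j];
      }
      // leap length bounding the relative propensity change via species drift
      double tau1 = R_PosInf;
      {
        std::vector<double> mu(ns, 0.0), s2(ns, 0.0);
        for (int j = 0; j < nr; ++j) {
          if (crit[j] || a[j] <= 0.0) continue;
          for (auto &d : R.delta[j]) {
            mu[d.first] += d.second * a[j];
            s2[d.first] += (double)d.second * d.second * a[j];
          }
        }
        for (int i = 0; i < ns; ++i) {
          if (mu[i] == 0.0 && s2[i] == 0.0) continue;
          double bound = std::max(eps * x[i] / g[i], 1.0);
          if (mu[i] != 0.0) tau1 = std::min(tau1, bound / std::fabs(mu[i]));
          if (s2[i] > 0.0) tau1 = std::min(tau1, bound * bound / s2[i]);
        }
      }
      if (tau1 < 10.0 / a0) {
        // leap not worthwhile: a burst of exact steps
        for (int step = 0; step < 100 && t < seg_end; ++step) {
          a0 = 0.0;
          for (int j = 0; j < nr; ++j) { a[j] = R.prop(x, j, c[j]); a0 += a[j]; }
          if (a0 <= 1e-12) break;
          double dt = R::exp_rand() / a0;
          if (t + dt >= seg_end) { record_until(x, seg_end, out_times, out, oi, false); t = seg_end; break; }
          t += dt;
          record_until(x, t, out_times, out, oi, false);
          double u = R::unif_rand() * a0, cum = 0.0;
          int jf = nr - 1;
          for (int j = 0; j < nr; ++j) { cum += a[j]; if (u <= cum) { jf = j; break; } }
          for (auto &d : R.delta[jf]) x[d.first] += d.second;
        }
        continue;
      }
      double tau2 = (a0c > 0.0) ? R::exp_rand() / a0c : R_PosInf;
      int retries = 0;
      for (;;) {
        double tau = std::min(tau1, tau2);
        bool fire_crit = (tau2 <= tau1);
        // never leap past the segment end or the next output time
        double cap = seg_end - t;
        if (oi < (int)out_times.size() && out_times[oi] > t)
          cap = std::min(cap, out_times[oi] - t);
        if (tau >= cap) { tau = cap; fire_crit = false; }
        xn = x;
        for (int j = 0; j < nr; ++j) {
          if (crit[j] || a[j] <= 0.0) continue;
          int k = (int)R::rpois(a[j] * tau);
          if (k > 0) for (auto &d : R.delta[j]) xn[d.first] += k * d.second;
        }
        if (fire_crit && a0c > 0.0) {
          double u = R::unif_rand() * a0c, cum = 0.0;
          int jf = -1;
          for (int j = 0; j < nr; ++j) {
            if (!crit[j] || a[j] <= 0.0) continue;
            cum += a[j]; jf = j;
            if (u <= cum) break;
          }
          if (jf >= 0) for (auto &d : R.delta[jf]) xn[d.first] += d.second;
        }
        bool neg = false;
        for (int i = 0; i < ns; ++i) if (xn[i] < 0) { neg = true; break; }
        if (!neg) {
          double tnew = t + tau;
          record_until(x, tnew, out_times, out, oi, false);
          t = tnew;
          x = xn;
          break;
        }
        tau1 *= 0.5;
        if (++retries > 40) stop("tau-leap failed to find a non-negative update");
      }
    }
  }
  record_until(x, breaks[nseg], out_times, out, oi, true);
  return out;
}
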