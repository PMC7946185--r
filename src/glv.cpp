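#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Per-capita gLV growth rates g_i = (r_i + f) - s_i x_i + sum_{j != i} a_ij x_j.
static void percap_rates(const std::vector<double>& x,
                         const NumericVector& r, const NumericVector& s,
                         const NumericMatrix& A, double f,
                         std::vector<double>& g) {
  const int S = x.size();
  for (int i = 0; i < S; ++i) {
    double acc = r[i] + f - s[i] * x[i];
    for (int j = 0; j < S; ++j) {
      if (j != i) acc += A(i, j) * x[j];
    }
    g[i] = acc;
  }
}

// Capped derivative: below the cap, dx_i = x_i g_i; at/above the cap the
// community competes for space zero-sum: dx_i = x_i (g_i - gbar), with gbar
// the abundance-weighted (default) or unweighted mean per-capita rate.
// regime: 0 = plain gLV, 1 = zero-sum cap competition. The cap regime is
// decided once per integration step (not per RK stage) so the stage
// derivatives stay consistent across the regime boundary; the weighted
// form conserves the total abundance exactly in either case.
static void regime_deriv(const std::vector<double>& x,
                         const NumericVector& r, const NumericVector& s,
                         const NumericMatrix& A, double f,
                         int regime, bool weighted_mean,
                         std::vector<double>& g, std::vector<double>& dx) {
  const int S = x.size();
  percap_rates(x, r, s, A, f, g);
  if (regime == 1) {
    double gbar = 0.0;
    if (weighted_mean) {
      double w = 0.0;
      for (int i = 0; i < S; ++i) { gbar += x[i] * g[i]; w += x[i]; }
      gbar = (w > 0.0) ? gbar / w : 0.0;
    } else {
      int npos = 0;
      for (int i = 0; i < S; ++i) if (x[i] > 0.0) { gbar += g[i]; ++npos; }
      gbar = (npos > 0) ? gbar / npos : 0.0;
    }
    for (int i = 0; i < S; ++i) dx[i] = x[i] * (g[i] - gbar);
  } else {
    for (int i = 0; i < S; ++i) dx[i] = x[i] * g[i];
  }
}

static int pick_regime(const std::vector<double>& x, double KT,
                       bool capped) {
  if (!capped) return 0;
  double tot = 0.0;
  for (size_t i = 0; i < x.size(); ++i) tot += x[i];
  return (tot >= KT * (1.0 - 1e-12)) ? 1 : 0;
}

// [[Rcpp::export]]
NumericVector cpp_capped_deriv(NumericVector x, NumericVector r,
                               NumericVector s, NumericMatrix A, double f,
                               double KT, bool capped, bool weighted_mean) {
  const int S = x.size();
  std::vector<double> xv(x.begin(), x.end()), g(S), dx(S);
  int regime = 0;
  if (capped) {
    double tot = 0.0;
    for (int i = 0; i < S; ++i) tot += xv[i];
    if (tot >= KT) regime = 1;
  }
  regime_deriv(xv, r, s, A, f, regime, weighted_mean, g, dx);
  return NumericVector(dx.begin(), dx.end());
}

// Cash-Karp RK45 tableau.
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
   253.0 / 4096}};
static const double CK_C5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                                512.0 / 1771};
static const double CK_C4[6] = {2825.0 / 27648, 0, 18575.0 / 48384,
                                13525.0 / 55296, 277.0 / 14336, 1.0 / 4};

// Integrate capped gLV dynamics to convergence or horizon.
//
// Convergence: the largest per-capita rate magnitude among extant species
// (capped regime uses the normalized rate g_i - gbar) stays below conv_tol
// for conv_window consecutive time units. Species dropping below ext_thresh
// are clamped to zero (extinction is absorbing). The state is projected back
// onto sum(x) <= KT whenever numerical drift pushes it above.
//
// [[Rcpp::export]]
List cpp_integrate_glv(NumericVector x0, NumericVector r, NumericVector s,
                       NumericMatrix A, double f, double KT, bool capped,
                       bool weighted_mean, double horizon, double ext_thresh,
                       double conv_tol, double conv_window, double rtol,
                       double atol, bool record, double record_dt) {
  const int S = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> g(S), dx(S), xtmp(S), err(S), x5(S);
  std::vector<std::vector<double>> k(6, std::vector<double>(S));

  double t = 0.0, h = 1e-3;
  const double hmin = 1e-12, hmax = 5.0;
  double quiet_since = -1.0;  // start of current below-tolerance stretch
  bool converged = false, ok = true;
  double max_total = 0.0;

  // secondary fixed-point detector for stiff (cap-pinned) states, where
  // the stepper's tolerance-scale wobble keeps raw per-capita rates above
  // the absolute threshold: consecutive window averages must agree to
  // 1e-8 relative AND rates must be small relative to the Jacobian scale.
  double rowLmax = 0.0;
  for (int i = 0; i < S; ++i) {
    double rl = s[i];
    for (int j = 0; j < S; ++j)
      if (j != i) rl += std::fabs(A(i, j));
    if (rl > rowLmax) rowLmax = rl;
  }
  std::vector<double> acc_x(S, 0.0), prev_mean(S, 0.0);
  double acc_t = 0.0, win_worst = 0.0, win_maxx = 0.0;
  bool prev_valid = false;
  double h_acc = 0.0;

  std::vector<double> rec_t;
  std::vector<double> rec_x;
  auto record_state = [&](double tt) {
    rec_t.push_back(tt);
    for (int i = 0; i < S; ++i) rec_x.push_back(x[i]);
  };

  // initial clamp and projection
  for (int i = 0; i < S; ++i)
    if (x[i] < ext_thresh) x[i] = 0.0;
  {
    double tot = 0.0;
    for (int i = 0; i < S; ++i) tot += x[i];
    if (tot > KT && capped)
      for (int i = 0; i < S; ++i) x[i] *= KT / tot;
    max_total = std::min(tot, capped ? KT : tot);
  }
  if (record) record_state(0.0);
  double next_rec = record_dt;

  while (t < horizon && !converged) {
    if (h > horizon - t) h = horizon - t;

    // Cash-Karp attempt with step-size control
    bool accepted = false;
    int tries = 0;
    const int regime = pick_regime(x, KT, capped);
    while (!accepted) {
      regime_deriv(x, r, s, A, f, regime, weighted_mean, g, k[0]);
      for (int stage = 1; stage < 6; ++stage) {
        for (int i = 0; i < S; ++i) {
          double acc = x[i];
          for (int m = 0; m < stage; ++m) acc += h * CK_B[stage][m] * k[m][i];
          xtmp[i] = (acc < 0.0) ? 0.0 : acc;
        }
        regime_deriv(xtmp, r, s, A, f, regime, weighted_mean, g, k[stage]);
      }
      double errmax = 0.0;
      for (int i = 0; i < S; ++i) {
        double d5 = 0.0, d4 = 0.0;
        for (int m = 0; m < 6; ++m) {
          d5 += CK_C5[m] * k[m][i];
          d4 += CK_C4[m] * k[m][i];
        }
        x5[i] = x[i] + h * d5;
        double scale = atol + rtol * std::max(std::fabs(x[i]), std::fabs(x5[i]));
        double e = std::fabs(h * (d5 - d4)) / scale;
        if (e > errmax) errmax = e;
        if (!std::isfinite(x5[i])) errmax = 1e30;
      }
      if (errmax <= 1.0) {
        accepted = true;
        // grow step
        double fac = (errmax > 1e-12) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
        double hnew = h * std::min(5.0, fac);
        for (int i = 0; i < S; ++i) x[i] = (x5[i] < 0.0) ? 0.0 : x5[i];
        t += h;
        h_acc = h;
        h = std::min(hnew, hmax);
      } else {
        double fac = 0.9 * std::pow(errmax, -0.25);
        h *= std::max(0.1, fac);
        if (h < hmin || ++tries > 200) { ok = false; break; }
      }
    }
    if (!ok) break;

    // extinction clamp + cap projection. Once the cap regime is entered
    // the zero-sum rule conserves the total, so the state is pinned to
    // sum(x) = KT exactly (extinction clamps release it).
    for (int i = 0; i < S; ++i)
      if (x[i] > 0.0 && x[i] < ext_thresh) x[i] = 0.0;
    double tot = 0.0;
    for (int i = 0; i < S; ++i) tot += x[i];
    if (capped && tot > 0.0 && (tot > KT || regime == 1)) {
      for (int i = 0; i < S; ++i) x[i] *= KT / tot;
      tot = KT;
    }
    if (tot > max_total) max_total = tot;
    for (int i = 0; i < S; ++i)
      if (!std::isfinite(x[i])) { ok = false; }
    if (!ok) break;

    // convergence bookkeeping on normalized per-capita rates
    percap_rates(x, r, s, A, f, g);
    double gbar = 0.0;
    bool at_cap = capped && tot >= KT * (1.0 - 1e-12);
    if (at_cap) {
      double w = 0.0;
      if (weighted_mean) {
        for (int i = 0; i < S; ++i) { gbar += x[i] * g[i]; w += x[i]; }
        gbar = (w > 0.0) ? gbar / w : 0.0;
      } else {
        int npos = 0;
        for (int i = 0; i < S; ++i) if (x[i] > 0.0) { gbar += g[i]; ++npos; }
        gbar = (npos > 0) ? gbar / npos : 0.0;
      }
    }
    double worst = 0.0;
    for (int i = 0; i < S; ++i) {
      if (x[i] <= 0.0) continue;
      double rate = at_cap ? (g[i] - gbar) : g[i];
      if (std::fabs(rate) > worst) worst = std::fabs(rate);
    }
    if (worst < conv_tol) {
      if (quiet_since < 0.0) quiet_since = t;
      if (t - quiet_since >= conv_window) converged = true;
    } else {
      quiet_since = -1.0;
    }

    // windowed stationarity detector
    if (!converged && std::isfinite(conv_window)) {
      for (int i = 0; i < S; ++i) {
        acc_x[i] += x[i] * h_acc;
        if (x[i] > win_maxx) win_maxx = x[i];
      }
      acc_t += h_acc;
      if (worst > win_worst) win_worst = worst;
      if (acc_t >= conv_window) {
        double scale_x = 0.0, maxdiff = 0.0;
        for (int i = 0; i < S; ++i) {
          double m = acc_x[i] / acc_t;
          acc_x[i] = m;  // reuse as current mean
          if (m > scale_x) scale_x = m;
        }
        if (prev_valid) {
          for (int i = 0; i < S; ++i) {
            double d = std::fabs(acc_x[i] - prev_mean[i]);
            if (d > maxdiff) maxdiff = d;
          }
          double rate_bound = 100.0 * rtol * rowLmax * win_maxx + conv_tol;
          if (scale_x > 0.0 && maxdiff / scale_x < 1e-8 &&
              win_worst < rate_bound)
            converged = true;
        }
        for (int i = 0; i < S; ++i) {
          prev_mean[i] = acc_x[i];
          acc_x[i] = 0.0;
        }
        prev_valid = true;
        acc_t = 0.0;
        win_worst = 0.0;
        win_maxx = 0.0;
      }
    }

    if (record && t >= next_rec) {
      record_state(t);
      while (next_rec <= t) next_rec += record_dt;
    }
  }
  if (record) record_state(t);

  List out = List::create(
      Named("x") = NumericVector(x.begin(), x.end()), Named("t") = t,
      Named("converged") = converged, Named("ok") = ok,
      Named("max_total") = max_total);
  if (record) {
    int n = rec_t.size();
    NumericMatrix traj(n, S);
    for (int row = 0; row < n; ++row)
      for (int i = 0; i < S; ++i) traj(row, i) = rec_x[row * S + i];
    out["time"] = NumericVector(rec_t.begin(), rec_t.end());
    out["trajectory"] = traj;
  }
  return out;
}

// Count directed simple paths from `source` to `target` by depth-first
// search. Edges are 0-based node indices. Counting stops once `cap` paths
// have been found (capped flag set in that case).
// [[Rcpp::export]]
List cpp_count_simple_paths(IntegerVector from, IntegerVector to, int n_nodes,
                            int source, int target, double cap) {
  std::vector<std::vector<int>> adj(n_nodes);
  for (int e = 0; e < from.size(); ++e) adj[from[e]].push_back(to[e]);
  std::vector<char> on_path(n_nodes, 0);
  double count = 0.0;
  bool hit_cap = false;

  // iterative DFS with explicit stack of (node, next-neighbour index)
  std::vector<std::pair<int, size_t>> stack;
  stack.push_back({source, 0});
  on_path[source] = 1;
  while (!stack.empty() && !hit_cap) {
    auto& top = stack.back();
    int v = top.first;
    if (v == target) {
      count += 1.0;
      if (count >= cap) hit_cap = true;
      on_path[v] = 0;
      stack.pop_back();
      continue;
    }
    if (top.second < adj[v].size()) {
      int w = adj[v][top.second++];
      if (!on_path[w]) {
        on_path[w] = 1;
        stack.push_back({w, 0});
      }
    } else {
      on_path[v] = 0;
      stack.pop_back();
    }
  }
  return List::create(Named("count") = count, Named("capped") = hit_cap);
}
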