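// Simulation engines for the dynamic tight-junction barrier models.
//
// Both engines share the two-state strand-section process: at a fixed 1-s
// cadence an intact section breaks with probability p_break * length and a
// broken one reseals with probability p_seal. The permeability engine
// propagates the piecewise-constant linear compartment ODE exactly over each
// interval (matrix exponential on the small clusters of compartments coupled
// by broken sections); the TER engine solves the loop (mesh) equations of
// the resistor network at every state snapshot.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  void reset() {
    for (size_t i = 0; i < parent.size(); ++i) parent[i] = (int)i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[a] = b;
  }
};

}  // namespace

// Permeability engine. Node codes in sec_from/sec_to: 1..n_comp are
// compartments, 0 is the basal reservoir (clamped), -1 the apical
// compartment (absorbing, no backflow). k_coeff = l_break * P_break.
// conc_basal = q_basal / A_basal. q0 holds initial compartment amounts.
// If window_start >= 0, compartment amounts are averaged over steps
// >= window_start (across replicates) and returned as comp_avg.
// [[Rcpp::export]]
List cpp_sim_permeability(IntegerVector sec_from, IntegerVector sec_to,
                          NumericVector sec_len, NumericVector area,
                          double p_break, double p_seal, double k_coeff,
                          double conc_basal, NumericVector q0,
                          int horizon, int reps, bool record_all,
                          int window_start) {
  const int n_sec = sec_from.size();
  const int n_comp = area.size();
  RNGScope scope;

  // Work in units of the basal concentration so the augmented constant
  // column has the same scale as the rate entries; rescale on output.
  const double scale = conc_basal;
  conc_basal = 1.0;

  std::vector<double> pb(n_sec), p0(n_sec);
  for (int s = 0; s < n_sec; ++s) {
    pb[s] = p_break * sec_len[s];
    if (pb[s] > 1.0) stop("p_break * length exceeds 1 for a section");
    p0[s] = (pb[s] > 0) ? pb[s] / (pb[s] + p_seal) : 0.0;
  }

  NumericMatrix qa_all;
  NumericVector qa_mean(horizon + 1);
  if (record_all) qa_all = NumericMatrix(horizon + 1, reps);
  NumericVector comp_avg(n_comp);
  long window_n = 0;
  double cons_err = 0.0;

  std::vector<int> state(n_sec);
  std::vector<double> q(n_comp);
  UnionFind uf(n_comp);
  std::vector<int> cluster_of(n_comp, -1);
  std::vector<int> local(n_comp, -1);
  std::vector<int> broken;
  broken.reserve(n_sec);
  // A cluster's propagator depends only on which sections form it, and the
  // same small clusters (a lone broken boundary section, a broken pair)
  // recur constantly across steps and replicates, so the matrix
  // exponentials are memoized by the sorted section-id key.
  std::map<std::vector<int>, arma::mat> expm_cache;

  for (int rep = 0; rep < reps; ++rep) {
    for (int s = 0; s < n_sec; ++s) state[s] = (unif_rand() < p0[s]) ? 1 : 0;
    for (int i = 0; i < n_comp; ++i) q[i] = q0[i] / scale;
    double qa = 0.0;
    if (record_all) qa_all(0, rep) = 0.0; else qa_mean[0] += 0.0;

    for (int t = 1; t <= horizon; ++t) {
      // synchronous state update
      broken.clear();
      for (int s = 0; s < n_sec; ++s) {
        if (state[s] == 1) {
          if (unif_rand() < p_seal) state[s] = 0;
        } else if (pb[s] > 0 && unif_rand() < pb[s]) {
          state[s] = 1;
        }
        if (state[s] == 1) broken.push_back(s);
      }

      if (!broken.empty()) {
        // clusters of compartments coupled by broken sections
        uf.reset();
        for (size_t b = 0; b < broken.size(); ++b) {
          int s = broken[b];
          int f = sec_from[s], to = sec_to[s];
          if (f > 0 && to > 0) uf.unite(f - 1, to - 1);
        }
        std::vector<std::vector<int> > cl_secs;
        std::vector<int> touched_roots;
        for (size_t b = 0; b < broken.size(); ++b) {
          int s = broken[b];
          int c = (sec_from[s] > 0) ? sec_from[s] - 1 : sec_to[s] - 1;
          int root = uf.find(c);
          if (cluster_of[root] < 0) {
            cluster_of[root] = (int)cl_secs.size();
            cl_secs.push_back(std::vector<int>());
            touched_roots.push_back(root);
          }
          cl_secs[cluster_of[root]].push_back(s);
        }

        for (size_t ci = 0; ci < cl_secs.size(); ++ci) {
          const std::vector<int>& secs = cl_secs[ci];
          // collect member compartments
          std::vector<int> members;
          for (size_t k = 0; k < secs.size(); ++k) {
            int s = secs[k];
            int nodes[2] = {sec_from[s], sec_to[s]};
            for (int e = 0; e < 2; ++e) {
              int c = nodes[e];
              if (c > 0 && local[c - 1] < 0) {
                local[c - 1] = (int)members.size();
                members.push_back(c - 1);
              }
            }
          }
          const int m = (int)members.size();
          if (expm_cache.size() > 100000) expm_cache.clear();
          std::map<std::vector<int>, arma::mat>::iterator hit =
              expm_cache.find(secs);
          if (hit == expm_cache.end()) {
            // states: 0..m-1 amounts, m apical gain, m+1 net basal inflow,
            // m+2 constant 1
            arma::mat M(m + 3, m + 3, arma::fill::zeros);
            for (size_t k = 0; k < secs.size(); ++k) {
              int s = secs[k];
              int f = sec_from[s], to = sec_to[s];
              if (f > 0 && to > 0) {
                int i = local[f - 1], j = local[to - 1];
                double kij = k_coeff / area[f - 1];   // rate f -> to
                double kji = k_coeff / area[to - 1];  // rate to -> f
                M(j, i) += kij; M(i, i) -= kij;
                M(i, j) += kji; M(j, j) -= kji;
              } else if (f == 0) {                    // basal <-> compartment
                int i = local[to - 1];
                double influx = k_coeff * conc_basal;
                double out = k_coeff / area[to - 1];
                M(i, m + 2) += influx; M(i, i) -= out;
                M(m + 1, m + 2) += influx; M(m + 1, i) -= out;
              } else {                                // compartment -> apical
                int i = local[f - 1];
                double out = k_coeff / area[f - 1];
                M(i, i) -= out;
                M(m, i) += out;
              }
            }
            hit = expm_cache.insert(
                std::make_pair(secs, arma::expmat(M))).first;
          }
          arma::vec z(m + 3, arma::fill::zeros);
          double sum_old = 0.0;
          for (int i = 0; i < m; ++i) {
            z[i] = q[members[i]];
            sum_old += z[i];
          }
          z[m + 2] = 1.0;
          arma::vec zn = hit->second * z;
          double sum_new = 0.0;
          for (int i = 0; i < m; ++i) {
            q[members[i]] = zn[i];
            sum_new += zn[i];
          }
          qa += zn[m];
          double in_basal = zn[m + 1];
          double scale = std::max(std::abs(sum_old) + std::abs(in_basal),
                                  1e-300);
          double err = std::abs((sum_new + zn[m]) - (sum_old + in_basal)) /
                       scale;
          if (err > cons_err) cons_err = err;
          for (int i = 0; i < m; ++i) local[members[i]] = -1;
        }
        for (size_t k = 0; k < touched_roots.size(); ++k)
          cluster_of[touched_roots[k]] = -1;
      }

      if (record_all) qa_all(t, rep) = qa; else qa_mean[t] += qa;
      if (window_start >= 0 && t >= window_start) {
        for (int i = 0; i < n_comp; ++i) comp_avg[i] += q[i];
        ++window_n;
      }
      if (!std::isfinite(qa)) stop("non-finite apical amount at t = %d", t);
    }
  }

  if (record_all) {
    for (int rep = 0; rep < reps; ++rep)
      for (int t = 0; t <= horizon; ++t) qa_all(t, rep) *= scale;
  } else {
    for (int t = 0; t <= horizon; ++t) qa_mean[t] *= scale / reps;
  }
  if (window_n > 0) {
    for (int i = 0; i < n_comp; ++i)
      comp_avg[i] *= scale / (double)window_n;
  }

  List out = List::create(
      _["cons_err"] = cons_err,
      _["comp_avg"] = comp_avg);
  if (record_all) out["qa"] = qa_all; else out["qa"] = qa_mean;
  return out;
}

// TER engine: loop (mesh) analysis of the dynamic resistor network at each
// 1-s state snapshot. sec_loops/sec_signs give, per section, the (up to
// two) current loops it borders (0-based; -1 for none) and the traversal
// sign of the section in each loop. outer is the index of the source loop.
// [[Rcpp::export]]
NumericVector cpp_sim_ter(int n_loops, int outer, IntegerMatrix sec_loops,
                          NumericMatrix sec_signs, NumericVector sec_len,
                          double R_strand, double R_break, double l_break,
                          double p_break, double p_seal, double V_s,
                          int horizon) {
  const int n_sec = sec_len.size();
  RNGScope scope;

  std::vector<double> pb(n_sec), p0(n_sec), r_intact(n_sec), r_broken(n_sec);
  for (int s = 0; s < n_sec; ++s) {
    pb[s] = p_break * sec_len[s];
    if (pb[s] > 1.0) stop("p_break * length exceeds 1 for a section");
    p0[s] = (pb[s] > 0) ? pb[s] / (pb[s] + p_seal) : 0.0;
    r_intact[s] = R_strand / sec_len[s];
    r_broken[s] = 1.0 / ((sec_len[s] - l_break) / R_strand + 1.0 / R_break);
  }

  std::vector<int> state(n_sec);
  for (int s = 0; s < n_sec; ++s) state[s] = (unif_rand() < p0[s]) ? 1 : 0;

  arma::mat M(n_loops, n_loops);
  arma::vec rhs(n_loops, arma::fill::zeros);
  rhs[outer] = V_s;

  NumericVector trace(horizon + 1);
  double r2d = 0.0;
  bool dirty = true;

  for (int t = 0; t <= horizon; ++t) {
    if (t > 0) {
      for (int s = 0; s < n_sec; ++s) {
        if (state[s] == 1) {
          if (unif_rand() < p_seal) { state[s] = 0; dirty = true; }
        } else if (pb[s] > 0 && unif_rand() < pb[s]) {
          state[s] = 1; dirty = true;
        }
      }
    }
    if (dirty) {
      M.zeros();
      for (int s = 0; s < n_sec; ++s) {
        double R = state[s] ? r_broken[s] : r_intact[s];
        int a = sec_loops(s, 0), b = sec_loops(s, 1);
        double sa = sec_signs(s, 0), sb = sec_signs(s, 1);
        if (a >= 0) M(a, a) += R;
        if (b >= 0) {
          M(b, b) += R;
          if (a >= 0) {
            M(a, b) += sa * sb * R;
            M(b, a) += sa * sb * R;
          }
        }
      }
      arma::vec I = arma::solve(M, rhs, arma::solve_opts::likely_sympd);
      r2d = V_s / std::abs(I[outer]);
      dirty = false;
    }
    trace[t] = r2d;
  }
  return trace;
}
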