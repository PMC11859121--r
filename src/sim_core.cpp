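// Compiled generation loop. Mirrors the pure-R reference engine in
// R/lifecycle.R exactly (same four stages, same distributions); uses R's RNG
// so set.seed() governs both engines.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

namespace {

// uniform integer in [0, n): guard against the pathological unif_rand() == 1
inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// marginal median of the first m entries of a scratch buffer (sorts in place)
inline double median_m(std::vector<double>& buf, int m) {
  std::sort(buf.begin(), buf.begin() + m);
  if (m % 2 == 1) return buf[m / 2];
  return 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
}

}  // namespace

// [[Rcpp::export]]
List sim_run_cpp(int N, double p, double delta_theta, double e, double sigma,
                 double d, int n_targets, double mu_cont, double delta_mut,
                 double mu_strat, IntegerVector allowed_codes,
                 bool paroch_evolvable, bool reliance_evolvable,
                 bool marker_reassign, int T) {
  const int n0 = static_cast<int>(std::lround(N * p));
  const int lo[2] = {0, n0};
  const int hi[2] = {n0, N};

  const double ox[2] = {std::cos(delta_theta / 2.0),
                        std::cos(-delta_theta / 2.0)};
  const double oy[2] = {std::sin(delta_theta / 2.0),
                        std::sin(-delta_theta / 2.0)};

  // parent-generation state
  std::vector<int> marker(N), strat(N);
  std::vector<double> paroch(N), rel(N), tx(N), ty(N), w(N);
  // offspring buffers
  std::vector<int> marker2(N), strat2(N);
  std::vector<double> paroch2(N), rel2(N), tx2(N), ty2(N), w2(N);

  const int n_allowed = allowed_codes.size();

  std::vector<int> perm(N);
  std::iota(perm.begin(), perm.end(), 0);
  std::vector<double> keep_x(n_targets), keep_y(n_targets), keep_w(n_targets);
  std::vector<double> scratch(n_targets);

  // trajectory: one row per generation x group
  const int n_rows = (T + 1) * 2;
  NumericMatrix traj(n_rows, 10);
  colnames(traj) = CharacterVector::create(
      "generation", "group", "group_size", "mean_reliance",
      "mean_parochialism", "mean_payoff", "freq_UT", "freq_CT", "freq_PT",
      "mean_payoff_pop");

  int row = 0;
  auto record = [&](int gen) {
    double pop_pay = 0.0;
    for (int i = 0; i < N; ++i) pop_pay += w[i];
    pop_pay /= N;
    for (int g = 0; g < 2; ++g) {
      const int ng = hi[g] - lo[g];
      double sr = 0.0, sp = 0.0, sw = 0.0;
      int cnt[3] = {0, 0, 0};
      for (int i = lo[g]; i < hi[g]; ++i) {
        sr += rel[i];
        sp += paroch[i];
        sw += w[i];
        ++cnt[strat[i]];
      }
      traj(row, 0) = gen;
      traj(row, 1) = g;
      traj(row, 2) = ng;
      traj(row, 3) = sr / ng;
      traj(row, 4) = sp / ng;
      traj(row, 5) = sw / ng;
      traj(row, 6) = static_cast<double>(cnt[0]) / ng;
      traj(row, 7) = static_cast<double>(cnt[1]) / ng;
      traj(row, 8) = static_cast<double>(cnt[2]) / ng;
      traj(row, 9) = pop_pay;
      ++row;
    }
  };

  // marker assignment by the reliability rule
  auto draw_marker = [&](int g) -> int {
    if (unif_rand() < e) return g;
    return (unif_rand() < p) ? 0 : 1;
  };

  // ---- initialization: non-parochial pure individual learners ----
  for (int g = 0; g < 2; ++g) {
    for (int i = lo[g]; i < hi[g]; ++i) {
      marker[i] = draw_marker(g);
      paroch[i] = 0.0;
      rel[i] = 0.0;
      strat[i] = 0;  // UT
      tx[i] = ox[g] + sigma * norm_rand();
      ty[i] = oy[g] + sigma * norm_rand();
      const double dx = tx[i] - ox[g], dy = ty[i] - oy[g];
      w[i] = std::exp(-(dx * dx + dy * dy) / d);
    }
  }
  record(0);

  for (int t = 1; t <= T; ++t) {
    // ---- stage 1: reproduction (per group, rejection sampling) ----
    for (int g = 0; g < 2; ++g) {
      const int ng = hi[g] - lo[g];
      double wmax = 0.0;
      for (int i = lo[g]; i < hi[g]; ++i) wmax = std::max(wmax, w[i]);
      for (int i = lo[g]; i < hi[g]; ++i) {
        int j;
        do {
          j = lo[g] + runif_int(ng);
        } while (unif_rand() * wmax >= w[j]);
        rel2[i] = rel[j];
        if (reliance_evolvable && unif_rand() < mu_cont)
          rel2[i] = clamp01(rel2[i] + delta_mut * norm_rand());
        paroch2[i] = paroch[j];
        if (paroch_evolvable && unif_rand() < mu_cont)
          paroch2[i] = clamp01(paroch2[i] + delta_mut * norm_rand());
        strat2[i] = strat[j];
        if (unif_rand() < mu_strat)
          strat2[i] = allowed_codes[runif_int(n_allowed)];
        marker2[i] = marker_reassign ? draw_marker(g) : marker[j];
      }
    }

    // ---- stages 2-4: model choice, learning, pay-off ----
    for (int g = 0; g < 2; ++g) {
      for (int i = lo[g]; i < hi[g]; ++i) {
        // sample n_targets distinct parents (partial Fisher-Yates; perm
        // stays a permutation across calls, so the sample remains uniform)
        int kept = 0;
        for (int k = 0; k < n_targets; ++k) {
          const int r = k + runif_int(N - k);
          std::swap(perm[k], perm[r]);
          const int j = perm[k];
          // parochial filter: unlike-marked targets excluded with
          // probability equal to the focal agent's parochialism
          if (marker[j] != marker2[i] && unif_rand() < paroch2[i]) continue;
          keep_x[kept] = tx[j];
          keep_y[kept] = ty[j];
          keep_w[kept] = w[j];
          ++kept;
        }

        double nx, ny;
        if (kept == 0) {
          // no surviving targets: rely exclusively on individual learning
          nx = ox[g] + sigma * norm_rand();
          ny = oy[g] + sigma * norm_rand();
        } else {
          double sx, sy;
          switch (strat2[i]) {
            case 0: {  // UT: uniformly random surviving target
              const int t0 = runif_int(kept);
              sx = keep_x[t0];
              sy = keep_y[t0];
              break;
            }
            case 1: {  // CT: marginal (componentwise) median
              std::copy(keep_x.begin(), keep_x.begin() + kept, scratch.begin());
              sx = median_m(scratch, kept);
              std::copy(keep_y.begin(), keep_y.begin() + kept, scratch.begin());
              sy = median_m(scratch, kept);
              break;
            }
            default: {  // PT: highest pay-off, ties broken uniformly
              int best = 0, n_tied = 1;
              for (int t0 = 1; t0 < kept; ++t0) {
                if (keep_w[t0] > keep_w[best]) {
                  best = t0;
                  n_tied = 1;
                } else if (keep_w[t0] == keep_w[best]) {
                  ++n_tied;
                  if (unif_rand() * n_tied < 1.0) best = t0;
                }
              }
              sx = keep_x[best];
              sy = keep_y[best];
            }
          }
          const double ix = ox[g] + sigma * norm_rand();
          const double iy = oy[g] + sigma * norm_rand();
          const double s = rel2[i];
          nx = s * sx + (1.0 - s) * ix;
          ny = s * sy + (1.0 - s) * iy;
        }
        tx2[i] = nx;
        ty2[i] = ny;
        const double dx = nx - ox[g], dy = ny - oy[g];
        w2[i] = std::exp(-(dx * dx + dy * dy) / d);
      }
    }

    // the parent generation is removed from the simulation
    marker.swap(marker2);
    strat.swap(strat2);
    paroch.swap(paroch2);
    rel.swap(rel2);
    tx.swap(tx2);
    ty.swap(ty2);
    w.swap(w2);
    record(t);

    if (t % 200 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector group_out(N);
  for (int i = 0; i < N; ++i) group_out[i] = (i < n0) ? 0 : 1;

  return List::create(
      _["trajectory"] = traj,
      _["final"] = DataFrame::create(
          _["group"] = group_out, _["marker"] = wrap(marker),
          _["parochialism"] = wrap(paroch), _["reliance"] = wrap(rel),
          _["strategy_code"] = wrap(strat), _["trait_x"] = wrap(tx),
          _["trait_y"] = wrap(ty), _["payoff"] = wrap(w)));
}
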