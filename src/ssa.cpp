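// Exact event-driven (Gillespie) core for the stochastic consumer-resource
// process, plus an independent linear birth-death simulator used as a
// Monte-Carlo oracle for the closed-form neutral baselines.
//
// Event rates (state N_1..N_S consumers, R_1..R_K resources):
//   inflow:            R_k -> R_k + 1            at rho_k
//   death:             N_i -> N_i - 1            at eta_i * N_i
//   consumption:       R_k -> R_k - 1            at (1-eps) * R_k C_ki N_i
//   consumption+birth: R_k -> R_k - 1, N_i + 1   at eps     * R_k C_ki N_i
// Speciation floor: a death event drawn for a species at abundance 1 leaves
// the state unchanged and logs an extinction (turnover) instead.
//
// Consumption events are selected resource-first (prob ~ R_k * (C N)_k) then
// consumer (prob ~ C_ki N_i), with cached partial sums updated in O(K) per
// event. Cached totals are refreshed from scratch periodically to keep
// floating-point drift out of the propensities.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double rexp_total(double total) {
  return ::exp_rand() / total;
}

// [[Rcpp::export]]
List ssa_run(NumericMatrix C, NumericVector rho, NumericVector eta,
             double eps, IntegerVector N0, IntegerVector R0,
             double gen_time, NumericVector snapshot_gens,
             double total_gens, bool record_resources, bool record_events) {
  const int K = C.nrow(), S = C.ncol();
  if (rho.size() != K || eta.size() != S || N0.size() != S || R0.size() != K)
    stop("dimension mismatch between C, rho, eta and the initial state");

  std::vector<double> Cm(C.begin(), C.end()); // column-major K x S
  std::vector<long long> N(S), R(K);
  for (int i = 0; i < S; ++i) {
    if (N0[i] < 1) stop("initial consumer abundances must be >= 1");
    N[i] = N0[i];
  }
  for (int k = 0; k < K; ++k) {
    if (R0[k] < 0) stop("initial resource abundances must be >= 0");
    R[k] = R0[k];
  }

  // cached propensities
  std::vector<double> w(K), cons(K), death(S);
  double In = 0.0, D = 0.0, Cons = 0.0;
  std::vector<double> cum_rho(K);
  for (int k = 0; k < K; ++k) { In += rho[k]; cum_rho[k] = In; }
  auto recompute = [&]() {
    D = 0.0; Cons = 0.0;
    for (int i = 0; i < S; ++i) { death[i] = eta[i] * N[i]; D += death[i]; }
    for (int k = 0; k < K; ++k) {
      double wk = 0.0;
      for (int j = 0; j < S; ++j) wk += Cm[k + (size_t)K * j] * N[j];
      w[k] = wk;
      cons[k] = wk * R[k];
      Cons += cons[k];
    }
  };
  recompute();

  const int n_snap = snapshot_gens.size();
  IntegerMatrix snapN(n_snap, S);
  IntegerMatrix snapR(record_resources ? n_snap : 0,
                      record_resources ? K : 0);
  NumericMatrix evc(record_events ? K : 0, record_events ? S : 0);

  // extinction log and per-species pending observations
  std::vector<int> ext_species;
  std::vector<double> ext_gen;
  std::vector<std::vector<double>> pend_gen(S);
  std::vector<std::vector<int>> pend_ab(S);
  std::vector<int> lnk_species, lnk_ab;
  std::vector<double> lnk_obs_gen, lnk_ext_gen;

  const double t_end = total_gens * gen_time;
  double t = 0.0;
  int snap_idx = 0;
  long long n_events = 0;
  long long cnt_inflow = 0, cnt_death = 0, cnt_floor = 0,
            cnt_cons_birth = 0, cnt_cons_nobirth = 0;

  auto take_snapshots_until = [&](double t_next) {
    while (snap_idx < n_snap && snapshot_gens[snap_idx] * gen_time <= t_next) {
      for (int i = 0; i < S; ++i) {
        snapN(snap_idx, i) = (int)N[i];
        pend_gen[i].push_back(snapshot_gens[snap_idx]);
        pend_ab[i].push_back((int)N[i]);
      }
      if (record_resources)
        for (int k = 0; k < K; ++k) snapR(snap_idx, k) = (int)R[k];
      ++snap_idx;
    }
  };

  while (t < t_end) {
    double total = In + D + Cons;
    double dt = rexp_total(total);
    double t_next = t + dt;
    take_snapshots_until(std::min(t_next, t_end));
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;

    double u = ::unif_rand() * total;
    if (u < In) {
      // resource inflow: binary search on the fixed cumulative rho
      int k = (int)(std::lower_bound(cum_rho.begin(), cum_rho.end(), u) -
                    cum_rho.begin());
      if (k >= K) k = K - 1;
      R[k] += 1;
      Cons += w[k];
      cons[k] += w[k];
      ++cnt_inflow;
    } else if (u < In + D) {
      double v = u - In;
      int i = 0;
      double acc = death[0];
      while (acc < v && i < S - 1) acc += death[++i];
      if (N[i] == 1) {
        // speciation floor: log turnover, flush linked observations
        double g = t / gen_time;
        ext_species.push_back(i + 1);
        ext_gen.push_back(g);
        for (size_t q = 0; q < pend_gen[i].size(); ++q) {
          lnk_species.push_back(i + 1);
          lnk_obs_gen.push_back(pend_gen[i][q]);
          lnk_ab.push_back(pend_ab[i][q]);
          lnk_ext_gen.push_back(g);
        }
        pend_gen[i].clear();
        pend_ab[i].clear();
        ++cnt_floor;
      } else {
        N[i] -= 1;
        D -= eta[i];
        death[i] -= eta[i];
        double dCons = 0.0;
        for (int k = 0; k < K; ++k) {
          double c = Cm[k + (size_t)K * i];
          w[k] -= c;
          double d = (double)R[k] * c;
          cons[k] -= d;
          dCons += d;
        }
        Cons -= dCons;
        ++cnt_death;
      }
    } else {
      // consumption: resource k ~ cons[k], then consumer i ~ C_ki N_i
      double v = u - In - D;
      int k = 0;
      double acc = cons[0];
      while (acc < v && k < K - 1) acc += cons[++k];
      double vk = v - (acc - cons[k]);         // remainder within cell k
      double target = vk / (double)R[k];       // uniform on [0, w_k)
      int i = 0;
      double acc2 = Cm[k] * N[0];
      while (acc2 < target && i < S - 1) {
        ++i;
        acc2 += Cm[k + (size_t)K * i] * N[i];
      }
      R[k] -= 1;
      Cons -= w[k];
      cons[k] -= w[k];
      if (record_events) evc(k, i) += 1.0;
      bool birth = (eps >= 1.0) || (::unif_rand() < eps);
      if (birth) {
        N[i] += 1;
        D += eta[i];
        death[i] += eta[i];
        double dCons = 0.0;
        for (int l = 0; l < K; ++l) {
          double c = Cm[l + (size_t)K * i];
          w[l] += c;
          double d = (double)R[l] * c;
          cons[l] += d;
          dCons += d;
        }
        Cons += dCons;
        ++cnt_cons_birth;
      } else {
        ++cnt_cons_nobirth;
      }
    }

    if ((++n_events & 0x1FFFFF) == 0) {
      recompute();
      Rcpp::checkUserInterrupt();
    }
  }
  take_snapshots_until(t_end);

  return List::create(
    _["snapshot_gens"] = snapshot_gens,
    _["N"] = snapN,
    _["R"] = record_resources ? (SEXP)snapR : R_NilValue,
    _["event_counts"] = record_events ? (SEXP)evc : R_NilValue,
    _["ext_species"] = wrap(ext_species),
    _["ext_gen"] = wrap(ext_gen),
    _["lnk_species"] = wrap(lnk_species),
    _["lnk_obs_gen"] = wrap(lnk_obs_gen),
    _["lnk_abundance"] = wrap(lnk_ab),
    _["lnk_ext_gen"] = wrap(lnk_ext_gen),
    _["final_N"] = wrap(std::vector<double>(N.begin(), N.end())),
    _["final_R"] = wrap(std::vector<double>(R.begin(), R.end())),
    _["n_events"] = (double)n_events,
    _["counts"] = NumericVector::create(
      _["inflow"] = (double)cnt_inflow, _["death"] = (double)cnt_death,
      _["extinction"] = (double)cnt_floor,
      _["cons_birth"] = (double)cnt_cons_birth,
      _["cons_nobirth"] = (double)cnt_cons_nobirth)
  );
}

// Linear birth-death process (per-capita birth rate p, death rate 1 per
// generation), absorbing at 0. Independent oracle for Eq-6-style life
// expectancies and for the var-D(t) baseline.

// [[Rcpp::export]]
NumericVector bd_absorption_times(int n0, double p, int reps) {
  if (n0 < 1 || p <= 0 || p >= 1) stop("need n0 >= 1 and 0 < p < 1");
  NumericVector out(reps);
  const double birth_frac = p / (1.0 + p);
  for (int r = 0; r < reps; ++r) {
    long long n = n0;
    double t = 0.0;
    while (n > 0) {
      double total = (1.0 + p) * (double)n;
      t += ::exp_rand() / total;
      if (::unif_rand() < birth_frac) ++n; else --n;
    }
    out[r] = t;
    if ((r & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix bd_sample_paths(int n0, double p, NumericVector t_grid,
                              int reps) {
  if (n0 < 1 || p <= 0 || p >= 1) stop("need n0 >= 1 and 0 < p < 1");
  const int nt = t_grid.size();
  IntegerMatrix out(reps, nt);
  const double birth_frac = p / (1.0 + p);
  for (int r = 0; r < reps; ++r) {
    long long n = n0;
    double t = 0.0;
    int j = 0;
    while (j < nt) {
      if (n == 0) {
        for (; j < nt; ++j) out(r, j) = 0;
        break;
      }
      double total = (1.0 + p) * (double)n;
      double t_next = t + ::exp_rand() / total;
      while (j < nt && t_grid[j] <= t_next) out(r, j++) = (int)n;
      t = t_next;
      if (::unif_rand() < birth_frac) ++n; else --n;
    }
    if ((r & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
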