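// Compiled BAOAB Langevin/SGLD integrator for the built-in analytic models.
// Draws noise from R's RNG via norm_rand() in exactly the same order as the
// pure-R reference path (one standard normal per dof per step), so the two
// paths are interchangeable on a shared seed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// model ids: 1 = harmonic (params: k), 2 = double well (params: barrier, x0)
static inline double model_energy(int id, const NumericVector& par,
                                  const std::vector<double>& x) {
  const int d = x.size();
  double e = 0.0;
  if (id == 1) {
    const double k = par[0];
    for (int i = 0; i < d; ++i) e += 0.5 * k * x[i] * x[i];
  } else {
    const double b = par[0], x0 = par[1];
    for (int i = 0; i < d; ++i) {
      double u = (x[i] / x0) * (x[i] / x0) - 1.0;
      e += b * u * u;
    }
  }
  return e;
}

static inline void model_force(int id, const NumericVector& par,
                               const std::vector<double>& x,
                               std::vector<double>& f) {
  const int d = x.size();
  if (id == 1) {
    const double k = par[0];
    for (int i = 0; i < d; ++i) f[i] = -k * x[i];
  } else {
    const double b = par[0], x0 = par[1], inv2 = 1.0 / (x0 * x0);
    for (int i = 0; i < d; ++i)
      f[i] = -4.0 * b * x[i] * ((x[i] / x0) * (x[i] / x0) - 1.0) * inv2;
  }
}

// [[Rcpp::export]]
List cpp_run_segment(NumericVector x_, NumericVector p_, NumericVector pavg_,
                     NumericVector mass, double dt, double gamma, double lam,
                     double tl, double kBT, int n_steps, int model_id,
                     NumericVector params) {
  const int d = x_.size();
  std::vector<double> x(x_.begin(), x_.end());
  std::vector<double> p(p_.begin(), p_.end());
  std::vector<double> pa(pavg_.begin(), pavg_.end());
  std::vector<double> f(d), c2(d);
  const double c1 = std::exp(-gamma * dt);
  for (int i = 0; i < d; ++i)
    c2[i] = std::sqrt((1.0 - c1 * c1) * mass[i % mass.size()] * kBT);
  const double w = dt / tl;
  double esum = 0.0;

  RNGScope scope;
  for (int s = 0; s < n_steps; ++s) {
    model_force(model_id, params, x, f);
    for (int i = 0; i < d; ++i) {
      double fi = f[i] + lam * gamma * pa[i];
      p[i] += 0.5 * dt * fi;
      x[i] += 0.5 * dt * p[i] / mass[i % mass.size()];
    }
    for (int i = 0; i < d; ++i)
      p[i] = c1 * p[i] + c2[i] * norm_rand();
    for (int i = 0; i < d; ++i)
      x[i] += 0.5 * dt * p[i] / mass[i % mass.size()];
    model_force(model_id, params, x, f);
    for (int i = 0; i < d; ++i) {
      double fi = f[i] + lam * gamma * pa[i];
      p[i] += 0.5 * dt * fi;
      pa[i] = (1.0 - w) * pa[i] + w * p[i];
      if (!std::isfinite(p[i]) || !std::isfinite(x[i]))
        stop("numerical blowup: non-finite state at coordinate %d", i + 1);
    }
    esum += model_energy(model_id, params, x);
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["p"] = NumericVector(p.begin(), p.end()),
                      _["p_avg"] = NumericVector(pa.begin(), pa.end()),
                      _["e_pot"] = model_energy(model_id, params, x),
                      _["e_mean"] = esum / n_steps);
}

// Full replica-exchange round loop for compiled models: dynamics segments,
// Metropolis neighbor swaps on alternating parity, walker labels, visit
// histograms and occupancy/energy logging. Consumes the R RNG in exactly the
// order of the modular R path (segments in replica order, then one uniform
// per attempted pair), so runs are bit-reproducible across both paths.
// Labels: 0 = unlabeled, 1 = cold, 2 = hot. Indices 1-based at the R border.
// [[Rcpp::export]]
List cpp_run_rounds(NumericMatrix X, NumericMatrix P, NumericMatrix PA,
                    IntegerVector window_of, IntegerVector replica_in,
                    IntegerVector label, NumericVector attempts,
                    NumericVector accepts, NumericVector round_trips,
                    NumericVector n_cold, NumericVector n_hot,
                    NumericVector temps, NumericVector mass, double dt,
                    double gamma, double lam, double tl, double kB,
                    int steps_per_swap, int n_rounds, int round_offset,
                    int model_id, NumericVector params, bool rescale) {
  const int d = X.nrow();
  const int n = X.ncol();
  IntegerMatrix occupancy(n_rounds, n);
  NumericMatrix energies(n_rounds, n);
  std::vector<double> e_win(n), x(d), p(d), pa(d), f(d), c2(d);
  const double c1 = std::exp(-gamma * dt);
  const double w = dt / tl;

  RNGScope scope;
  for (int round = 0; round < n_rounds; ++round) {
    // dynamics segment per replica, at its window's temperature
    for (int r = 0; r < n; ++r) {
      const int win = window_of[r] - 1;
      const double kBT = kB * temps[win];
      for (int i = 0; i < d; ++i) {
        x[i] = X(i, r); p[i] = P(i, r); pa[i] = PA(i, r);
        c2[i] = std::sqrt((1.0 - c1 * c1) * mass[i % mass.size()] * kBT);
      }
      for (int s = 0; s < steps_per_swap; ++s) {
        model_force(model_id, params, x, f);
        for (int i = 0; i < d; ++i) {
          p[i] += 0.5 * dt * (f[i] + lam * gamma * pa[i]);
          x[i] += 0.5 * dt * p[i] / mass[i % mass.size()];
        }
        for (int i = 0; i < d; ++i)
          p[i] = c1 * p[i] + c2[i] * norm_rand();
        for (int i = 0; i < d; ++i)
          x[i] += 0.5 * dt * p[i] / mass[i % mass.size()];
        model_force(model_id, params, x, f);
        for (int i = 0; i < d; ++i) {
          p[i] += 0.5 * dt * (f[i] + lam * gamma * pa[i]);
          pa[i] = (1.0 - w) * pa[i] + w * p[i];
          if (!std::isfinite(p[i]) || !std::isfinite(x[i]))
            stop("numerical blowup: non-finite state at coordinate %d", i + 1);
        }
      }
      for (int i = 0; i < d; ++i) { X(i, r) = x[i]; P(i, r) = p[i]; PA(i, r) = pa[i]; }
      e_win[win] = model_energy(model_id, params, x);
    }
    // Metropolis swaps: even parity pairs (0,1),(2,3),...; odd (1,2),(3,4),...
    const int parity = (round_offset + round) % 2;  // 0 -> even
    for (int lo = parity; lo < n - 1; lo += 2) {
      const double beta_a = 1.0 / (kB * temps[lo]);
      const double beta_b = 1.0 / (kB * temps[lo + 1]);
      double pr = std::exp((beta_a - beta_b) * (e_win[lo] - e_win[lo + 1]));
      if (pr > 1.0) pr = 1.0;
      attempts[lo] += 1.0;
      if (unif_rand() < pr) {
        accepts[lo] += 1.0;
        const int ra = replica_in[lo] - 1, rb = replica_in[lo + 1] - 1;
        replica_in[lo] = rb + 1; replica_in[lo + 1] = ra + 1;
        window_of[ra] = lo + 2; window_of[rb] = lo + 1;
        if (rescale) {
          const double sa = std::sqrt(temps[lo + 1] / temps[lo]);
          const double sb = std::sqrt(temps[lo] / temps[lo + 1]);
          for (int i = 0; i < d; ++i) {
            P(i, ra) *= sa; PA(i, ra) *= sa;
            P(i, rb) *= sb; PA(i, rb) *= sb;
          }
        }
      }
    }
    // walker labels and round trips
    const int r_cold = replica_in[0] - 1, r_hot = replica_in[n - 1] - 1;
    if (label[r_cold] == 2) round_trips[r_cold] += 1.0;
    label[r_cold] = 1;
    label[r_hot] = 2;
    // visit histogram and logs
    for (int r = 0; r < n; ++r) {
      const int win = window_of[r] - 1;
      if (label[r] == 1) n_cold[win] += 1.0;
      else if (label[r] == 2) n_hot[win] += 1.0;
      occupancy(round, r) = window_of[r];
      energies(round, win) = e_win[win];
    }
  }
  return List::create(_["occupancy"] = occupancy, _["energies"] = energies);
}
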