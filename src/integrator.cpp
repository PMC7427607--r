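// Delay-SDE integrator for the two-layer multiplex FitzHugh-Nagumo ring network.
//
// Deterministic part: classical 4th-order Runge-Kutta; delayed arguments are
// read from a per-layer history ring buffer on the dt grid, linearly
// interpolated at the half-step stage times.  Stochastic part: additive
// sigma*sqrt(dt)*N(0,1) injected per neuron after each deterministic step
// (weak order 1 in the noise, order 4 in the drift at sigma = 0).
//
// Spike detection runs online with Schmitt-trigger semantics so that very long
// horizons never require storing the full trace.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// Portable N(0,1): mt19937_64 (bit-exact across platforms) + polar Box-Muller.
// std::normal_distribution is implementation-defined, so it is not used.
struct Gauss {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(std::uint64_t seed) : eng(seed) {}
  double unif() {
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);  // (0,1), 53-bit
  }
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

inline double gate(double v, double lambda, double theta) {
  return 1.0 / (1.0 + std::exp(-lambda * (v - theta)));
}

}  // namespace

// [[Rcpp::export]]
List sim_multiplex_cpp(int n_layers, int N,
                       IntegerVector l_type, NumericVector l_kappa,
                       IntegerVector l_lag, IntegerVector l_range,
                       NumericVector l_sigma,
                       int m_type,  // 0 none, 1 electrical, 2 chem inhib, 3 chem excit
                       double kappa_m, int m_lag,
                       double alpha, double beta, double eps,
                       double lambda, double theta_syn, double v_syn,
                       double dt, double n_steps_d, double t_transient,
                       NumericMatrix v0, NumericMatrix w0,
                       NumericMatrix v_start,
                       double seed,
                       double up_threshold, double rearm_threshold,
                       int record_stride, int include_self) {
  const long long n_steps = (long long)(n_steps_d + 0.5);
  const int L = n_layers;
  int max_lag = 0;
  for (int l = 0; l < L; ++l) if (l_lag[l] > max_lag) max_lag = l_lag[l];
  if (L == 2 && m_type != 0 && m_lag > max_lag) max_lag = m_lag;
  const int depth = max_lag + 2;

  // flat state / history: layer-major
  std::vector<double> v((size_t)L * N), w((size_t)L * N);
  std::vector<double> hist((size_t)L * depth * N);
  auto H = [&](int l, long long row, int i) -> double& {
    return hist[((size_t)l * depth + (size_t)(row % depth)) * N + i];
  };
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < N; ++i) {
      v[(size_t)l * N + i] = v_start(l, i);
      w[(size_t)l * N + i] = w0(l, i);
      for (int d = 0; d < depth; ++d) H(l, d, i) = v0(l, i);
    }
  long long head = depth - 1;  // row holding v at current time
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < N; ++i) H(l, head, i) = v[(size_t)l * N + i];

  Gauss rng((std::uint64_t)seed);

  // online spike detection
  std::vector<char> armed((size_t)L * N);
  std::vector<double> vprev((size_t)L * N);
  std::vector<std::vector<std::vector<double>>> spikes(
      L, std::vector<std::vector<double>>(N));
  for (size_t a = 0; a < (size_t)L * N; ++a) {
    armed[a] = v[a] < rearm_threshold;
    vprev[a] = v[a];
  }

  // optional strided trace
  std::vector<double> rec_t;
  std::vector<std::vector<double>> rec_v(L), rec_w(L);
  auto record = [&](double t) {
    rec_t.push_back(t);
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < N; ++i) {
        rec_v[l].push_back(v[(size_t)l * N + i]);
        rec_w[l].push_back(w[(size_t)l * N + i]);
      }
  };
  if (record_stride > 0) record(0.0);

  // scratch
  std::vector<double> sv((size_t)L * N), sw((size_t)L * N);
  std::vector<double> k1((size_t)2 * L * N), k2((size_t)2 * L * N),
      k3((size_t)2 * L * N), k4((size_t)2 * L * N);
  std::vector<double> vd_intra((size_t)L * N), vd_mux((size_t)L * N), g(N);
  const double sqdt = std::sqrt(dt);
  long long blow_step = -1;
  int blow_layer = -1, blow_neuron = -1;

  // fill vd_intra / vd_mux for one stage offset c; sv holds the stage state
  auto fill_delayed = [&](double c) {
    for (int l = 0; l < L; ++l) {
      double* vd = &vd_intra[(size_t)l * N];
      if (l_kappa[l] != 0.0) {
        if (l_lag[l] == 0) {
          const double* s = &sv[(size_t)l * N];
          for (int i = 0; i < N; ++i) vd[i] = s[i];
        } else {
          const double* a = &hist[((size_t)l * depth +
                                   (size_t)((head - l_lag[l]) % depth)) * N];
          const double* b = &hist[((size_t)l * depth +
                                   (size_t)((head - l_lag[l] + 1) % depth)) * N];
          if (c == 0.0)
            for (int i = 0; i < N; ++i) vd[i] = a[i];
          else
            for (int i = 0; i < N; ++i) vd[i] = (1.0 - c) * a[i] + c * b[i];
        }
      }
      if (L == 2 && m_type != 0) {
        int lo = 1 - l;
        double* vm = &vd_mux[(size_t)l * N];
        if (m_lag == 0) {
          const double* s = &sv[(size_t)lo * N];
          for (int i = 0; i < N; ++i) vm[i] = s[i];
        } else {
          const double* a = &hist[((size_t)lo * depth +
                                   (size_t)((head - m_lag) % depth)) * N];
          const double* b = &hist[((size_t)lo * depth +
                                   (size_t)((head - m_lag + 1) % depth)) * N];
          if (c == 0.0)
            for (int i = 0; i < N; ++i) vm[i] = a[i];
          else
            for (int i = 0; i < N; ++i) vm[i] = (1.0 - c) * a[i] + c * b[i];
        }
      }
    }
  };

  // drift of the stage state (sv, sw) into (kv, kw)
  auto drift_eval = [&](double* kv, double* kw) {
    for (int l = 0; l < L; ++l) {
      const double kap = l_kappa[l];
      const int rn = l_range[l];
      const int type = l_type[l];
      const double* svl = &sv[(size_t)l * N];
      const double* swl = &sw[(size_t)l * N];
      const double* vd = &vd_intra[(size_t)l * N];
      const double* vm = &vd_mux[(size_t)l * N];
      double* kvl = kv + (size_t)l * N;
      double* kwl = kw + (size_t)l * N;
      if (kap != 0.0 && type == 1)
        for (int i = 0; i < N; ++i) g[i] = gate(vd[i], lambda, theta_syn);
      const double knorm = (kap != 0.0) ? kap / (2.0 * rn) : 0.0;
      for (int i = 0; i < N; ++i) {
        const double vi = svl[i], wi = swl[i];
        double coup = 0.0;
        if (kap != 0.0) {
          double acc = 0.0;
          if (type == 0) {
            for (int d = 1; d <= rn; ++d) {
              int jl = i - d; if (jl < 0) jl += N;
              int jr = i + d; if (jr >= N) jr -= N;
              acc += vd[jl] + vd[jr];
            }
            double nterm = 2.0 * rn;
            if (include_self) { acc += vd[i]; nterm += 1.0; }
            coup = knorm * (acc - nterm * vi);
          } else {
            for (int d = 1; d <= rn; ++d) {
              int jl = i - d; if (jl < 0) jl += N;
              int jr = i + d; if (jr >= N) jr -= N;
              acc += g[jl] + g[jr];
            }
            if (include_self) acc += g[i];
            coup = -knorm * (vi - v_syn) * acc;  // inhibitory: subtracted
          }
        }
        double mux = 0.0;
        if (L == 2 && m_type != 0 && kappa_m != 0.0) {
          if (m_type == 1)
            mux = kappa_m * (vm[i] - vi);
          else {
            double mc = kappa_m * (vi - v_syn) * gate(vm[i], lambda, theta_syn);
            mux = (m_type == 2) ? -mc : mc;
          }
        }
        kvl[i] = vi - vi * vi * vi / 3.0 - wi + coup + mux;
        kwl[i] = eps * (vi + alpha - beta * wi);
      }
    }
  };

  const size_t M = (size_t)L * N;
  for (long long step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    // k1
    for (size_t a = 0; a < M; ++a) { sv[a] = v[a]; sw[a] = w[a]; }
    fill_delayed(0.0);
    drift_eval(k1.data(), k1.data() + M);
    // k2
    for (size_t a = 0; a < M; ++a) {
      sv[a] = v[a] + 0.5 * dt * k1[a];
      sw[a] = w[a] + 0.5 * dt * k1[M + a];
    }
    fill_delayed(0.5);
    drift_eval(k2.data(), k2.data() + M);
    // k3
    for (size_t a = 0; a < M; ++a) {
      sv[a] = v[a] + 0.5 * dt * k2[a];
      sw[a] = w[a] + 0.5 * dt * k2[M + a];
    }
    fill_delayed(0.5);
    drift_eval(k3.data(), k3.data() + M);
    // k4
    for (size_t a = 0; a < M; ++a) {
      sv[a] = v[a] + dt * k3[a];
      sw[a] = w[a] + dt * k3[M + a];
    }
    fill_delayed(1.0);
    drift_eval(k4.data(), k4.data() + M);
    // combine + noise
    for (int l = 0; l < L; ++l) {
      const double sig = l_sigma[l];
      for (int i = 0; i < N; ++i) {
        const size_t a = (size_t)l * N + i;
        v[a] += dt / 6.0 * (k1[a] + 2.0 * k2[a] + 2.0 * k3[a] + k4[a]);
        w[a] += dt / 6.0 * (k1[M + a] + 2.0 * k2[M + a] + 2.0 * k3[M + a] +
                            k4[M + a]);
        if (sig > 0.0) v[a] += sig * sqdt * rng();
      }
    }
    ++head;
    for (int l = 0; l < L; ++l) {
      double* hrow = &hist[((size_t)l * depth + (size_t)(head % depth)) * N];
      for (int i = 0; i < N; ++i) {
        const size_t a = (size_t)l * N + i;
        const double vn = v[a], vp = vprev[a];
        hrow[i] = vn;
        // Schmitt-trigger spike detection on the post-noise state
        if (armed[a] && vn >= up_threshold && vp < up_threshold) {
          double ts = t + dt * (up_threshold - vp) / (vn - vp);
          if (ts >= t_transient) spikes[l][i].push_back(ts);
          armed[a] = 0;
        } else if (!armed[a] && vn < rearm_threshold) {
          armed[a] = 1;
        }
        vprev[a] = vn;
      }
    }
    if ((step & 1023) == 0 || step == n_steps - 1) {
      for (size_t a = 0; a < M && blow_step < 0; ++a)
        if (!std::isfinite(v[a]) || !std::isfinite(w[a])) {
          blow_step = step;
          blow_layer = (int)(a / N);
          blow_neuron = (int)(a % N);
        }
      if (blow_step >= 0) break;
    }
    if (record_stride > 0 && ((step + 1) % record_stride == 0)) record(t + dt);
    if ((step & 262143) == 0) Rcpp::checkUserInterrupt();
  }

  List sp(L);
  for (int l = 0; l < L; ++l) {
    List spl(N);
    for (int i = 0; i < N; ++i)
      spl[i] = NumericVector(spikes[l][i].begin(), spikes[l][i].end());
    sp[l] = spl;
  }
  NumericMatrix vf(L, N), wf(L, N);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < N; ++i) {
      vf(l, i) = v[(size_t)l * N + i];
      wf(l, i) = w[(size_t)l * N + i];
    }

  List out = List::create(
      _["spikes"] = sp, _["v_final"] = vf, _["w_final"] = wf,
      _["blow_step"] = (double)blow_step, _["blow_layer"] = blow_layer + 1,
      _["blow_neuron"] = blow_neuron + 1);
  if (record_stride > 0) {
    out["rec_time"] = NumericVector(rec_t.begin(), rec_t.end());
    List rv(L), rw(L);
    for (int l = 0; l < L; ++l) {
      NumericMatrix mv((int)rec_t.size(), N), mw((int)rec_t.size(), N);
      for (size_t kk = 0; kk < rec_t.size(); ++kk)
        for (int i = 0; i < N; ++i) {
          mv((int)kk, i) = rec_v[l][kk * N + i];
          mw((int)kk, i) = rec_w[l][kk * N + i];
        }
      rv[l] = mv; rw[l] = mw;
    }
    out["rec_v"] = rv;
    out["rec_w"] = rw;
  }
  return out;
}

// Ornstein-Uhlenbeck helper sharing the stepping scheme (RK4 drift + additive
// noise increment): dv = -theta_rate * v dt + sigma dW.  Used by the
// integrator-contract tests; returns streaming moments after a burn-in.
// [[Rcpp::export]]
List sim_ou_cpp(double theta_rate, double sigma, double dt, double n_steps_d,
                double seed, double burn_frac) {
  const long long n_steps = (long long)(n_steps_d + 0.5);
  const long long burn = (long long)(burn_frac * n_steps);
  Gauss rng((std::uint64_t)seed);
  double v = 0.0;
  const double sqdt = std::sqrt(dt);
  double s1 = 0.0, s2 = 0.0;
  long long n = 0;
  for (long long step = 0; step < n_steps; ++step) {
    double k1 = -theta_rate * v;
    double k2 = -theta_rate * (v + 0.5 * dt * k1);
    double k3 = -theta_rate * (v + 0.5 * dt * k2);
    double k4 = -theta_rate * (v + dt * k3);
    v += dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4) + sigma * sqdt * rng();
    if (step >= burn) { s1 += v; s2 += v * v; ++n; }
  }
  double mean = s1 / n;
  double var = s2 / n - mean * mean;
  return List::create(_["mean"] = mean, _["var"] = var, _["n"] = (double)n);
}
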