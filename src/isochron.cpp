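#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Phase velocity of the forced Kuramoto circuit:
//   dtheta_i/dt = omega_i + (K/N) [ sum_j A_ij sin(theta_j - theta_i)
//                                   + K_ext sin(theta_ext - theta_i) ]
// A is row-oriented: A(i, j) = 1 means j is an input of i.
static inline void kuramoto_deriv(const NumericMatrix& A,
                                  const double* omega, double K, double Kext,
                                  double theta_ext, const double* th,
                                  int N, double* dth) {
  const double KoverN = K / N;
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int j = 0; j < N; ++j) {
      if (A(i, j) != 0.0) s += std::sin(th[j] - th[i]);
    }
    s += Kext * std::sin(theta_ext - th[i]);
    dth[i] = omega[i] + KoverN * s;
  }
}

static inline double wrap2pi(double x) {
  const double twopi = 2.0 * M_PI;
  x -= std::floor(x / twopi) * twopi;
  if (x >= twopi) x -= twopi;  // guard against rounding at the boundary
  if (x < 0) x = 0;
  return x;
}

// Classical fixed-step RK4 for the forced circuit. theta_ext(t) =
// phi0 + omega_ext * t. Phases are stored wrapped to [0, 2pi); the order
// parameter is evaluated at every stored step, optionally treating the
// forcing as an extra node (divisor N+1).
// [[Rcpp::export(.rk4_kuramoto)]]
List rk4_kuramoto(NumericMatrix adj, NumericVector omega, double K,
                  double K_ext, double omega_ext, double phi0,
                  NumericVector theta0, double dt, int n_steps,
                  bool include_forcing) {
  const int N = omega.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> k1(N), k2(N), k3(N), k4(N), tmp(N);

  NumericVector times(n_steps + 1);
  NumericMatrix phases(n_steps + 1, N);
  NumericVector fphase(n_steps + 1);
  NumericVector order(n_steps + 1);

  const double* om = omega.begin();
  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    const double text = phi0 + omega_ext * t;
    times[step] = t;
    fphase[step] = wrap2pi(text);
    double cs = 0.0, sn = 0.0;
    for (int i = 0; i < N; ++i) {
      phases(step, i) = wrap2pi(th[i]);
      cs += std::cos(th[i]);
      sn += std::sin(th[i]);
    }
    double denom = N;
    if (include_forcing) {
      cs += std::cos(text);
      sn += std::sin(text);
      denom += 1.0;
    }
    order[step] = std::sqrt(cs * cs + sn * sn) / denom;

    if (step == n_steps) break;

    kuramoto_deriv(adj, om, K, K_ext, text, th.data(), N, k1.data());
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    kuramoto_deriv(adj, om, K, K_ext, phi0 + omega_ext * (t + 0.5 * dt),
                   tmp.data(), N, k2.data());
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k2[i];
    kuramoto_deriv(adj, om, K, K_ext, phi0 + omega_ext * (t + 0.5 * dt),
                   tmp.data(), N, k3.data());
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + dt * k3[i];
    kuramoto_deriv(adj, om, K, K_ext, phi0 + omega_ext * (t + dt),
                   tmp.data(), N, k4.data());
    for (int i = 0; i < N; ++i)
      th[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }

  return List::create(_["times"] = times, _["phases"] = phases,
                      _["forcing_phase"] = fphase, _["order_series"] = order);
}

// Centered sliding-window maximum (monotonic deque, O(n)). Window is
// clipped at the edges, matching a "partial" rolling max.
// [[Rcpp::export(.running_max)]]
NumericVector running_max(NumericVector x, int window) {
  const int n = x.size();
  if (window < 1) stop("window must be >= 1");
  NumericVector out(n);
  const int half_lo = (window - 1) / 2, half_hi = window / 2;
  std::deque<int> dq;
  int right = -1;
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - half_lo);
    const int hi = std::min(n - 1, i + half_hi);
    while (right < hi) {
      ++right;
      while (!dq.empty() && x[dq.back()] <= x[right]) dq.pop_back();
      dq.push_back(right);
    }
    while (!dq.empty() && dq.front() < lo) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}
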