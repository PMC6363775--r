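#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 for the within-compartment selection interval: every
// compartment runs the coupled logistic dynamics with its local cooperator
// fraction and neighborhood size equal to its current occupancy (floored
// at 1), under a global (shared-K) or per-compartment density factor.
// Kernel only; orchestration, rounding and mixing stay in R.

struct CompPar {
  double aC, aD, dC, dD, kap, K, beta, sigma, es;
  bool global;
  int N;
};

static void comp_deriv(const std::vector<double>& s, std::vector<double>& out,
                       const CompPar& p) {
  const int N = p.N;
  double Ytot = 0.0;
  if (p.global)
    for (int i = 0; i < 2 * N; ++i) Ytot += std::max(s[i], 0.0);
  const double Kloc = p.global ? p.K : p.K / N;
  const double EKg = 1.0 - Ytot / Kloc;
  for (int i = 0; i < N; ++i) {
    const double c = std::max(s[i], 0.0), d = std::max(s[N + i], 0.0);
    const double occ = c + d;
    const double n = std::max(occ, 1.0);
    const double y = occ > 0.0 ? c / occ : 0.0;
    const double NC = (1.0 + (n - 1.0) * y) / n;
    const double ND = (n - 1.0) * y / n;
    const double rC = p.aC * p.es / (1.0 + std::exp(p.sigma - p.beta * NC)) -
                      p.kap;
    const double rD = p.aD * p.es / (1.0 + std::exp(p.sigma - p.beta * ND));
    const double EK = p.global ? EKg : 1.0 - occ / Kloc;
    out[i] = rC * EK * c - p.dC * c;
    out[N + i] = rD * EK * d - p.dD * d;
  }
}

// [[Rcpp::export(name = ".compartment_rk4_cpp")]]
NumericMatrix compartment_rk4_cpp(NumericVector C, NumericVector D,
                                  List par, double T_s, int n_steps,
                                  bool global_capacity) {
  const int N = C.size();
  CompPar p;
  p.aC = par["alpha_C"]; p.aD = par["alpha_D"];
  p.dC = par["delta_C"]; p.dD = par["delta_D"];
  p.kap = par["kappa"]; p.K = par["K"];
  p.beta = par["beta"]; p.sigma = par["sigma"];
  p.es = 1.0 + std::exp(p.sigma);
  p.global = global_capacity; p.N = N;

  std::vector<double> s(2 * N), k1(2 * N), k2(2 * N), k3(2 * N), k4(2 * N),
      tmp(2 * N);
  for (int i = 0; i < N; ++i) { s[i] = C[i]; s[N + i] = D[i]; }
  const double h = T_s / n_steps;
  for (int step = 0; step < n_steps; ++step) {
    comp_deriv(s, k1, p);
    for (int i = 0; i < 2 * N; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
    comp_deriv(tmp, k2, p);
    for (int i = 0; i < 2 * N; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
    comp_deriv(tmp, k3, p);
    for (int i = 0; i < 2 * N; ++i) tmp[i] = s[i] + h * k3[i];
    comp_deriv(tmp, k4, p);
    for (int i = 0; i < 2 * N; ++i)
      s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = std::max(s[i], 0.0);
    out(i, 1) = std::max(s[N + i], 0.0);
  }
  return out;
}
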