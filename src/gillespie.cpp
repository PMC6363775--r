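#include <Rcpp.h>
using namespace Rcpp;

// Direct-method (Gillespie) simulation of the birth-death process:
//   C -> C + C  at per-capita rate max(0, r_C(y) * E_K)
//   D -> D + D  at per-capita rate max(0, r_D(y) * E_K)
//   C -> 0      at per-capita rate delta_C
//   D -> 0      at per-capita rate delta_D
// with E_K = 1 - (C + D)/K. Negative effective birth rates clamp to zero
// (the jump process needs nonnegative propensities); deaths continue, so a
// population above K decays. Uses R's RNG: runs are reproducible under
// set.seed(). In sampled mode the neighborhood composition is drawn per
// event by hypergeometric sampling from the current population instead of
// using its expectation.

static inline double benefit(double N, double beta, double sigma) {
  return (1.0 + std::exp(sigma)) / (1.0 + std::exp(sigma - beta * N));
}

// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(int C0, int D0, double t_max, NumericVector record,
                   List par, bool sampled) {
  const double alpha_C = par["alpha_C"], alpha_D = par["alpha_D"];
  const double delta_C = par["delta_C"], delta_D = par["delta_D"];
  const double kappa = par["kappa"], K = par["K"];
  const double beta = par["beta"], sigma = par["sigma"];
  const double n_C = par["n_C"], n_D = par["n_D"];
  const int nrec = record.size();

  IntegerVector recC(nrec), recD(nrec);
  int C = C0, D = D0, irec = 0;
  double t = 0.0;
  long nevents = 0;

  while (true) {
    const double Y = C + D;
    double bC = 0.0, bD = 0.0;
    if (Y > 0) {
      const double EK = R_finite(K) ? 1.0 - Y / K : 1.0;
      double NC, ND;
      if (!sampled) {
        const double y = C / Y;
        NC = (1.0 + (n_C - 1.0) * y) / n_C;
        ND = (n_D - 1.0) * y / n_D;
      } else {
        // draw n - 1 neighbors without replacement from the rest of the
        // population (truncated when fewer remain); producer fraction is
        // taken over the realized provider group incl. the focal cell
        if (C > 0) {
          int m = (int) std::min(std::round(n_C) - 1.0, Y - 1.0);
          int k = (m > 0) ? (int) R::rhyper(C - 1, D, m) : 0;
          NC = (1.0 + k) / (1.0 + m);
        } else NC = 0.0;
        if (D > 0) {
          int m = (int) std::min(std::round(n_D) - 1.0, Y - 1.0);
          int k = (m > 0) ? (int) R::rhyper(C, D - 1, m) : 0;
          ND = (double) k / (1.0 + m);
        } else ND = 0.0;
      }
      const double rC = alpha_C * benefit(NC, beta, sigma) - kappa;
      const double rD = alpha_D * benefit(ND, beta, sigma);
      bC = C * std::max(0.0, rC * EK);
      bD = D * std::max(0.0, rD * EK);
    }
    const double dC = C * delta_C, dD = D * delta_D;
    const double a0 = bC + bD + dC + dD;

    double t_next = (a0 > 0.0) ? t + R::exp_rand() / a0 : R_PosInf;
    while (irec < nrec && record[irec] < t_next && record[irec] <= t_max) {
      recC[irec] = C; recD[irec] = D; ++irec;
    }
    if (t_next > t_max || a0 <= 0.0) break;
    t = t_next;

    const double u = R::unif_rand() * a0;
    if (u < bC) ++C;
    else if (u < bC + bD) ++D;
    else if (u < bC + bD + dC) --C;
    else --D;
    ++nevents;
    if ((nevents & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  while (irec < nrec) { recC[irec] = C; recD[irec] = D; ++irec; }

  return List::create(_["x_C"] = recC, _["x_D"] = recD,
                      _["final_C"] = C, _["final_D"] = D,
                      _["t_final"] = t, _["n_events"] = (double) nevents);
}
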