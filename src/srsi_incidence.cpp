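#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Daily new-reader counts of the SRS/I system from a fixed-step RK4
// integration. Used inside the least-squares fitting objective, where the
// integrator is called tens of thousands of times; the simulation-facing
// API integrates adaptively instead. I(t) is implied by conservation and
// not tracked. On numerical blowup (absurd parameter corners during
// multistart) the remaining days are filled with a large constant so the
// objective stays finite and strongly penalised.
// [[Rcpp::export]]
NumericVector srsi_incidence_rk4(double lam, double alpha, double p,
                                 double R0, double N, int n_days,
                                 double h = 0.02) {
  const int steps = (int)std::lround(1.0 / h);
  const double hh = 1.0 / steps;
  double S = N - R0, R = R0, C = 0.0, Cprev = 0.0;
  NumericVector out(n_days);
  const double big = 1e12;
  bool blown = false;

  for (int d = 0; d < n_days; ++d) {
    if (!blown) {
      for (int s = 0; s < steps; ++s) {
        double f1 = lam * S * R, i1 = alpha * R;
        double dS1 = -f1 + p * i1, dR1 = f1 - i1;

        double S2 = S + 0.5 * hh * dS1, R2 = R + 0.5 * hh * dR1;
        double f2 = lam * S2 * R2, i2 = alpha * R2;
        double dS2 = -f2 + p * i2, dR2 = f2 - i2;

        double S3 = S + 0.5 * hh * dS2, R3 = R + 0.5 * hh * dR2;
        double f3 = lam * S3 * R3, i3 = alpha * R3;
        double dS3 = -f3 + p * i3, dR3 = f3 - i3;

        double S4 = S + hh * dS3, R4 = R + hh * dR3;
        double f4 = lam * S4 * R4, i4 = alpha * R4;
        double dS4 = -f4 + p * i4, dR4 = f4 - i4;

        S += hh * (dS1 + 2 * dS2 + 2 * dS3 + dS4) / 6.0;
        R += hh * (dR1 + 2 * dR2 + 2 * dR3 + dR4) / 6.0;
        C += hh * (f1 + 2 * f2 + 2 * f3 + f4) / 6.0;

        if (!std::isfinite(S) || !std::isfinite(R) || !std::isfinite(C) ||
            std::fabs(S) > 1e3 * N || std::fabs(R) > 1e3 * N) {
          blown = true;
          break;
        }
      }
    }
    out[d] = blown ? big : (C - Cprev);
    Cprev = C;
  }
  return out;
}
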