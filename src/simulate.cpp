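#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit Euler for the three-compartment fatigue model.
//
// Demand is supplied on a 1 s grid and held constant (zero-order hold)
// across the n_sub substeps of each second. After every substep the
// reserve constraint M0 - MA - MF >= 0 is enforced: MF keeps its own
// dynamics and, once the reserve is exhausted, fatigue eats into the
// active pool (MA <- M0 - MF). All compartments are kept non-negative.
//
// Returns the full substep series plus a flag marking any substep where
// dt*MP*alphaA >= 1 or dt*MA*betaD >= 1 (single-step overshoot bound).

// [[Rcpp::export(".sim_enhanced_cpp")]]
List sim_enhanced_cpp(NumericVector mad, double m0, double alpha_a,
                      double beta_d, double f, double r,
                      int n_sub, double ma0, double mf0) {
  const int n = mad.size();
  const double dt = 1.0 / n_sub;
  const int npts = (n - 1) * n_sub + 1;
  NumericVector ma(npts), mf(npts);
  double a = ma0, q = mf0;
  bool warn = false;
  ma[0] = a;
  mf[0] = q;
  int idx = 1;
  for (int k = 0; k < n - 1; ++k) {
    const double d = mad[k];
    for (int s = 0; s < n_sub; ++s) {
      double mp = m0 - a - q;
      if (mp < 0.0) mp = 0.0;
      const double delta = d - a;
      if (dt * mp * alpha_a >= 1.0 || dt * a * beta_d >= 1.0) warn = true;
      const double dma = (delta > 0.0) ? delta * mp * alpha_a
                                       : delta * a * beta_d;
      const double dmf = a * f - q * r;
      a += dt * dma;
      q += dt * dmf;
      if (q < 0.0) q = 0.0;
      if (q > m0) q = m0;
      if (a < 0.0) a = 0.0;
      if (a + q > m0) a = m0 - q;
      ma[idx] = a;
      mf[idx] = q;
      ++idx;
    }
  }
  return List::create(_["ma"] = ma, _["mf"] = mf, _["warn"] = warn);
}

// Baseline (prior four-compartment) model: while demand is attainable the
// activation rate equals the finite-difference derivative of the demand;
// when demand exceeds M0 - MF every available unit is recruited
// (MA capped at M0 - MF). The cap is applied after the derivative update
// inside the substep, so a demand drop issued while the athlete is
// saturated still drives MA down. MA is deliberately NOT clipped at zero:
// the baseline's negative-activation failure mode must be reproducible.

// [[Rcpp::export(".sim_sns_cpp")]]
List sim_sns_cpp(NumericVector mad, double m0, double f, double r,
                 int n_sub, double ma0, double mf0) {
  const int n = mad.size();
  const double dt = 1.0 / n_sub;
  const int npts = (n - 1) * n_sub + 1;
  NumericVector ma(npts), mf(npts);
  double a = ma0, q = mf0;
  ma[0] = a;
  mf[0] = q;
  int idx = 1;
  for (int k = 0; k < n - 1; ++k) {
    const double d = mad[k];
    // forward finite difference of the demand on the 1 s grid
    const double dd = (k + 1 < n) ? (mad[k + 1] - mad[k]) : 0.0;
    for (int s = 0; s < n_sub; ++s) {
      a += dd * dt;
      if (d >= m0 - q && a > m0 - q) a = m0 - q;
      q += dt * (a * f - q * r);
      ma[idx] = a;
      mf[idx] = q;
      ++idx;
    }
  }
  return List::create(_["ma"] = ma, _["mf"] = mf, _["warn"] = false);
}
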