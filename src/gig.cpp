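#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Generalised inverse Gaussian sampler.
//
// Target density: f(x) proportional to x^(lambda-1) exp(-(psi*x + chi/x)/2),
// x > 0. Strategy: reduce to the standard symmetric form
//   g(x) proportional to x^(lam-1) exp(-omega*(x + 1/x)/2),  omega = sqrt(chi*psi),
// via X = sqrt(chi/psi) * Xstd, using 1/Xstd ~ GIGstd(-lam, omega) when
// lam < 0. On the log scale s = log x the standard density is
//   h(s) = lam*s - omega*cosh(s),
// which is strictly log-concave, so a universal 3-piece rejection envelope
// applies: uniform on [sL, sR] where the normalised log-density equals -1,
// exponential tails with the tangent slopes at sL and sR. Expected
// acceptance is bounded away from zero for every (lam, omega).

static double gig_logh(double s, double lam, double omega) {
  return lam * s - omega * std::cosh(s);
}

// solve f(s) = lam*s - omega*cosh(s) - hmax = -1 on one side of the mode by
// bracketed bisection (robust for all parameter magnitudes)
static double gig_cut(double m, double hmax, double lam, double omega,
                      bool right) {
  double step = 1.0 / std::sqrt(std::max(omega * std::cosh(m), 1e-300));
  if (!std::isfinite(step) || step <= 0) step = 1.0;
  double dir = right ? 1.0 : -1.0;
  double dist = step;
  double lo = m, hi = m + dir * dist;
  int guard = 0;
  while (gig_logh(hi, lam, omega) - hmax > -1.0 && guard++ < 200) {
    lo = hi;
    dist *= 2.0;
    hi = m + dir * dist;
  }
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (gig_logh(mid, lam, omega) - hmax > -1.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// one draw from the standard form, lam >= 0, omega > 0
static double rgig_std(double lam, double omega) {
  double m = std::asinh(lam / omega);          // mode of h(s)
  double hmax = gig_logh(m, lam, omega);
  double sR = gig_cut(m, hmax, lam, omega, true);
  double sL = gig_cut(m, hmax, lam, omega, false);
  // tangent slopes of the normalised log-density at the cut points
  double dR = omega * std::sinh(sR) - lam;     // > 0 (decay rate rightwards)
  double dL = lam - omega * std::sinh(sL);     // > 0 (decay rate leftwards)
  double Ac = sR - sL;
  double Ar = std::exp(-1.0) / dR;
  double Al = std::exp(-1.0) / dL;
  double A = Ac + Ar + Al;
  for (int it = 0; it < 10000; ++it) {
    double u = unif_rand() * A;
    double s, loghat;
    if (u < Ac) {
      s = sL + u;
      loghat = 0.0;
    } else if (u < Ac + Ar) {
      s = sR + exp_rand() / dR;
      loghat = -1.0 - dR * (s - sR);
    } else {
      s = sL - exp_rand() / dL;
      loghat = -1.0 - dL * (sL - s);
    }
    double logf = gig_logh(s, lam, omega) - hmax;
    if (std::log(unif_rand()) <= logf - loghat) return std::exp(s);
  }
  Rcpp::stop("GIG rejection sampler failed to accept");  // unreachable
}

static double rgig1(double lambda, double chi, double psi) {
  if (!(psi > 0.0)) Rcpp::stop("rgig: psi must be positive");
  if (chi < 0.0) Rcpp::stop("rgig: chi must be non-negative");
  if (chi == 0.0) {
    if (lambda <= 0.0)
      Rcpp::stop("rgig: chi = 0 requires lambda > 0 (gamma limit)");
    return R::rgamma(lambda, 2.0 / psi);
  }
  double omega = std::sqrt(chi * psi);
  double scale = std::sqrt(chi / psi);
  if (lambda >= 0.0) return scale * rgig_std(lambda, omega);
  return scale / rgig_std(-lambda, omega);
}

// [[Rcpp::export(name = ".rgig_cpp")]]
NumericVector rgig_cpp(int n, NumericVector lambda, NumericVector chi,
                       NumericVector psi) {
  NumericVector out(n);
  int nl = lambda.size(), nc = chi.size(), np = psi.size();
  for (int i = 0; i < n; ++i) {
    out[i] = rgig1(lambda[i % nl], chi[i % nc], psi[i % np]);
  }
  return out;
}

// One Gibbs sweep over the company frailties in fixed ascending order, for
// histories where every company is active over the whole window. Maintains
//   M0z = sum_b wB[b] / Z[b]   (buyer-side weight total)
//   T   = sum_c Z[c] * P[c]    (owner-weighted exposure total)
// incrementally so the sweep is O(N). Per company c the GIG full
// conditional has
//   lambda = M[c] + 1/xi,
//   chi    = 2 * D2 = 2 * wB[c] * (T - Z[c]*P[c]),
//   psi    = 2 * (D1 + 1/xi),  D1 = P[c]*(M0z - wB[c]/Z[c]) + Psc[c].
// [[Rcpp::export(name = ".gibbs_sweep_cpp")]]
NumericVector gibbs_sweep_cpp(NumericVector Z_in, NumericVector P,
                              NumericVector Psc, NumericVector wB,
                              IntegerVector M, double xi) {
  NumericVector Z = clone(Z_in);
  int N = Z.size();
  double M0z = 0.0, T = 0.0;
  for (int i = 0; i < N; ++i) {
    M0z += wB[i] / Z[i];
    T += Z[i] * P[i];
  }
  double inv_xi = 1.0 / xi;
  for (int c = 0; c < N; ++c) {
    double D1 = P[c] * std::max(M0z - wB[c] / Z[c], 0.0) + Psc[c];
    double D2 = wB[c] * std::max(T - Z[c] * P[c], 0.0);
    double znew = rgig1(M[c] + inv_xi, 2.0 * D2, 2.0 * (D1 + inv_xi));
    M0z += wB[c] * (1.0 / znew - 1.0 / Z[c]);
    T += P[c] * (znew - Z[c]);
    Z[c] = znew;
  }
  return Z;
}
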