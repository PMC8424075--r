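#include <Rcpp.h>
using namespace Rcpp;

// EM fit of the interval-mapping mixture at a vector of scan positions.
//
// At each position the phenotype is modelled as a two-component Gaussian
// mixture with component means mu + a and mu - a (a = additive effect on
// the +1/-1 genotype scale), a common variance, and *fixed* per-line
// mixing proportions equal to the conditional probability of the +1 QTL
// genotype given the flanking marker genotypes.  Only (mu, a, sigma2) are
// estimated; the mixing proportions are not updated, which is what makes
// this the interval-mapping likelihood rather than a free mixture.
//
// dy:    n x I matrix of background-adjusted phenotypes, one column per
//        marker interval (the adjustment excludes the interval's own
//        flanking cofactors, so it changes between intervals).
// ivl:   length-P vector of 1-based interval indices, one per position.
// pplus: n x P matrix, P(QTL genotype = +1 | flanking markers) per line.
//
// Returns a P x 5 matrix: LOD, a, mu, sigma2, iterations.
// The null likelihood per interval is the single-Gaussian ML fit to that
// interval's adjusted phenotype; LOD = log10 L1 - log10 L0, floored at 0
// (the mixture nests the null at a = 0, so negative values can only be
// numerical noise).
// [[Rcpp::export]]
NumericMatrix em_scan_cpp(NumericMatrix dy, IntegerVector ivl,
                          NumericMatrix pplus,
                          double tol = 1e-8, int maxit = 200) {
  const int n = dy.nrow(), I = dy.ncol(), P = ivl.size();
  if (pplus.nrow() != n || pplus.ncol() != P)
    stop("dimension mismatch between dy and pplus");

  // single-Gaussian (null) log-likelihood per interval
  std::vector<double> ll0(I);
  for (int k = 0; k < I; ++k) {
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) s += dy(i, k);
    const double mu0 = s / n;
    for (int i = 0; i < n; ++i) {
      const double d = dy(i, k) - mu0;
      ss += d * d;
    }
    double sig0 = ss / n;
    if (sig0 < 1e-12) sig0 = 1e-12;
    ll0[k] = -0.5 * n * (std::log(2.0 * M_PI * sig0) + 1.0);
  }

  NumericMatrix out(P, 5);
  std::vector<double> w(n);

  for (int p = 0; p < P; ++p) {
    const int k = ivl[p] - 1;
    if (k < 0 || k >= I) stop("interval index out of range");
    const double *y = &dy(0, k);
    const double *pp = &pplus(0, p);

    // least-squares start on the expected QTL code x = 2p - 1
    double sx = 0, sxx = 0, sy = 0, sxy = 0;
    for (int i = 0; i < n; ++i) {
      const double x = 2.0 * pp[i] - 1.0;
      sx += x; sxx += x * x; sy += y[i]; sxy += x * y[i];
    }
    const double vx = sxx - sx * sx / n;
    double a = (vx > 1e-12) ? (sxy - sx * sy / n) / vx : 0.0;
    double mu = (sy - a * sx) / n;
    double sig2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double r = y[i] - mu - a * (2.0 * pp[i] - 1.0);
      sig2 += r * r;
    }
    sig2 /= n;
    if (sig2 < 1e-12) sig2 = 1e-12;

    double ll = 0.0, llold = 0.0;
    int it;
    for (it = 0; it < maxit; ++it) {
      // E step and observed-data log-likelihood at current parameters
      llold = ll;
      ll = 0.0;
      double Sw = 0.0, Swy = 0.0, Sy = 0.0;
      const double inv2s = -0.5 / sig2;
      for (int i = 0; i < n; ++i) {
        const double dp = y[i] - mu - a, dm = y[i] - mu + a;
        const double ep = std::exp(inv2s * dp * dp);
        const double em = std::exp(inv2s * dm * dm);
        double den = pp[i] * ep + (1.0 - pp[i]) * em;
        if (den < 1e-300) den = 1e-300;
        const double wi = pp[i] * ep / den;
        w[i] = wi;
        ll += std::log(den);
        Sw += wi;
        Swy += (2.0 * wi - 1.0) * y[i];
        Sy += y[i];
      }
      ll -= 0.5 * n * std::log(2.0 * M_PI * sig2);
      if (it > 0 &&
          std::fabs(ll - llold) < tol * (std::fabs(llold) + 1e-8)) break;

      // M step: weighted normal equations for (mu, a), then sigma2
      const double c = 2.0 * Sw - n;
      const double det = (double)n * n - c * c;
      if (std::fabs(det) < 1e-9 * n * n) {
        mu = Sy / n;
        a = 0.0;
      } else {
        mu = (n * Sy - c * Swy) / det;
        a = (n * Swy - c * Sy) / det;
      }
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double dp = y[i] - mu - a, dm = y[i] - mu + a;
        ss += w[i] * dp * dp + (1.0 - w[i]) * dm * dm;
      }
      sig2 = ss / n;
      if (sig2 < 1e-12) sig2 = 1e-12;
    }

    double lod = (ll - ll0[k]) / std::log(10.0);
    if (lod < 0) lod = 0;
    out(p, 0) = lod;
    out(p, 1) = a;
    out(p, 2) = mu;
    out(p, 3) = sig2;
    out(p, 4) = it;
  }

  colnames(out) = CharacterVector::create("lod", "add", "mu", "sigma2",
                                          "iterations");
  return out;
}

// Observed-data log-likelihood of the interval-mapping mixture at given
// parameters (used by tests to assert EM monotonicity and to cross-check
// against grid-search maximisation).
// [[Rcpp::export]]
double im_loglik_cpp(NumericVector y, NumericVector pplus,
                     double mu, double a, double sig2) {
  const int n = y.size();
  double ll = 0.0;
  const double inv2s = -0.5 / sig2;
  for (int i = 0; i < n; ++i) {
    const double dp = y[i] - mu - a, dm = y[i] - mu + a;
    double den = pplus[i] * std::exp(inv2s * dp * dp) +
                 (1.0 - pplus[i]) * std::exp(inv2s * dm * dm);
    if (den < 1e-300) den = 1e-300;
    ll += std::log(den);
  }
  return ll - 0.5 * n * std::log(2.0 * M_PI * sig2);
}
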