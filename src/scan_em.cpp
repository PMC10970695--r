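#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Interval-mapping EM at a batch of scan positions.
//
// P: n x (3 * npos) matrix; columns 3j..3j+2 hold each line's prior
//    probability of QTL genotype A/H/B at position j, conditioned on
//    the flanking markers. A row summing to zero at a position means
//    the line has no flanking information there and is skipped.
// y: (cofactor-adjusted) phenotype, length n; NA lines are skipped.
//
// At each position a three-component normal mixture with common
// variance is fitted by EM (component weights fixed at the priors);
// the null is a single normal on the same lines. Returns one row per
// position: LOD, muA, muH, muB, sigma2, sigma2_null, n_used.
// [[Rcpp::export]]
NumericMatrix scan_em_cpp(const NumericMatrix& P, const NumericVector& y,
                          int maxit = 200, double tol = 1e-8) {
  const int n = P.nrow();
  const int npos = P.ncol() / 3;
  NumericMatrix out(npos, 7);
  std::vector<int> idx;
  idx.reserve(n);
  std::vector<double> w(3), mu(3), muw(3);

  for (int j = 0; j < npos; ++j) {
    const int c0 = 3 * j;
    idx.clear();
    for (int i = 0; i < n; ++i) {
      const double ps = P(i, c0) + P(i, c0 + 1) + P(i, c0 + 2);
      if (ps > 0 && R_finite(y[i])) idx.push_back(i);
    }
    const int m = idx.size();
    if (m < 3) {
      out(j, 0) = NA_REAL;
      for (int k = 1; k < 6; ++k) out(j, k) = NA_REAL;
      out(j, 6) = m;
      continue;
    }
    // null model: single normal, MLE variance
    double s = 0.0;
    for (int ii = 0; ii < m; ++ii) s += y[idx[ii]];
    const double m0 = s / m;
    double rss0 = 0.0;
    for (int ii = 0; ii < m; ++ii) {
      const double d = y[idx[ii]] - m0;
      rss0 += d * d;
    }
    double sig0 = rss0 / m;
    if (sig0 < 1e-300) sig0 = 1e-300;
    const double ll0 = -0.5 * m * (std::log(2.0 * M_PI * sig0) + 1.0);

    // init component means from prior-weighted averages
    const double sigfloor = 1e-8 * sig0;
    for (int g = 0; g < 3; ++g) { mu[g] = 0.0; muw[g] = 0.0; }
    for (int ii = 0; ii < m; ++ii) {
      const int i = idx[ii];
      for (int g = 0; g < 3; ++g) {
        mu[g] += P(i, c0 + g) * y[i];
        muw[g] += P(i, c0 + g);
      }
    }
    for (int g = 0; g < 3; ++g)
      mu[g] = (muw[g] > 1e-12) ? mu[g] / muw[g] : m0;
    double sig = sig0;
    double ll1 = -HUGE_VAL;

    for (int it = 0; it < maxit; ++it) {
      double ll = 0.0;
      double sw[3] = {0.0, 0.0, 0.0};
      double swy[3] = {0.0, 0.0, 0.0};
      double rss = 0.0;
      const double inv2s = 1.0 / (2.0 * sig);
      for (int ii = 0; ii < m; ++ii) {
        const int i = idx[ii];
        double tot = 0.0;
        for (int g = 0; g < 3; ++g) {
          const double d = y[i] - mu[g];
          w[g] = P(i, c0 + g) * std::exp(-d * d * inv2s);
          tot += w[g];
        }
        const double ps = P(i, c0) + P(i, c0 + 1) + P(i, c0 + 2);
        if (tot < 1e-300) {  // numeric underflow: fall back to priors
          for (int g = 0; g < 3; ++g) w[g] = P(i, c0 + g);
          tot = ps;
          ll += -700.0;  // ~ log of the underflowed density
        } else {
          ll += std::log(tot / ps) - 0.5 * std::log(2.0 * M_PI * sig);
        }
        for (int g = 0; g < 3; ++g) {
          const double r = w[g] / tot;
          sw[g] += r;
          swy[g] += r * y[i];
          const double d = y[i] - mu[g];
          rss += r * d * d;
        }
      }
      for (int g = 0; g < 3; ++g)
        if (sw[g] > 1e-12) mu[g] = swy[g] / sw[g];
      sig = rss / m;
      if (sig < sigfloor) sig = sigfloor;
      if (std::fabs(ll - ll1) < tol) { ll1 = ll; break; }
      ll1 = ll;
    }
    double lod = (ll1 - ll0) / std::log(10.0);
    if (lod < 0) lod = 0;  // EM local optimum can dip below null
    out(j, 0) = lod;
    out(j, 1) = mu[0];
    out(j, 2) = mu[1];
    out(j, 3) = mu[2];
    out(j, 4) = sig;
    out(j, 5) = sig0;
    out(j, 6) = m;
  }
  colnames(out) = CharacterVector::create("lod", "muA", "muH", "muB",
                                          "sigma2", "sigma2_null", "n");
  return out;
}

// Haley-Knott regression scan at a batch of positions.
//
// Same interface as scan_em_cpp, but the QTL effect is fitted by least
// squares on the prior-EXPECTED additive score x* = P(A) - P(B) and
// dominance score z* = P(H); LOD = (n/2) log10(RSS0 / RSS1). Bounded
// for any phenotype (including 0/1 traits) and exactly the regression
// LOD at fully informative marker positions.
// [[Rcpp::export]]
NumericMatrix scan_hk_cpp(const NumericMatrix& P, const NumericVector& y) {
  const int n = P.nrow();
  const int npos = P.ncol() / 3;
  NumericMatrix out(npos, 7);
  std::vector<int> idx;
  idx.reserve(n);

  for (int j = 0; j < npos; ++j) {
    const int c0 = 3 * j;
    idx.clear();
    for (int i = 0; i < n; ++i) {
      const double ps = P(i, c0) + P(i, c0 + 1) + P(i, c0 + 2);
      if (ps > 0 && R_finite(y[i])) idx.push_back(i);
    }
    const int m = idx.size();
    if (m < 4) {
      for (int k = 0; k < 6; ++k) out(j, k) = NA_REAL;
      out(j, 6) = m;
      continue;
    }
    // accumulate X'X and X'y for X = [1, x*, z*] (priors renormalised)
    double sxx = 0, szz = 0, sxz = 0, sx = 0, sz = 0;
    double sxy = 0, szy = 0, sy = 0, syy = 0;
    for (int ii = 0; ii < m; ++ii) {
      const int i = idx[ii];
      const double ps = P(i, c0) + P(i, c0 + 1) + P(i, c0 + 2);
      const double xs = (P(i, c0) - P(i, c0 + 2)) / ps;
      const double zs = P(i, c0 + 1) / ps;
      sxx += xs * xs; szz += zs * zs; sxz += xs * zs;
      sx += xs; sz += zs;
      sxy += xs * y[i]; szy += zs * y[i];
      sy += y[i]; syy += y[i] * y[i];
    }
    // centred normal equations
    const double cxx = sxx - sx * sx / m;
    const double czz = szz - sz * sz / m;
    const double cxz = sxz - sx * sz / m;
    const double cxy = sxy - sx * sy / m;
    const double czy = szy - sz * sy / m;
    const double rss0 = syy - sy * sy / m;
    double b1 = 0, b2 = 0;
    const double det = cxx * czz - cxz * cxz;
    const double scale = (cxx > czz ? cxx : czz);
    if (det > 1e-12 * scale * scale && scale > 0) {
      b1 = (cxy * czz - czy * cxz) / det;
      b2 = (czy * cxx - cxy * cxz) / det;
    } else if (cxx > 1e-12) {
      b1 = cxy / cxx;
    } else if (czz > 1e-12) {
      b2 = czy / czz;
    }
    double rss1 = rss0 - (b1 * cxy + b2 * czy);
    if (rss1 < 1e-12 * (rss0 > 1 ? rss0 : 1)) rss1 = 1e-12 * (rss0 > 1 ? rss0 : 1);
    const double b0 = (sy - b1 * sx - b2 * sz) / m;
    double lod = 0.5 * m * std::log10(rss0 / rss1);
    if (!R_finite(lod) || lod < 0) lod = 0;
    out(j, 0) = lod;
    out(j, 1) = b0 + b1;        // muA
    out(j, 2) = b0 + b2;        // muH
    out(j, 3) = b0 - b1;        // muB
    out(j, 4) = rss1 / m;
    out(j, 5) = rss0 / m;
    out(j, 6) = m;
  }
  colnames(out) = CharacterVector::create("lod", "muA", "muH", "muB",
                                          "sigma2", "sigma2_null", "n");
  return out;
}
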