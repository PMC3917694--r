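#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Feasible-region volume of free node ages under the calibrated uniform
// tree prior, by recursive piecewise-polynomial integration.  Each node v
// carries V_v(t): the volume of order-consistent assignments of the free
// ages in v's subtree, all < t.  Tips and fixed (calibrated/root) nodes
// are step functions; free nodes integrate the product of their children.
// Polynomials are kept in shifted local bases (powers of t - break) for
// conditioning; callers pass ages rescaled to O(1).

struct PP {
  std::vector<double> breaks;            // ascending; f = 0 below breaks[0]
  std::vector<std::vector<double>> coefs;  // per piece, ascending powers
};

static double horner(const std::vector<double>& c, double x) {
  double out = 0.0;
  for (int j = (int)c.size() - 1; j >= 0; --j) out = out * x + c[j];
  return out;
}

static double ppEval(const PP& f, double t) {
  if (t < f.breaks[0]) return 0.0;
  int j = (int)(std::upper_bound(f.breaks.begin(), f.breaks.end(), t)
                - f.breaks.begin()) - 1;
  return horner(f.coefs[j], t - f.breaks[j]);
}

static std::vector<double> polyShift(const std::vector<double>& c, double d) {
  int n = (int)c.size();
  if (n == 1 || d == 0.0) return c;
  std::vector<double> out(n, 0.0);
  // out_k = sum_{j>=k} C(j,k) c_j d^(j-k)
  for (int k = 0; k < n; ++k) {
    double binom = 1.0, dp = 1.0, s = 0.0;
    for (int j = k; j < n; ++j) {
      s += c[j] * binom * dp;
      binom = binom * (j + 1) / (double)(j + 1 - k);
      dp *= d;
    }
    out[k] = s;
  }
  return out;
}

static PP ppMul(const PP& f, const PP& g) {
  double start = std::max(f.breaks[0], g.breaks[0]);
  std::vector<double> br;
  br.push_back(start);
  for (double b : f.breaks) if (b > start) br.push_back(b);
  for (double b : g.breaks) if (b > start) br.push_back(b);
  std::sort(br.begin(), br.end());
  br.erase(std::unique(br.begin(), br.end()), br.end());
  PP out; out.breaks = br;
  for (double b : br) {
    int jf = (int)(std::upper_bound(f.breaks.begin(), f.breaks.end(), b)
                   - f.breaks.begin()) - 1;
    int jg = (int)(std::upper_bound(g.breaks.begin(), g.breaks.end(), b)
                   - g.breaks.begin()) - 1;
    std::vector<double> cf = polyShift(f.coefs[jf], b - f.breaks[jf]);
    std::vector<double> cg = polyShift(g.coefs[jg], b - g.breaks[jg]);
    std::vector<double> prod(cf.size() + cg.size() - 1, 0.0);
    for (size_t i = 0; i < cf.size(); ++i)
      for (size_t j = 0; j < cg.size(); ++j) prod[i + j] += cf[i] * cg[j];
    out.coefs.push_back(prod);
  }
  return out;
}

static PP ppIntegrate(const PP& f) {
  PP out; out.breaks = f.breaks;
  double C = 0.0;
  for (size_t i = 0; i < f.breaks.size(); ++i) {
    const std::vector<double>& c = f.coefs[i];
    std::vector<double> anti(c.size() + 1);
    anti[0] = C;
    for (size_t j = 0; j < c.size(); ++j) anti[j + 1] = c[j] / (double)(j + 1);
    out.coefs.push_back(anti);
    if (i + 1 < f.breaks.size())
      C = horner(anti, f.breaks[i + 1] - f.breaks[i]);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_age_log_volume(IntegerVector postorder, IntegerMatrix kids,
                          int nTip, NumericVector fixedAges) {
  const int nNode = 2 * nTip - 1;
  std::vector<PP> pps(nNode);
  for (int i = 0; i < nTip; ++i) {
    pps[i].breaks.assign(1, fixedAges[i]);
    pps[i].coefs.assign(1, std::vector<double>(1, 1.0));
  }
  for (int k = 0; k < postorder.size(); ++k) {
    const int v = postorder[k] - 1;
    PP prod = ppMul(pps[kids(v, 0) - 1], pps[kids(v, 1) - 1]);
    if (NumericVector::is_na(fixedAges[v])) {
      pps[v] = ppIntegrate(prod);
    } else {
      double val = ppEval(prod, fixedAges[v]);
      pps[v].breaks.assign(1, fixedAges[v]);
      pps[v].coefs.assign(1, std::vector<double>(1, val));
    }
  }
  double v = ppEval(pps[nTip], fixedAges[nTip]);  // root id = nTip (0-based)
  if (!(v > 0.0) || !R_FINITE(v)) return R_NegInf;
  return std::log(v);
}
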