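#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning for partitioned GTR+Gamma+I likelihoods.
//
// Node numbering is ape-style (tips 1..nTip, root nTip+1).  `postorder`
// lists internal node ids children-first; `kids` row v holds the two
// children of internal node v (1-based ids, zero rows for tips/unused).
// `lenByNode(v-1, p)` is the branch length (expected substitutions/site,
// already rate- and multiplier-scaled) of the edge above node v for
// partition p.  Tip states are IUPAC bitmasks (A=1, C=2, G=4, T=8).
//
// Per-node rescaling with log-scaler accumulation keeps 200-taxon trees
// finite; the invariant-sites term is combined on the log scale.

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export]]
NumericVector cpp_partition_loglik(int nTip,
                                   IntegerVector postorder,
                                   IntegerMatrix kids,
                                   NumericMatrix lenByNode,
                                   List patterns,
                                   List weights,
                                   List Us, List Uinvs, List lambdas,
                                   NumericMatrix catRates,
                                   NumericVector pinv,
                                   NumericMatrix freqs,
                                   IntegerVector partIdx) {
  const int nNode = 2 * nTip - 1;
  const int root = nTip;  // 0-based id of root (== nTip+1 in 1-based)
  const int nCat = catRates.nrow();
  const int nPost = postorder.size();
  const int* postp = INTEGER(postorder);
  const int* kidsp = INTEGER(kids);      // column-major: kids(v,j)=kidsp[j*nNode+v]
  const double* lenp = REAL(lenByNode);
  NumericVector out(partIdx.size());

  for (int pi = 0; pi < partIdx.size(); ++pi) {
    const int p = partIdx[pi] - 1;
    IntegerMatrix pat = patterns[p];
    const int* patp = INTEGER(pat);      // column-major nTip x npat
    NumericVector w = weights[p];
    NumericMatrix U = Us[p], Uinv = Uinvs[p];
    const double* Up = REAL(U);
    const double* Uip = REAL(Uinv);
    NumericVector lam = lambdas[p];
    const int npat = pat.ncol();
    const double pv = pinv[p];
    const double* fq = REAL(freqs) + (size_t)p * 4;
    const double* blen = lenp + (size_t)p * nNode;

    // constant-compatible state mass per pattern (bit AND over tips)
    std::vector<double> invProb(npat, 0.0);
    for (int i = 0; i < npat; ++i) {
      int m = 15;
      const int* col = patp + (size_t)i * nTip;
      for (int t = 0; t < nTip; ++t) m &= col[t];
      double s = 0.0;
      for (int st = 0; st < 4; ++st) if (m & (1 << st)) s += fq[st];
      invProb[i] = s;
    }

    // category-independent tip partials
    std::vector<double> tipPart((size_t)nTip * npat * 4);
    for (int t = 0; t < nTip; ++t)
      for (int i = 0; i < npat; ++i) {
        const int m = patp[(size_t)i * nTip + t];
        double* pp = &tipPart[((size_t)t * npat + i) * 4];
        pp[0] = m & 1; pp[1] = (m >> 1) & 1;
        pp[2] = (m >> 2) & 1; pp[3] = (m >> 3) & 1;
      }

    std::vector<double> catLog((size_t)npat * nCat);
    std::vector<double> part((size_t)(nNode - nTip) * npat * 4);
    std::vector<double> logscale(npat);
    std::vector<double> P((size_t)nNode * 16);

    for (int cat = 0; cat < nCat; ++cat) {
      const double r = catRates(cat, p);
      for (int v = 0; v < nNode; ++v) {
        if (v == root) continue;
        const double bl = blen[v] * r;
        double e[4];
        for (int k = 0; k < 4; ++k) e[k] = std::exp(lam[k] * bl);
        double* Pv = &P[(size_t)v * 16];
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            double s = 0.0;
            for (int k = 0; k < 4; ++k)
              s += Up[a + 4 * k] * e[k] * Uip[k + 4 * b];
            Pv[a * 4 + b] = s > 0.0 ? s : 0.0;
          }
      }
      std::fill(logscale.begin(), logscale.end(), 0.0);
      for (int k = 0; k < nPost; ++k) {
        const int v = postp[k] - 1;
        const int c1 = kidsp[v] - 1, c2 = kidsp[nNode + v] - 1;
        const double* P1 = &P[(size_t)c1 * 16];
        const double* P2 = &P[(size_t)c2 * 16];
        const double* q1base = c1 < nTip ? &tipPart[(size_t)c1 * npat * 4]
                                         : &part[(size_t)(c1 - nTip) * npat * 4];
        const double* q2base = c2 < nTip ? &tipPart[(size_t)c2 * npat * 4]
                                         : &part[(size_t)(c2 - nTip) * npat * 4];
        double* pvbase = &part[(size_t)(v - nTip) * npat * 4];
        for (int i = 0; i < npat; ++i) {
          const double* q1 = q1base + (size_t)i * 4;
          const double* q2 = q2base + (size_t)i * 4;
          double* pv_ = pvbase + (size_t)i * 4;
          double mx = 0.0;
          for (int a = 0; a < 4; ++a) {
            const double* r1 = P1 + a * 4;
            const double* r2 = P2 + a * 4;
            const double s1 = r1[0] * q1[0] + r1[1] * q1[1] +
                              r1[2] * q1[2] + r1[3] * q1[3];
            const double s2 = r2[0] * q2[0] + r2[1] * q2[1] +
                              r2[2] * q2[2] + r2[3] * q2[3];
            const double val = s1 * s2;
            pv_[a] = val;
            if (val > mx) mx = val;
          }
          if (mx > 0.0 && mx < 1e-80) {
            pv_[0] /= mx; pv_[1] /= mx; pv_[2] /= mx; pv_[3] /= mx;
            logscale[i] += std::log(mx);
          } else if (mx == 0.0) {
            logscale[i] = R_NegInf;
          }
        }
      }
      const double* rp = &part[(size_t)(root - nTip) * npat * 4];
      for (int i = 0; i < npat; ++i) {
        const double* pr = rp + (size_t)i * 4;
        const double s = fq[0] * pr[0] + fq[1] * pr[1] +
                         fq[2] * pr[2] + fq[3] * pr[3];
        catLog[(size_t)i * nCat + cat] =
          s > 0.0 ? std::log(s) + logscale[i] : R_NegInf;
      }
    }

    double total = 0.0;
    const double logCat = -std::log((double)nCat);
    for (int i = 0; i < npat; ++i) {
      double varPart = R_NegInf;
      for (int cat = 0; cat < nCat; ++cat)
        varPart = logsumexp2(varPart, catLog[(size_t)i * nCat + cat]);
      varPart += logCat;
      double a = (pv > 0.0 && invProb[i] > 0.0)
        ? std::log(pv) + std::log(invProb[i]) : R_NegInf;
      double b = (pv < 1.0) ? std::log1p(-pv) + varPart : R_NegInf;
      double li = logsumexp2(a, b);
      if (!R_FINITE(li) && li != R_NegInf)
        stop("numerical underflow in likelihood at pattern %d", i + 1);
      total += w[i] * li;
    }
    out[pi] = total;
  }
  return out;
}
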