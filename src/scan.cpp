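#include <Rcpp.h>
using namespace Rcpp;

// r^2 between two 0/1 haplotype columns given their derived counts and the
// count of haplotypes derived at both.
static inline double r2_from_counts(double n, double ca, double cb,
                                    double cab) {
  double pa = ca / n, pb = cb / n, pab = cab / n;
  double num = pab - pa * pb;
  double den = pa * (1.0 - pa) * pb * (1.0 - pb);
  return num * num / den;
}

// Sliding-window LD contrast: window split at the middle SNP into left
// (floor(W/2)) and right halves; statistic = (mean r2 within left + mean r2
// within right) / (2 * mean r2 between halves + eps), capped at `cap`.
// mat is n_hap x S (0/1). Returns one value per window of W consecutive SNPs.
// [[Rcpp::export(name = ".mu_ld_windows_cpp")]]
NumericVector mu_ld_windows_cpp(IntegerMatrix mat, int W, double eps,
                                double cap) {
  int n = mat.nrow(), S = mat.ncol();
  int nwin = S - W + 1;
  if (nwin < 1) return NumericVector(0);
  NumericVector out(nwin);
  std::vector<double> cnt(S);
  // pack each site's haplotype column into 64-bit words for popcount dots
  int nw64 = (n + 63) / 64;
  std::vector<uint64_t> bits((size_t)S * nw64, 0);
  for (int j = 0; j < S; ++j) {
    int c = 0;
    for (int i = 0; i < n; ++i) {
      if (mat(i, j)) {
        ++c;
        bits[(size_t)j * nw64 + i / 64] |= (uint64_t)1 << (i % 64);
      }
    }
    cnt[j] = c;
  }
  int half = W / 2;
  for (int w = 0; w < nwin; ++w) {
    double sumL = 0, sumR = 0, sumB = 0;
    int nL = 0, nR = 0, nB = 0;
    for (int a = 0; a < W; ++a) {
      int ja = w + a;
      const uint64_t* pa = &bits[(size_t)ja * nw64];
      for (int b = a + 1; b < W; ++b) {
        int jb = w + b;
        const uint64_t* pb = &bits[(size_t)jb * nw64];
        int cab = 0;
        for (int k = 0; k < nw64; ++k)
          cab += __builtin_popcountll(pa[k] & pb[k]);
        double v = r2_from_counts(n, cnt[ja], cnt[jb], cab);
        bool a_left = a < half, b_left = b < half;
        if (a_left && b_left) { sumL += v; ++nL; }
        else if (!a_left && !b_left) { sumR += v; ++nR; }
        else { sumB += v; ++nB; }
      }
    }
    if (nL == 0 || nR == 0) {
      out[w] = NA_REAL;  // a half with < 2 usable sites: window skipped
      continue;
    }
    double within = sumL / nL + sumR / nR;
    double between = sumB / nB;
    double v = within / (2.0 * between + eps);
    out[w] = v > cap ? cap : v;
  }
  return out;
}
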