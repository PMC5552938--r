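#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Patch-grid template matching by normalized cross-correlation.
//
// `a` is tiled into patch_rows x patch_cols patches (remainder to the last
// row/col). Each patch slides over `b` within +/- slide_margin of its home
// position (windows fully inside b only); the patch score is the maximum
// zero-mean normalized correlation coefficient over positions. Constant
// patches (zero variance) score constant_patch_score; constant windows are
// skipped. Returns per-patch scores and the offsets of the best positions.
// [[Rcpp::export]]
List itm_similarity_cpp(NumericMatrix a, NumericMatrix b,
                        int patch_rows, int patch_cols,
                        int slide_margin, double constant_patch_score) {
  const int H = a.nrow(), W = a.ncol();
  const int BH = b.nrow(), BW = b.ncol();
  const double *pa = a.begin(), *pb = b.begin();
  const int npatch = patch_rows * patch_cols;
  const double eps = 1e-12;

  NumericVector scores(npatch);
  IntegerVector best_dr(npatch), best_dc(npatch);
  LogicalVector constant(npatch);

  const int base_h = H / patch_rows, base_w = W / patch_cols;
  int pidx = 0;
  for (int pr = 0; pr < patch_rows; ++pr) {
    const int r0 = pr * base_h;
    const int h = (pr == patch_rows - 1) ? H - r0 : base_h;
    for (int pc = 0; pc < patch_cols; ++pc, ++pidx) {
      const int c0 = pc * base_w;
      const int w = (pc == patch_cols - 1) ? W - c0 : base_w;
      const double n = (double)h * (double)w;

      double suma = 0.0, suma2 = 0.0;
      for (int j = 0; j < w; ++j) {
        const double *acol = pa + (size_t)(c0 + j) * H + r0;
        for (int i = 0; i < h; ++i) { suma += acol[i]; suma2 += acol[i] * acol[i]; }
      }
      const double va = suma2 - suma * suma / n;
      if (va <= eps) {
        scores[pidx] = constant_patch_score;
        best_dr[pidx] = NA_INTEGER; best_dc[pidx] = NA_INTEGER;
        constant[pidx] = true;
        continue;
      }

      double best = R_NegInf;
      int bdr = NA_INTEGER, bdc = NA_INTEGER;
      for (int dr = -slide_margin; dr <= slide_margin; ++dr) {
        const int rr = r0 + dr;
        if (rr < 0 || rr + h > BH) continue;
        for (int dc = -slide_margin; dc <= slide_margin; ++dc) {
          const int cc = c0 + dc;
          if (cc < 0 || cc + w > BW) continue;
          double sumb = 0.0, sumb2 = 0.0, sumab = 0.0;
          for (int j = 0; j < w; ++j) {
            const double *acol = pa + (size_t)(c0 + j) * H + r0;
            const double *bcol = pb + (size_t)(cc + j) * BH + rr;
            for (int i = 0; i < h; ++i) {
              const double av = acol[i], bv = bcol[i];
              sumb += bv; sumb2 += bv * bv; sumab += av * bv;
            }
          }
          const double vb = sumb2 - sumb * sumb / n;
          if (vb <= eps) continue;
          const double ncc = (sumab - suma * sumb / n) / std::sqrt(va * vb);
          if (ncc > best) { best = ncc; bdr = dr; bdc = dc; }
        }
      }
      if (!R_finite(best)) {
        scores[pidx] = constant_patch_score;
        best_dr[pidx] = NA_INTEGER; best_dc[pidx] = NA_INTEGER;
        constant[pidx] = true;
      } else {
        scores[pidx] = best;
        best_dr[pidx] = bdr; best_dc[pidx] = bdc;
      }
    }
  }
  return List::create(_["patch_scores"] = scores,
                      _["best_dr"] = best_dr, _["best_dc"] = best_dc,
                      _["constant"] = constant);
}
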