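#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int iround(double x) { return (int)std::floor(x + 0.5); }

// Part-wise SAD similarity maximized over a scale/translation grid.
//
// `a` is tiled into parts_rows x parts_cols parts (remainder rows/cols to
// the last part). For every part, candidate regions of `b` are sampled
// around the corresponding location for each scale and integer translation;
// translations are applied in the part's scaled coordinate frame, so the
// sample for part pixel (i, j) under (s, dr, dc) is
//   b[round(cy + (i - (h-1)/2 + dr) * s), round(cx + (j - (w-1)/2 + dc) * s)]
// (nearest-neighbour; scale 1 with zero translation reproduces the aligned
// pixels exactly). Candidate similarity is 1 - SAD/(overlap * max_intensity)
// over the in-bounds overlap; candidates whose overlap fraction falls below
// `min_overlap` are skipped. per_part = TRUE takes the max per part and
// averages; otherwise one shared transform maximizes the part mean.
//
// Implementation: per (part, scale) the needed window of b is gathered once
// on the rounded scaled lattice, after which every translation is a
// contiguous sub-window SAD with analytic overlap counts; candidates are
// visited near-identity first so the running best gives an early-abort
// bound (the max is order-independent).
// [[Rcpp::export]]
List sad_similarity_cpp(NumericMatrix a, NumericMatrix b,
                        int parts_rows, int parts_cols,
                        NumericVector scales, int max_translation,
                        double min_overlap, double max_intensity,
                        bool per_part) {
  const int H = a.nrow(), W = a.ncol();
  const int BH = b.nrow(), BW = b.ncol();
  const double *pa = a.begin(), *pb = b.begin();
  const int nparts = parts_rows * parts_cols;
  const int T = max_translation;

  std::vector<double> sc(scales.begin(), scales.end());
  std::sort(sc.begin(), sc.end(), [](double x, double y) {
    return std::fabs(x - 1.0) < std::fabs(y - 1.0);
  });
  std::vector<std::pair<int,int> > trans;
  for (int dr = -T; dr <= T; ++dr)
    for (int dc = -T; dc <= T; ++dc)
      trans.push_back(std::make_pair(dr, dc));
  std::sort(trans.begin(), trans.end(),
            [](const std::pair<int,int> &u, const std::pair<int,int> &v) {
    return u.first * u.first + u.second * u.second <
           v.first * v.first + v.second * v.second;
  });
  const int ntrans = (int)trans.size(), nscale = (int)sc.size();

  std::vector<double> simmat;
  if (!per_part) simmat.assign((size_t)nscale * ntrans * nparts, 0.0);

  NumericVector part_scores(nparts);
  const int base_h = H / parts_rows, base_w = W / parts_cols;
  std::vector<int> rext, cext;
  std::vector<double> G;

  int pidx = 0;
  for (int pr = 0; pr < parts_rows; ++pr) {
    const int r0 = pr * base_h;
    const int h = (pr == parts_rows - 1) ? H - r0 : base_h;
    for (int pc = 0; pc < parts_cols; ++pc, ++pidx) {
      const int c0 = pc * base_w;
      const int w = (pc == parts_cols - 1) ? W - c0 : base_w;
      const double cy = r0 + (h - 1) / 2.0, cx = c0 + (w - 1) / 2.0;
      const double hw = (double)h * (double)w;
      const int gh = h + 2 * T, gw = w + 2 * T;
      rext.resize(gh); cext.resize(gw);
      G.assign((size_t)gh * gw, 0.0);
      double best = -1.0;

      for (int si = 0; si < nscale; ++si) {
        const double s = sc[si];
        for (int i = 0; i < gh; ++i)
          rext[i] = iround(cy + (i - T - (h - 1) / 2.0) * s);
        for (int j = 0; j < gw; ++j)
          cext[j] = iround(cx + (j - T - (w - 1) / 2.0) * s);
        // in-bounds sub-ranges of the gathered lattice (monotone for s > 0)
        int rvlo = 0; while (rvlo < gh && rext[rvlo] < 0) ++rvlo;
        int rvhi = gh; while (rvhi > rvlo && rext[rvhi - 1] >= BH) --rvhi;
        int cvlo = 0; while (cvlo < gw && cext[cvlo] < 0) ++cvlo;
        int cvhi = gw; while (cvhi > cvlo && cext[cvhi - 1] >= BW) --cvhi;
        for (int j = cvlo; j < cvhi; ++j) {
          const double *bcol = pb + (size_t)cext[j] * BH;
          double *gcol = &G[(size_t)j * gh];
          for (int i = rvlo; i < rvhi; ++i) gcol[i] = bcol[rext[i]];
        }

        for (int ti = 0; ti < ntrans; ++ti) {
          const int dr = trans[ti].first, dc = trans[ti].second;
          // overlap of the translated part with the in-bounds lattice
          const int ilo = std::max(0, rvlo - T - dr);
          const int ihi = std::min(h, rvhi - T - dr);
          const int jlo = std::max(0, cvlo - T - dc);
          const int jhi = std::min(w, cvhi - T - dc);
          if (ihi <= ilo || jhi <= jlo) continue;
          const double count = (double)(ihi - ilo) * (double)(jhi - jlo);
          if (count / hw < min_overlap) continue;
          const double abort_thr = (per_part && best > 0.0)
            ? (1.0 - best) * hw * max_intensity : R_PosInf;
          double sad = 0.0;
          bool aborted = false;
          for (int j = jlo; j < jhi; ++j) {
            const double *acol = pa + (size_t)(c0 + j) * H + r0;
            const double *gcol = &G[(size_t)(j + T + dc) * gh + (T + dr)];
            for (int i = ilo; i < ihi; ++i)
              sad += std::fabs(acol[i] - gcol[i]);
            if (sad > abort_thr) { aborted = true; break; }
          }
          if (aborted) continue;
          const double sim = 1.0 - sad / (count * max_intensity);
          if (per_part) {
            if (sim > best) best = sim;
          } else {
            simmat[(size_t)(si * ntrans + ti) * nparts + pidx] = sim;
          }
        }
      }
      if (per_part) part_scores[pidx] = (best < 0.0) ? 0.0 : best;
    }
  }

  double score;
  if (per_part) {
    score = 0.0;
    for (int p = 0; p < nparts; ++p) score += part_scores[p];
    score /= nparts;
  } else {
    score = 0.0;
    int best_t = 0;
    for (int t = 0; t < nscale * ntrans; ++t) {
      double m = 0.0;
      for (int p = 0; p < nparts; ++p) m += simmat[(size_t)t * nparts + p];
      m /= nparts;
      if (m > score) { score = m; best_t = t; }
    }
    for (int p = 0; p < nparts; ++p)
      part_scores[p] = simmat[(size_t)best_t * nparts + p];
  }
  return List::create(_["score"] = score, _["part_scores"] = part_scores);
}
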