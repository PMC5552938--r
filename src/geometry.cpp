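#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bilinear sampling of img at fractional (row, col) positions (1-based, as in
// R matrix indexing). Samples outside [1, nrow] x [1, ncol] return `fill`;
// corners that fall outside during interpolation also contribute `fill`.
// [[Rcpp::export]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector r,
                                  NumericVector c, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double *p = img.begin();
  const int n = r.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    const double rr = r[k] - 1.0, cc = c[k] - 1.0;  // 0-based internal
    if (rr < -0.5 || rr > H - 0.5 || cc < -0.5 || cc > W - 0.5) {
      out[k] = fill;
      continue;
    }
    const int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
    const double fr = rr - r0, fc = cc - c0;
    double v = 0.0;
    for (int di = 0; di <= 1; ++di) {
      for (int dj = 0; dj <= 1; ++dj) {
        const double wgt = (di ? fr : 1.0 - fr) * (dj ? fc : 1.0 - fc);
        if (wgt == 0.0) continue;
        const int ri = r0 + di, ci = c0 + dj;
        const double val = (ri < 0 || ri >= H || ci < 0 || ci >= W)
          ? fill : p[(size_t)ci * H + ri];
        v += wgt * val;
      }
    }
    out[k] = v;
  }
  return out;
}

// Inverse-mapped similarity warp about the image center: the forward model
// maps master point q to s * R(theta) * (q - C) + C + (dy, dx). Bilinear
// sampling, out-of-bounds filled with `fill`. Identity parameters reproduce
// the input exactly.
// [[Rcpp::export]]
NumericMatrix warp_similarity_cpp(NumericMatrix img, double scale,
                                  double theta_deg, double dy, double dx,
                                  double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double *p = img.begin();
  NumericMatrix out(H, W);
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  const double inv_s = 1.0 / scale;
  for (int c = 0; c < W; ++c) {
    const double xc = c - cx - dx;
    for (int r = 0; r < H; ++r) {
      const double yc = r - cy - dy;
      // inverse rotation by -theta, inverse scale
      const double qy = ( ct * yc - st * xc) * inv_s + cy;
      const double qx = ( st * yc + ct * xc) * inv_s + cx;
      double v;
      if (qy < -0.5 || qy > H - 0.5 || qx < -0.5 || qx > W - 0.5) {
        v = fill;
      } else {
        const int r0 = (int)std::floor(qy), c0 = (int)std::floor(qx);
        const double fr = qy - r0, fc = qx - c0;
        v = 0.0;
        for (int di = 0; di <= 1; ++di) {
          for (int dj = 0; dj <= 1; ++dj) {
            const double wgt = (di ? fr : 1.0 - fr) * (dj ? fc : 1.0 - fc);
            if (wgt == 0.0) continue;
            const int ri = r0 + di, ci = c0 + dj;
            const double val = (ri < 0 || ri >= H || ci < 0 || ci >= W)
              ? fill : p[(size_t)ci * H + ri];
            v += wgt * val;
          }
        }
      }
      out(r, c) = v;
    }
  }
  return out;
}

// mean over A points of the distance to the nearest B point; returns +inf
// as soon as the partial sum exceeds `cap * nA` (the best mean seen so far)
static double mean_nn_residual(const arma::mat &TA, const arma::mat &B,
                               double cap = arma::datum::inf) {
  const arma::uword nA = TA.n_rows, nB = B.n_rows;
  const double lim = cap * (double)nA;
  double tot = 0.0;
  for (arma::uword i = 0; i < nA; ++i) {
    double best = arma::datum::inf;
    const double y = TA(i, 0), x = TA(i, 1);
    for (arma::uword j = 0; j < nB; ++j) {
      const double dy = y - B(j, 0), dx = x - B(j, 1);
      const double d2 = dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    tot += std::sqrt(best);
    if (tot > lim) return arma::datum::inf;
  }
  return tot / (double)nA;
}

// Robust affine alignment of keypoint locations only (no descriptors).
// A, B: n x 2 matrices of (row, col) locations. idxA/idxB: iters x 3 0-based
// index triples pre-sampled in R (so seeding stays on the R side). Each
// candidate affine map is solved exactly from the triple, rejected when the
// triple is degenerate or |det| leaves [det_min, det_max] (guards against
// collapse maps that trivially shrink residuals), and scored by the mean
// nearest-neighbour distance from transformed A points to B. The best model
// is polished by trimmed iterative closest point with least-squares affine
// refits. Returns the final residual and transform.
// [[Rcpp::export]]
List point_affine_cpp(arma::mat A, arma::mat B, arma::imat idxA,
                      arma::imat idxB, int refine_iters,
                      double det_min, double det_max) {
  const arma::uword nA = A.n_rows;
  arma::mat M = arma::eye(2, 2);
  arma::vec t = arma::zeros(2);
  double best_res = mean_nn_residual(A, B);  // identity baseline

  const int iters = idxA.n_rows;
  arma::mat TA(nA, 2);
  for (int it = 0; it < iters; ++it) {
    const double y1 = A(idxA(it, 0), 0), x1 = A(idxA(it, 0), 1);
    const double y2 = A(idxA(it, 1), 0), x2 = A(idxA(it, 1), 1);
    const double y3 = A(idxA(it, 2), 0), x3 = A(idxA(it, 2), 1);
    // closed-form 3x3 solve (Cramer) of [yi xi 1] p = target
    const double dX = y1 * (x2 - x3) - x1 * (y2 - y3) + (y2 * x3 - y3 * x2);
    if (std::fabs(dX) < 1e-9) continue;  // collinear or repeated triple
    double Mc[2][2], tc[2];
    for (int c = 0; c < 2; ++c) {
      const double v1 = B(idxB(it, 0), c);
      const double v2 = B(idxB(it, 1), c);
      const double v3 = B(idxB(it, 2), c);
      const double p0 = (v1 * (x2 - x3) - x1 * (v2 - v3) +
                         (v2 * x3 - v3 * x2)) / dX;
      const double p1 = (y1 * (v2 - v3) - v1 * (y2 - y3) +
                         (y2 * v3 - y3 * v2)) / dX;
      const double p2 = (y1 * (x2 * v3 - x3 * v2) - x1 * (y2 * v3 - y3 * v2) +
                         v1 * (y2 * x3 - y3 * x2)) / dX;
      Mc[c][0] = p0; Mc[c][1] = p1; tc[c] = p2;
    }
    const double dt = Mc[0][0] * Mc[1][1] - Mc[0][1] * Mc[1][0];
    if (!std::isfinite(dt) || std::fabs(dt) < det_min || std::fabs(dt) > det_max)
      continue;
    for (arma::uword i = 0; i < nA; ++i) {
      TA(i, 0) = Mc[0][0] * A(i, 0) + Mc[0][1] * A(i, 1) + tc[0];
      TA(i, 1) = Mc[1][0] * A(i, 0) + Mc[1][1] * A(i, 1) + tc[1];
    }
    const double res = mean_nn_residual(TA, B, best_res);
    if (res < best_res) {
      best_res = res;
      M(0, 0) = Mc[0][0]; M(0, 1) = Mc[0][1];
      M(1, 0) = Mc[1][0]; M(1, 1) = Mc[1][1];
      t(0) = tc[0]; t(1) = tc[1];
    }
  }

  // trimmed ICP polish
  for (int k = 0; k < refine_iters; ++k) {
    arma::mat TA = A * M.t();
    TA.each_row() += t.t();
    arma::uvec nn(nA);
    arma::vec d(nA);
    for (arma::uword i = 0; i < nA; ++i) {
      double best = arma::datum::inf;
      arma::uword bj = 0;
      for (arma::uword j = 0; j < B.n_rows; ++j) {
        const double dy = TA(i, 0) - B(j, 0), dx = TA(i, 1) - B(j, 1);
        const double d2 = dy * dy + dx * dx;
        if (d2 < best) { best = d2; bj = j; }
      }
      nn(i) = bj; d(i) = std::sqrt(best);
    }
    const double med = arma::median(d);
    const double thr = std::max(3.0 * med, 1e-8);
    arma::uvec keep = arma::find(d <= thr);
    if (keep.n_elem < 3) {
      arma::uvec ord = arma::sort_index(d);
      keep = ord.head(3);
    }

    arma::mat Xk(keep.n_elem, 3), Yk(keep.n_elem, 2);
    for (arma::uword u = 0; u < keep.n_elem; ++u) {
      const arma::uword i = keep(u);
      Xk(u, 0) = A(i, 0); Xk(u, 1) = A(i, 1); Xk(u, 2) = 1.0;
      Yk(u, 0) = B(nn(i), 0); Yk(u, 1) = B(nn(i), 1);
    }
    arma::mat Pk;
    bool ok = arma::solve(Pk, Xk, Yk);
    if (!ok) break;
    arma::mat Mn = Pk.rows(0, 1).t();
    const double dt = Mn(0, 0) * Mn(1, 1) - Mn(0, 1) * Mn(1, 0);
    if (!std::isfinite(dt) || std::fabs(dt) < det_min || std::fabs(dt) > det_max)
      break;
    arma::vec tn = Pk.row(2).t();
    arma::mat TAn = A * Mn.t();
    TAn.each_row() += tn.t();
    const double res = mean_nn_residual(TAn, B);
    if (res < best_res) { best_res = res; M = Mn; t = tn; }
    else break;
  }

  return List::create(_["residual"] = best_res,
                      _["M"] = M, _["t"] = t);
}
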