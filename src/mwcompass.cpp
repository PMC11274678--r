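#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Conventions shared with the R code: x = column index increasing rightward,
// y = -(row index), so positive angles are counterclockwise when the image is
// displayed with row 1 on top. Pixel centres sit at integer (row, col).

// [[Rcpp::export]]
NumericMatrix rotate_bilinear_cpp(NumericMatrix img, double angle_deg,
                                  double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double cy = (H + 1.0) / 2.0, cx = (W + 1.0) / 2.0;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double xc = (c + 1) - cx;
      double yc = -((r + 1) - cy);
      // inverse rotation to find the source position
      double xs = xc * ct + yc * st;
      double ys = -xc * st + yc * ct;
      double sc = cx + xs;      // source column (1-based, fractional)
      double sr = cy - ys;      // source row
      int c0 = (int)std::floor(sc), r0 = (int)std::floor(sr);
      double fc = sc - c0, fr = sr - r0;
      double v = fill;
      if (r0 >= 1 && r0 + 1 <= H && c0 >= 1 && c0 + 1 <= W) {
        double v00 = img(r0 - 1, c0 - 1), v01 = img(r0 - 1, c0);
        double v10 = img(r0, c0 - 1),     v11 = img(r0, c0);
        v = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
            fr       * ((1 - fc) * v10 + fc * v11);
      } else if (sr >= 0.5 && sr <= H + 0.5 && sc >= 0.5 && sc <= W + 0.5) {
        // within half a pixel of the border: clamp instead of filling
        int rc = std::min(std::max(r0 + (fr > 0.5 ? 1 : 0), 1), H);
        int cc = std::min(std::max(c0 + (fc > 0.5 ? 1 : 0), 1), W);
        v = img(rc - 1, cc - 1);
      }
      out(r, c) = v;
    }
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  // symmetric (half-sample) reflection of a 0-based index onto [0, n)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Weighted sum of shifted copies of img: out(r,c) = sum_k w[k] *
// img(reflect(r + dr[k]), reflect(c + dc[k])). The caller turns a PSF into
// (dr, dc, w) triples; only non-zero kernel entries are passed in.
// [[Rcpp::export]]
NumericMatrix shift_sum_reflect_cpp(NumericMatrix img, IntegerVector dr,
                                    IntegerVector dc, NumericVector w) {
  const int H = img.nrow(), W = img.ncol();
  const int K = w.size();
  NumericMatrix out(H, W);
  for (int k = 0; k < K; ++k) {
    const double wk = w[k];
    const int drk = dr[k], dck = dc[k];
    for (int c = 0; c < W; ++c) {
      const int sc = reflect_idx(c + dck, W);
      const double *col = &img(0, sc);
      double *ocol = &out(0, c);
      for (int r = 0; r < H; ++r)
        ocol[r] += wk * col[reflect_idx(r + drk, H)];
    }
  }
  return out;
}

// Radon transform: line-integral projections. Column j holds the projection
// for angles_deg[j]; each pixel's value is deposited into the offset bins by
// linear interpolation of t = x*cos(phi) + y*sin(phi) (package axis
// convention), so values are non-negative for non-negative images.
// [[Rcpp::export]]
NumericMatrix radon_cpp(NumericMatrix img, NumericVector angles_deg) {
  const int H = img.nrow(), W = img.ncol();
  const double cy = (H + 1.0) / 2.0, cx = (W + 1.0) / 2.0;
  const int A = angles_deg.size();
  const double diag = std::sqrt((double)H * H + (double)W * W);
  const int nbins = (int)std::floor(diag) + 3;
  const double mid = (nbins + 1.0) / 2.0;
  NumericMatrix sino(nbins, A);
  const double *ip = &img(0, 0);
  std::vector<double> yst(H);
  for (int a = 0; a < A; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    double *col = &sino(0, a);
    for (int r = 0; r < H; ++r)
      yst[r] = -((r + 1) - cy) * st + mid;
    for (int c = 0; c < W; ++c) {
      const double xct = ((c + 1) - cx) * ct;
      const double *icol = ip + (size_t)c * H;
      for (int r = 0; r < H; ++r) {
        const double v = icol[r];
        const double p = xct + yst[r];      // fractional bin position
        const int b0 = (int)p;              // p >= 1 for in-range pixels
        const double f = p - b0;
        if (b0 >= 1 && b0 <= nbins) col[b0 - 1] += v * (1.0 - f);
        if (b0 + 1 >= 1 && b0 + 1 <= nbins) col[b0] += v * f;
      }
    }
  }
  return sino;
}

// 8-connected component labelling (two-pass union-find).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);  // parent[0] unused
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // neighbours already visited in column-major order
      const int nr[4] = { r - 1, r - 1, r, r + 1 };
      const int nc[4] = { c - 1, c,     c - 1, c - 1 };
      // (r-1, c) is prior only within the same column; include all four
      // prior neighbours of the 8-neighbourhood for column-major scanning
      for (int k = 0; k < 4; ++k) {
        if (nr[k] < 0 || nr[k] >= H || nc[k] < 0 || nc[k] >= W) continue;
        const int l = lab(nr[k], nc[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        parent.push_back((int)parent.size());
        best = (int)parent.size() - 1;
      }
      lab(r, c) = best;
    }
  }
  // second pass: flatten and renumber densely
  std::vector<int> newid(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > 0) {
        int root = find(lab(r, c));
        if (newid[root] == 0) newid[root] = ++next;
        lab(r, c) = newid[root];
      }
  return lab;
}
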