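#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling (stack-based flood fill).
// Labels are 1..k in first-encounter order (column-major scan), 0 = background.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(j * H + i);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % H, cj = idx / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(nj * H + ni);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Inverse-mapping nearest-neighbour transfer of a binary mask into a target
// frame. ainv (length 4, column-major 2x2) and binv (length 2) give the
// inverse map source = ainv * target + binv in (x = col, y = row) 0-based
// pixel-centre coordinates. Target pixels mapping outside the source frame
// become background.
// [[Rcpp::export(name = ".transfer_nn_cpp")]]
LogicalMatrix transfer_nn_cpp(LogicalMatrix src, NumericVector ainv,
                              NumericVector binv, int H, int W) {
  int h = src.nrow(), w = src.ncol();
  LogicalMatrix out(H, W);
  double a11 = ainv[0], a21 = ainv[1], a12 = ainv[2], a22 = ainv[3];
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double x = a11 * j + a12 * i + binv[0];
      double y = a21 * j + a22 * i + binv[1];
      long fx = std::lround(x), fy = std::lround(y);
      if (fx >= 0 && fy >= 0 && fx < w && fy < h && src(fy, fx))
        out(i, j) = true;
    }
  }
  return out;
}

// Forward-mapped overlap counts used by the registration objective: map
// source foreground pixel centres (full-resolution coords) through the
// candidate transform, divide by the pyramid factor, round to the grid of the
// (subsampled) target mask, and count in-bounds points and target hits.
// [[Rcpp::export(name = ".forward_overlap_cpp")]]
NumericVector forward_overlap_cpp(NumericVector fx, NumericVector fy,
                                  NumericVector a, NumericVector b,
                                  double fac, LogicalMatrix target) {
  int H = target.nrow(), W = target.ncol();
  int n = fx.size();
  double a11 = a[0], a21 = a[1], a12 = a[2], a22 = a[3];
  double nv = 0, nh = 0;
  for (int k = 0; k < n; ++k) {
    double x = (a11 * fx[k] + a12 * fy[k] + b[0]) / fac;
    double y = (a21 * fx[k] + a22 * fy[k] + b[1]) / fac;
    long xi = std::lround(x), yi = std::lround(y);
    if (xi < 0 || yi < 0 || xi >= W || yi >= H) continue;
    nv += 1;
    if (target(yi, xi)) nh += 1;
  }
  return NumericVector::create(nv, nh);
}
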