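// Binary-mask utilities: 8-connected labeling, hole filling, farthest pair.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        int rr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int nr = rr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              q.push(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Fill interior holes: background reachable 4-connectedly from the border
// stays background, everything else becomes foreground.
// [[Rcpp::export(name = ".fill_holes")]]
IntegerMatrix fill_holes(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix outside(H, W);
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if ((r == 0 || r == H - 1 || c == 0 || c == W - 1) &&
          mask(r, c) == 0 && outside(r, c) == 0) {
        outside(r, c) = 1;
        q.push(std::make_pair(r, c));
      }
    }
  }
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    int r = q.front().first, c = q.front().second;
    q.pop();
    for (int k = 0; k < 4; ++k) {
      int nr = r + dr[k], nc = c + dc[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (mask(nr, nc) == 0 && outside(nr, nc) == 0) {
        outside(nr, nc) = 1;
        q.push(std::make_pair(nr, nc));
      }
    }
  }
  IntegerMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      out(r, c) = outside(r, c) ? 0 : 1;
  return out;
}

// Exhaustive farthest pair over a point set (rows of an n x 2 matrix).
// Returns 1-based indices of the maximizing pair and the squared distance.
// [[Rcpp::export(name = ".farthest_pair")]]
List farthest_pair(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 1) stop("no points");
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double dr = pts(i, 0) - pts(j, 0);
      double dc = pts(i, 1) - pts(j, 1);
      double d2 = dr * dr + dc * dc;
      if (d2 > best) { best = d2; bi = i; bj = j; }
    }
  }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1, _["dist2"] = best);
}

// For each row of `a`, the minimum Euclidean distance to rows of `b`, and the
// index of the nearest row. Used by width / parenchyma / surface metrics.
// [[Rcpp::export(name = ".nearest_dists")]]
List nearest_dists(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector d(na);
  IntegerVector idx(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < nb; ++j) {
      double dr = a(i, 0) - b(j, 0), dc = a(i, 1) - b(j, 1);
      double d2 = dr * dr + dc * dc;
      if (d2 < best) { best = d2; bj = j; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bj + 1;
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}
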