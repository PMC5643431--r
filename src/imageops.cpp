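// Low-level binary-image and classifier primitives.
// All matrices are row-major R matrices; coordinates returned to R are 1-based.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int DR8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = { 0, 0,-1, 1};

// Connected-component labelling, conn = 4 or 8.  0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dr = (conn == 8) ? DR8 : DR4;
  const int *dc = (conn == 8) ? DC8 : DC4;
  int nn = (conn == 8) ? 8 : 4;
  int cur = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    if (!mask(r, c) || lab(r, c)) continue;
    ++cur;
    stack.clear(); stack.push_back(r + c * nr);
    lab(r, c) = cur;
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int rr = idx % nr, cc = idx / nr;
      for (int k = 0; k < nn; ++k) {
        int r2 = rr + dr[k], c2 = cc + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (mask(r2, c2) && !lab(r2, c2)) {
          lab(r2, c2) = cur;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  return lab;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance to the nearest TRUE pixel.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix on) {
  int nr = on.nrow(), nc = on.ncol();
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {                     // along columns
    for (int r = 0; r < nr; ++r) f[r] = on(r, c) ? 0.0 : 1e18;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {                     // then rows
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// Zhang-Suen topology-preserving thinning to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(clone(mask));
  std::vector<int> kill;
  bool changed = true;
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c) ? 1 : 0;
  };
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
        if (!img(r, c)) continue;
        int p2 = P(r-1,c), p3 = P(r-1,c+1), p4 = P(r,c+1), p5 = P(r+1,c+1),
            p6 = P(r+1,c), p7 = P(r+1,c-1), p8 = P(r,c-1), p9 = P(r-1,c-1);
        int B = p2+p3+p4+p5+p6+p7+p8+p9;
        if (B < 2 || B > 6) continue;
        int A = (p2==0&&p3==1)+(p3==0&&p4==1)+(p4==0&&p5==1)+(p5==0&&p6==1)
              + (p6==0&&p7==1)+(p7==0&&p8==1)+(p8==0&&p9==1)+(p9==0&&p2==1);
        if (A != 1) continue;
        if (pass == 0) {
          if (p2*p4*p6 != 0 || p4*p6*p8 != 0) continue;
        } else {
          if (p2*p4*p8 != 0 || p2*p6*p8 != 0) continue;
        }
        kill.push_back(r + c * nr);
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i] % nr, kill[i] / nr) = false;
    }
  }
  return img;
}

// Square-window median filter with edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  int w = 2 * radius + 1;
  std::vector<double> buf(w * w);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int n = 0;
    for (int dc = -radius; dc <= radius; ++dc) for (int dr = -radius; dr <= radius; ++dr) {
      int rr = std::min(std::max(r + dr, 0), nr - 1);
      int cc = std::min(std::max(c + dc, 0), nc - 1);
      buf[n++] = img(rr, cc);
    }
    std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
    double med = buf[n / 2];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
      med = 0.5 * (med + lo);
    }
    out(r, c) = med;
  }
  return out;
}

// Sliding square-window mean/sd/max/min (half-width hw, edge replication).
// [[Rcpp::export]]
List cpp_window_stats(NumericMatrix img, int hw) {
  int nr = img.nrow(), nc = img.ncol();
  // padded integral images for mean/sd
  int pr = nr + 2 * hw, pc = nc + 2 * hw;
  std::vector<double> S((pr + 1) * (pc + 1), 0.0), S2((pr + 1) * (pc + 1), 0.0);
  auto padval = [&](int r, int c) -> double {
    int rr = std::min(std::max(r - hw, 0), nr - 1);
    int cc = std::min(std::max(c - hw, 0), nc - 1);
    return img(rr, cc);
  };
  for (int c = 0; c < pc; ++c) for (int r = 0; r < pr; ++r) {
    double v = padval(r, c);
    size_t i = (size_t)(r + 1) + (size_t)(c + 1) * (pr + 1);
    size_t iu = (size_t)r + (size_t)(c + 1) * (pr + 1);
    size_t il = (size_t)(r + 1) + (size_t)c * (pr + 1);
    size_t iul = (size_t)r + (size_t)c * (pr + 1);
    S[i]  = v   + S[iu]  + S[il]  - S[iul];
    S2[i] = v*v + S2[iu] + S2[il] - S2[iul];
  }
  NumericMatrix mu(nr, nc), sd(nr, nc), mx(nr, nc), mn(nr, nc);
  double area = (2.0 * hw + 1) * (2.0 * hw + 1);
  auto rect = [&](std::vector<double> &A, int r0, int c0, int r1, int c1) {
    return A[(size_t)r1 + (size_t)c1 * (pr + 1)] - A[(size_t)r0 + (size_t)c1 * (pr + 1)]
         - A[(size_t)r1 + (size_t)c0 * (pr + 1)] + A[(size_t)r0 + (size_t)c0 * (pr + 1)];
  };
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    double s  = rect(S,  r, c, r + 2 * hw + 1, c + 2 * hw + 1);
    double s2 = rect(S2, r, c, r + 2 * hw + 1, c + 2 * hw + 1);
    mu(r, c) = s / area;
    double var = s2 / area - (s / area) * (s / area);
    sd(r, c) = var > 0 ? std::sqrt(var) : 0.0;
  }
  // separable min/max on the padded image
  NumericMatrix rmx(pr, nc), rmn(pr, nc);
  for (int r = 0; r < pr; ++r) for (int c = 0; c < nc; ++c) {
    double vmax = -1e300, vmin = 1e300;
    for (int dc = 0; dc <= 2 * hw; ++dc) {
      double v = padval(r, c + dc);
      if (v > vmax) vmax = v;
      if (v < vmin) vmin = v;
    }
    rmx(r, c) = vmax; rmn(r, c) = vmin;
  }
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    double vmax = -1e300, vmin = 1e300;
    for (int dr = 0; dr <= 2 * hw; ++dr) {
      if (rmx(r + dr, c) > vmax) vmax = rmx(r + dr, c);
      if (rmn(r + dr, c) < vmin) vmin = rmn(r + dr, c);
    }
    mx(r, c) = vmax; mn(r, c) = vmin;
  }
  return List::create(_["mean"] = mu, _["sd"] = sd, _["max"] = mx, _["min"] = mn);
}

// Viterbi decoding of one observation sequence under Gaussian emissions.
// loglik(t, s) is precomputed in R; here we just run the recursion.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericMatrix loglik, NumericMatrix logtrans, NumericVector loginit) {
  int n = loglik.nrow(), k = loglik.ncol();
  IntegerVector path(n);
  if (n == 0) return path;
  NumericMatrix delta(n, k);
  IntegerMatrix psi(n, k);
  for (int s = 0; s < k; ++s) delta(0, s) = loginit[s] + loglik(0, s);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < k; ++s) {
      double best = -1e300; int arg = 0;
      for (int s0 = 0; s0 < k; ++s0) {
        double v = delta(t - 1, s0) + logtrans(s0, s);
        if (v > best) { best = v; arg = s0; }
      }
      delta(t, s) = best + loglik(t, s);
      psi(t, s) = arg;
    }
  }
  double best = -1e300; int arg = 0;
  for (int s = 0; s < k; ++s) if (delta(n - 1, s) > best) { best = delta(n - 1, s); arg = s; }
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based states
}

// Bilinear affine warp: out(r,c) samples moving at M %*% (r,c) + t (0-based).
// Outside pixels are NaN.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericVector par) {
  int nr = img.nrow(), nc = img.ncol();
  double a11 = par[0], a12 = par[1], a21 = par[2], a22 = par[3], tr = par[4], tc = par[5];
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    double sr = a11 * r + a12 * c + tr;
    double sc = a21 * r + a22 * c + tc;
    if (sr < 0 || sc < 0 || sr > nr - 1 || sc > nc - 1) { out(r, c) = NA_REAL; continue; }
    int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
    int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
    double fr = sr - r0, fc = sc - c0;
    out(r, c) = (1 - fr) * (1 - fc) * img(r0, c0) + (1 - fr) * fc * img(r0, c1)
              + fr * (1 - fc) * img(r1, c0) + fr * fc * img(r1, c1);
  }
  return out;
}

// Meyer-style marker watershed: flood `markers` over `mask` by ascending priority.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers, LogicalMatrix mask) {
  int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix lab(clone(markers));
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r)
    if (markers(r, c) > 0) pq.push(Node(priority(r, c), r + c * nr));
  while (!pq.empty()) {
    int idx = pq.top().second; pq.pop();
    int r = idx % nr, c = idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2) != 0) continue;
      lab(r2, c2) = l;
      pq.push(Node(priority(r2, c2), r2 + c2 * nr));
    }
  }
  return lab;
}

// Moore-neighbour boundary trace of the component containing (r0, c0), 1-based I/O.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(LogicalMatrix mask, int r0, int c0) {
  int nr = mask.nrow(), nc = mask.ncol();
  --r0; --c0;
  // clockwise Moore neighbourhood starting west
  static const int mr[8] = { 0,-1,-1,-1, 0, 1, 1, 1};
  static const int mc[8] = {-1,-1, 0, 1, 1, 1, 0,-1};
  auto inside = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc && mask(r, c);
  };
  std::vector<int> rows, cols;
  int r = r0, c = c0, dir = 0;
  rows.push_back(r); cols.push_back(c);
  int startdir = -1;
  for (int iter = 0; iter < 8 * nr * nc; ++iter) {
    bool found = false;
    for (int k = 0; k < 8; ++k) {
      int d = (dir + k) % 8;
      int r2 = r + mr[d], c2 = c + mc[d];
      if (inside(r2, c2)) {
        if (r == r0 && c == c0) {
          if (startdir < 0) startdir = d;
          else if ((int)rows.size() > 1 && d == startdir) { found = false; break; }
        }
        r = r2; c = c2; dir = (d + 5) % 8;  // backtrack
        rows.push_back(r); cols.push_back(c);
        found = true;
        break;
      }
    }
    if (!found) break;
    if ((int)rows.size() > 2 && r == r0 && c == c0) break;
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) { out(i, 0) = rows[i] + 1; out(i, 1) = cols[i] + 1; }
  return out;
}

// ---------------------------------------------------------------------------
// Bagged CART forest for binary pixel classification (Gini impurity).
// Uses R's RNG so set.seed() governs reproducibility.
// ---------------------------------------------------------------------------
struct TreeNode { int feat; double thr; int left, right; double pred; };

static void build_node(const NumericMatrix &X, const IntegerVector &y,
                       std::vector<int> &idx, int lo, int hi,
                       std::vector<TreeNode> &nodes, int node_id,
                       int mtry, int min_node, int depth, int max_depth) {
  int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  double p1 = (double)pos / n;
  nodes[node_id].pred = p1;
  nodes[node_id].feat = -1;
  if (n < 2 * min_node || depth >= max_depth || pos == 0 || pos == n) return;
  int p = X.ncol();
  // sample mtry features without replacement
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }
  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  double parent = 1.0 - p1 * p1 - (1 - p1) * (1 - p1);
  std::vector<std::pair<double,int> > vals(n);
  for (int jj = 0; jj < mtry && jj < p; ++jj) {
    int j = feats[jj];
    for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[lo + i], j), y[idx[lo + i]]);
    std::sort(vals.begin(), vals.end());
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      int ln = i + 1, rn = n - ln;
      if (ln < min_node || rn < min_node) continue;
      double lp = (double)lpos / ln, rp = (double)(pos - lpos) / rn;
      double g = parent
        - ((double)ln / n) * (1.0 - lp * lp - (1 - lp) * (1 - lp))
        - ((double)rn / n) * (1.0 - rp * rp - (1 - rp) * (1 - rp));
      if (g > best_gain + 1e-12) {
        best_gain = g; best_feat = j;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return;
  // partition idx[lo,hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;
  int li = nodes.size(); nodes.push_back(TreeNode());
  int ri = nodes.size(); nodes.push_back(TreeNode());
  nodes[node_id].feat = best_feat;
  nodes[node_id].thr = best_thr;
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  build_node(X, y, idx, lo, mid, nodes, li, mtry, min_node, depth + 1, max_depth);
  build_node(X, y, idx, mid, hi, nodes, ri, mtry, min_node, depth + 1, max_depth);
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                    int min_node, int max_depth) {
  RNGScope scope;
  int n = X.nrow();
  List trees(ntree);
  NumericVector oob_sum(n);
  IntegerVector oob_n(n);
  std::vector<int> idx(n);
  std::vector<bool> inbag(n);
  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), false);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
      inbag[k] = true;
    }
    std::vector<TreeNode> nodes;
    nodes.push_back(TreeNode());
    build_node(X, y, idx, 0, n, nodes, 0, mtry, min_node, 0, max_depth);
    int m = nodes.size();
    NumericMatrix tm(m, 5);
    for (int i = 0; i < m; ++i) {
      tm(i, 0) = nodes[i].feat; tm(i, 1) = nodes[i].thr;
      tm(i, 2) = nodes[i].feat >= 0 ? nodes[i].left : -1;
      tm(i, 3) = nodes[i].feat >= 0 ? nodes[i].right : -1;
      tm(i, 4) = nodes[i].pred;
    }
    trees[t] = tm;
    // OOB predictions
    for (int i = 0; i < n; ++i) {
      if (inbag[i]) continue;
      int cur = 0;
      while (nodes[cur].feat >= 0)
        cur = (X(i, nodes[cur].feat) <= nodes[cur].thr) ? nodes[cur].left : nodes[cur].right;
      oob_sum[i] += nodes[cur].pred;
      oob_n[i] += 1;
    }
  }
  return List::create(_["trees"] = trees, _["oob_sum"] = oob_sum, _["oob_n"] = oob_n);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while (tm(cur, 0) >= 0)
        cur = (X(i, (int)tm(cur, 0)) <= tm(cur, 1)) ? (int)tm(cur, 2) : (int)tm(cur, 3);
      out[i] += tm(cur, 4);
    }
  }
  return out / (double)ntree;
}
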