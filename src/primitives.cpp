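#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pixel-loop primitives backing the raster operators in R/imageproc.R.
// Matrices are column-major (R layout); index = row + col * nrow.

// [[Rcpp::export]]
NumericMatrix cpp_median3x3(NumericMatrix img) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  double v[9];
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        // edge replication: clamp coordinates to the raster
        int cc = c + dc; if (cc < 0) cc = 0; if (cc >= w) cc = w - 1;
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr; if (rr < 0) rr = 0; if (rr >= h) rr = h - 1;
          v[k++] = img(rr, cc);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(r, c) = v[4];
    }
  }
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of each foreground pixel to the nearest background pixel.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(h, w);
  // pass 1: columns
  {
    std::vector<double> f(h), d(h);
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) f[r] = mask(r, c) ? INF : 0.0;
      edt_1d(f, d, h);
      for (int r = 0; r < h; ++r) g(r, c) = d[r];
    }
  }
  // pass 2: rows
  NumericMatrix out(h, w);
  {
    std::vector<double> f(w), d(w);
    for (int r = 0; r < h; ++r) {
      for (int c = 0; c < w; ++c) f[c] = g(r, c);
      edt_1d(f, d, w);
      for (int c = 0; c < w; ++c) out(r, c) = std::sqrt(d[c]);
    }
  }
  return out;
}

// Fill background regions not 4-connected to the raster border.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  std::vector<char> reach((size_t)h * w, 0);
  std::queue<int> q;
  auto push = [&](int r, int c) {
    int idx = r + c * h;
    if (!mask(r, c) && !reach[idx]) { reach[idx] = 1; q.push(idx); }
  };
  for (int c = 0; c < w; ++c) { push(0, c); push(h - 1, c); }
  for (int r = 0; r < h; ++r) { push(r, 0); push(r, w - 1); }
  const int dr[4] = { -1, 1, 0, 0 };
  const int dc[4] = { 0, 0, -1, 1 };
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % h, c = idx / h;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr >= 0 && rr < h && cc >= 0 && cc < w) push(rr, cc);
    }
  }
  LogicalMatrix out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      out(r, c) = mask(r, c) || !reach[r + c * h];
  return out;
}

// Connected-component labeling; labels assigned in row-major raster order of
// each component's first pixel, so output labels are contiguous 1..K.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  int n8 = (connectivity == 8) ? 8 : 4;
  const int dr[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dc[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * h);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int pr = idx % h, pc = idx / h;
        for (int k = 0; k < n8; ++k) {
          int rr = pr + dr[k], cc = pc + dc[k];
          if (rr >= 0 && rr < h && cc >= 0 && cc < w &&
              mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * h);
          }
        }
      }
    }
  }
  return lab;
}

// Grayscale reconstruction by dilation of marker under mask (hybrid
// raster-scan + FIFO algorithm), 8-connectivity. Used for the h-maxima
// transform that merges regional maxima separated by shallow dips.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  const int h = marker.nrow(), w = marker.ncol();
  NumericMatrix J(clone(marker));
  // forward pass: neighbors already visited in raster (column-major) order
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      double m = J(r, c);
      if (r > 0) m = std::max(m, J(r - 1, c));
      if (c > 0) {
        m = std::max(m, J(r, c - 1));
        if (r > 0) m = std::max(m, J(r - 1, c - 1));
        if (r < h - 1) m = std::max(m, J(r + 1, c - 1));
      }
      J(r, c) = std::min(m, mask(r, c));
    }
  }
  // backward pass + seed queue
  std::queue<int> q;
  for (int c = w - 1; c >= 0; --c) {
    for (int r = h - 1; r >= 0; --r) {
      double m = J(r, c);
      if (r < h - 1) m = std::max(m, J(r + 1, c));
      if (c < w - 1) {
        m = std::max(m, J(r, c + 1));
        if (r < h - 1) m = std::max(m, J(r + 1, c + 1));
        if (r > 0) m = std::max(m, J(r - 1, c + 1));
      }
      J(r, c) = std::min(m, mask(r, c));
      bool push = false;
      for (int dc = 0; dc <= 1 && !push; ++dc) {
        for (int dr = -1; dr <= 1 && !push; ++dr) {
          if (dr <= 0 && dc == 0) continue;   // only N- neighbors
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
          if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) push = true;
        }
      }
      if (push) q.push(r + c * h);
    }
  }
  const int dr8[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dc8[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % h, c = idx / h;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(J(r, c), mask(rr, cc));
        q.push(rr + cc * h);
      }
    }
  }
  return J;
}

// Marker-controlled watershed on a height map (here: negated distance map,
// flooded from the highest distance downward). Seeds carry positive labels;
// pixels where two catchment basins meet become watershed lines (label 0),
// so split objects are disconnected in the output.
struct WsEntry {
  double d; long ord; int idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.d != b.d) return a.d < b.d;   // pop highest distance first
    return a.ord > b.ord;               // FIFO among equal heights
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix dist, IntegerMatrix seeds, LogicalMatrix mask) {
  const int h = dist.nrow(), w = dist.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  const int WSHED = -1;
  const int dr[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dc[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long ord = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) lab(r, c) = seeds(r, c);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr >= 0 && rr < h && cc >= 0 && cc < w &&
            mask(rr, cc) && lab(rr, cc) == 0)
          pq.push({ dist(rr, cc), ord++, rr + cc * h });
      }
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int r = e.idx % h, c = e.idx / h;
    if (lab(r, c) != 0) continue;
    int found = 0; bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
      int l = lab(rr, cc);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    if (found == 0) continue;           // re-queued later by a labeled neighbor
    lab(r, c) = conflict ? WSHED : found;
    if (!conflict) {
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr >= 0 && rr < h && cc >= 0 && cc < w &&
            mask(rr, cc) && lab(rr, cc) == 0)
          pq.push({ dist(rr, cc), ord++, rr + cc * h });
      }
    }
  }
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      if (lab(r, c) == WSHED) lab(r, c) = 0;
  return lab;
}
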