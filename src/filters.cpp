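#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>

using namespace Rcpp;

// Window anchor shared by all median paths: a window of side w centred at i
// spans rows/cols [i - floor(w/2), i + (w - 1 - floor(w/2))], i.e. [-w/2,
// w/2 - 1] for even w and the symmetric window for odd w.  Windows are
// clipped at the image border (median over the available pixels).
static inline void window_bounds(int i, int w, int n, int &lo, int &hi) {
  lo = i - w / 2;
  hi = lo + w - 1;
  if (lo < 0) lo = 0;
  if (hi > n - 1) hi = n - 1;
}

// Lower median: the k-th smallest with k = (n + 1) / 2 (integer division),
// so the output value always occurs in the window.

// Sliding-histogram median for values lying on the 1/256 grey grid in
// [0, 255] (this covers plain 8-bit images, whose values are whole greys).
// Values are mapped to integer keys k = v * 256 in [0, 65535] and tracked
// in a two-level histogram (256 coarse blocks over 65536 fine bins), one
// histogram per output row, updated column by column; cost O(H * W * w)
// plus at most a 512-bin scan per pixel.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter_q16(const NumericMatrix &img, int window) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  std::vector<int> key((size_t)H * W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      key[(size_t)(y + x * H)] = (int)(img(y, x) * 256.0 + 0.5);
  std::vector<int> fine(65536), coarse(256);

  for (int y = 0; y < H; ++y) {
    int ry0, ry1;
    window_bounds(y, window, H, ry0, ry1);

    std::fill(fine.begin(), fine.end(), 0);
    std::fill(coarse.begin(), coarse.end(), 0);
    int cx0, cx1;
    window_bounds(0, window, W, cx0, cx1);
    int n = 0;
    for (int x = cx0; x <= cx1; ++x)
      for (int r = ry0; r <= ry1; ++r) {
        int k = key[(size_t)(r + x * H)];
        ++fine[k]; ++coarse[k >> 8]; ++n;
      }

    for (int x = 0; x < W; ++x) {
      if (x > 0) {
        int drop = (x - 1) - window / 2;            // leftmost col of old window
        if (drop >= 0) {
          for (int r = ry0; r <= ry1; ++r) {
            int k = key[(size_t)(r + drop * H)];
            --fine[k]; --coarse[k >> 8]; --n;
          }
        }
        int add = x - window / 2 + window - 1;      // rightmost col of new window
        if (add <= W - 1) {
          for (int r = ry0; r <= ry1; ++r) {
            int k = key[(size_t)(r + add * H)];
            ++fine[k]; ++coarse[k >> 8]; ++n;
          }
        }
      }
      int target = (n + 1) / 2, cum = 0, blk = 0;
      for (; blk < 256; ++blk) { cum += coarse[blk]; if (cum >= target) break; }
      cum -= coarse[blk];
      int k = blk << 8;
      for (;; ++k) { cum += fine[k]; if (cum >= target) break; }
      out(y, x) = k / 256.0;
    }
  }
  return out;
}

// Exact generic median filter for arbitrary numeric data; O(w^2 log w) per
// pixel, intended for small images and oracle-style use.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter_naive(const NumericMatrix &img, int window) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);

  for (int y = 0; y < H; ++y) {
    int ry0, ry1;
    window_bounds(y, window, H, ry0, ry1);
    for (int x = 0; x < W; ++x) {
      int cx0, cx1;
      window_bounds(x, window, W, cx0, cx1);
      buf.clear();
      for (int c = cx0; c <= cx1; ++c)
        for (int r = ry0; r <= ry1; ++r) buf.push_back(img(r, c));
      size_t k = (buf.size() + 1) / 2 - 1;
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(y, x) = buf[k];
    }
  }
  return out;
}

struct Cand { double v; int y; int x; };

// Prominence-based local-maxima segmentation.
//
// Candidates are pixels with no strictly higher 8-neighbour.  Candidates are
// visited in decreasing value (ties in raster order: smallest y, then x).  A
// candidate at value v is accepted when the connected region of pixels with
// value >= v - tolerance reachable from it contains no pixel higher than v
// and no pixel already claimed by a stronger (or earlier equal) peak — i.e.
// a maximum within the noise tolerance of higher ground is suppressed.
// Accepted peaks claim their region by flood fill over unclaimed qualifying
// pixels; a pixel adjacent to a different label is left unclaimed so
// distinct peak regions stay separated by at least one background pixel.
//
// When a candidate is rejected, every pixel of equal value inside the
// traversed region is marked dead: it spans the identical region at the
// identical threshold, so it would be rejected for the same reason.  This
// keeps the total flood work bounded by (#distinct values) x (image size)
// on heavily quantised (8-bit) images.
// [[Rcpp::export]]
List cpp_find_maxima(const NumericMatrix &img, double tolerance,
                     bool exclude_edges, int connectivity) {
  const int H = img.nrow(), W = img.ncol();
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, 1, -1, 0};
  const int *gdy = (connectivity == 4) ? dy4 : dy8;
  const int *gdx = (connectivity == 4) ? dx4 : dx8;
  const int gn = (connectivity == 4) ? 4 : 8;

  // candidate scan: no strictly higher 8-neighbour
  std::vector<Cand> cands;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double v = img(y, x);
      bool is_cand = true;
      for (int k = 0; k < 8 && is_cand; ++k) {
        int ny = y + dy8[k], nx = x + dx8[k];
        if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
        if (img(ny, nx) > v) is_cand = false;
      }
      if (is_cand) cands.push_back({v, y, x});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.v != b.v) return a.v > b.v;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });

  IntegerMatrix labels(H, W);                 // 0 = background
  std::vector<int> stamp((size_t)H * W, 0);   // visit epochs for traversal
  std::vector<char> dead((size_t)H * W, 0);   // known-rejected pixels
  int epoch = 0;
  std::vector<int> stack_;
  std::vector<int> visited;
  std::vector<int> px, py;

  for (const Cand &c : cands) {
    if (labels(c.y, c.x) != 0) continue;      // claimed: within a stronger peak
    if (dead[(size_t)(c.y + c.x * H)]) continue;
    if (exclude_edges && (c.y == 0 || c.x == 0 || c.y == H - 1 || c.x == W - 1))
      continue;
    const double vc = c.v, floor_ = vc - tolerance;

    // traversal flood: reject if higher ground or an already-claimed region
    // is reachable without descending more than `tolerance` below the peak
    ++epoch;
    bool reject = false;
    stack_.clear();
    visited.clear();
    stack_.push_back(c.y + c.x * H);
    stamp[(size_t)(c.y + c.x * H)] = epoch;
    visited.push_back(c.y + c.x * H);
    while (!stack_.empty() && !reject) {
      int idx = stack_.back(); stack_.pop_back();
      int y = idx % H, x = idx / H;
      for (int k = 0; k < gn; ++k) {
        int ny = y + gdy[k], nx = x + gdx[k];
        if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
        double v = img(ny, nx);
        if (v < floor_) continue;
        if (v > vc || labels(ny, nx) != 0) { reject = true; break; }
        size_t nidx = (size_t)(ny + nx * H);
        if (stamp[nidx] != epoch) {
          stamp[nidx] = epoch;
          stack_.push_back(nidx);
          visited.push_back(nidx);
        }
      }
    }
    if (reject) {
      for (int idx : visited)
        if (img(idx % H, idx / H) == vc) dead[(size_t)idx] = 1;
      continue;
    }

    // claim flood: grow the region for this accepted peak
    int lab = (int)px.size() + 1;
    labels(c.y, c.x) = lab;
    stack_.clear();
    stack_.push_back(c.y + c.x * H);
    while (!stack_.empty()) {
      int idx = stack_.back(); stack_.pop_back();
      int y = idx % H, x = idx / H;
      for (int k = 0; k < gn; ++k) {
        int ny = y + gdy[k], nx = x + gdx[k];
        if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
        if (labels(ny, nx) != 0) continue;
        if (img(ny, nx) < floor_) continue;
        bool touches_other = false;
        for (int j = 0; j < 8 && !touches_other; ++j) {
          int qy = ny + dy8[j], qx = nx + dx8[j];
          if (qy < 0 || qy >= H || qx < 0 || qx >= W) continue;
          int l = labels(qy, qx);
          if (l != 0 && l != lab) touches_other = true;
        }
        if (touches_other) continue;          // watershed line between regions
        labels(ny, nx) = lab;
        stack_.push_back(ny + nx * H);
      }
    }
    px.push_back(c.x);
    py.push_back(c.y);
  }

  return List::create(_["labels"] = labels,
                      _["peak_x"] = wrap(px),
                      _["peak_y"] = wrap(py));
}

// Connected-component labelling of a binary mask (values 0/1), 4- or
// 8-connectivity.  Returns the label matrix and per-component pixel areas.
// [[Rcpp::export]]
List cpp_label_components(const IntegerMatrix &mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, 1, -1, 0};
  const int *gdy = (connectivity == 4) ? dy4 : dy8;
  const int *gdx = (connectivity == 4) ? dx4 : dx8;
  const int gn = (connectivity == 4) ? 4 : 8;

  IntegerMatrix labels(H, W);
  std::vector<int> areas;
  std::vector<int> stack_;

  for (int y0 = 0; y0 < H; ++y0) {
    for (int x0 = 0; x0 < W; ++x0) {
      if (mask(y0, x0) == 0 || labels(y0, x0) != 0) continue;
      int lab = (int)areas.size() + 1, area = 0;
      labels(y0, x0) = lab;
      stack_.clear();
      stack_.push_back(y0 + x0 * H);
      while (!stack_.empty()) {
        int idx = stack_.back(); stack_.pop_back();
        ++area;
        int y = idx % H, x = idx / H;
        for (int k = 0; k < gn; ++k) {
          int ny = y + gdy[k], nx = x + gdx[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) == 0 || labels(ny, nx) != 0) continue;
          labels(ny, nx) = lab;
          stack_.push_back(ny + nx * H);
        }
      }
      areas.push_back(area);
    }
  }

  return List::create(_["labels"] = labels, _["areas"] = wrap(areas));
}
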