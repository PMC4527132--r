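// Label-map primitives: 8-connected component labelling with deterministic
// raster-order labels, and a seeded watershed by priority flooding.  Both
// are fully tie-break-specified so identical inputs always give identical
// label maps.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
using namespace Rcpp;

// Matrices are column-major (R layout); "raster order" here means
// row-major scan order (row 1 left to right, then row 2, ...), matching the
// way the images are described and displayed.
static inline double raster_index(int r, int c, int ncol) {
  return (double)r * ncol + c;
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.emplace_back(r, c);
      lab(r, c) = next;
      while (!stack.empty()) {
        auto [cr, cc] = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.emplace_back(r2, c2);
            }
          }
        }
      }
    }
  }
  return lab;
}

struct QueueItem {
  double elevation;
  long long order;   // FIFO tie-break: earlier-queued pixels flood first
  int r, c, label;
};
struct QueueCmp {
  bool operator()(const QueueItem& a, const QueueItem& b) const {
    if (a.elevation != b.elevation) return a.elevation > b.elevation; // min-heap
    return a.order > b.order;
  }
};

// Seeded watershed restricted to mask > 0: floods outward from the seed
// pixels in order of increasing elevation; every mask pixel ends up with
// the label of the seed whose flood reached it first.  Seeds are expected
// one pixel per object (label value at that pixel), already suppressed.
// [[Rcpp::export(name = ".seeded_watershed")]]
IntegerMatrix seeded_watershed(NumericMatrix elevation, IntegerMatrix mask,
                               IntegerMatrix seed_rows, IntegerVector seed_labels) {
  const int nr = elevation.nrow(), nc = elevation.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("elevation and mask dimensions differ");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QueueItem, std::vector<QueueItem>, QueueCmp> pq;
  long long order = 0;
  const int ns = seed_rows.nrow();
  for (int i = 0; i < ns; ++i) {
    int r = seed_rows(i, 0) - 1, c = seed_rows(i, 1) - 1; // 1-based from R
    if (r < 0 || r >= nr || c < 0 || c >= nc) stop("seed outside image");
    if (mask(r, c) == 0) stop("seed outside mask");
    lab(r, c) = seed_labels[i];
    pq.push({elevation(r, c), order++, r, c, seed_labels[i]});
  }
  while (!pq.empty()) {
    QueueItem it = pq.top();
    pq.pop();
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int r2 = it.r + dr, c2 = it.c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (mask(r2, c2) == 0 || lab(r2, c2) != 0) continue;
        lab(r2, c2) = it.label;
        // flood order: a neighbour may not be popped before its queuing
        // elevation; clamp to the current front so the queue stays monotone
        double e2 = elevation(r2, c2) > it.elevation ? elevation(r2, c2)
                                                     : it.elevation;
        pq.push({e2, order++, r2, c2, it.label});
      }
    }
  }
  return lab;
}

// Local maxima of `img` within mask > 0 (8-neighbourhood; neighbours
// outside the mask are ignored).  Returns a 0/1 matrix of candidate pixels;
// plateau handling (one seed per connected equal-value plateau) is done on
// the R side with cc_label.
// [[Rcpp::export(name = ".local_max_mask")]]
IntegerMatrix local_max_mask(NumericMatrix img, IntegerMatrix mask) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0) continue;
      double v = img(r, c);
      bool ok = true;
      for (int dr = -1; dr <= 1 && ok; ++dr)
        for (int dc = -1; dc <= 1 && ok; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) == 0) continue;
          if (img(r2, c2) > v) ok = false;
        }
      if (ok) out(r, c) = 1;
    }
  }
  return out;
}
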