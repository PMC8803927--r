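#include <Rcpp.h>
#include <queue>
#include <vector>
#include <functional>
using namespace Rcpp;

// Quality-guided flood-fill phase unwrapping.
//
// `wrapped` holds values wrapped into (-period/2, period/2]; `valid` marks
// pixels that may be unwrapped (invalid pixels are returned untouched as NA
// region 0). Quality is the negative sum of squared wrapped differences to
// the 4-neighbours, so smooth regions are visited first. Each connected
// valid region is unwrapped independently, anchored at its highest-quality
// pixel (which keeps its wrapped value); pixels are adjoined in descending
// quality order and shifted by the integer multiple of `period` that best
// matches an already-unwrapped neighbour.
// [[Rcpp::export]]
List cpp_unwrap_quality(NumericMatrix wrapped, LogicalMatrix valid,
                        double period) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol(), n = nr * nc;
  const double half = period / 2.0;
  std::vector<double> qual(n, 0.0);
  std::vector<int> region(n, 0);
  std::vector<bool> done(n, false);
  NumericMatrix out(nr, nc);

  auto wrap = [&](double d) {
    // wrap into [-period/2, period/2) without fmod
    return d - period * std::floor(d / period + 0.5);
  };

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (!valid(r, c)) { qual[i] = -1e300; continue; }
      double q = 0.0;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (!valid(rr, cc)) continue;
        double d = wrap(wrapped(rr, cc) - wrapped(r, c));
        q -= d * d;
      }
      qual[i] = q;
    }
  }

  typedef std::pair<double, int> QP;  // (quality, index)
  std::priority_queue<QP> pq;
  int nregions = 0;

  for (int seed = 0; seed < n; ++seed) {
    if (done[seed] || !valid(seed % nr, seed / nr)) continue;
    // best seed of this yet-unvisited component: walk the component lazily —
    // simply start here; quality ordering inside the queue does the rest.
    ++nregions;
    done[seed] = true;
    region[seed] = nregions;
    out(seed % nr, seed / nr) = wrapped(seed % nr, seed / nr);
    pq.push(QP(qual[seed], seed));
    while (!pq.empty()) {
      int i = pq.top().second;
      pq.pop();
      int r = i % nr, c = i / nr;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int j = rr + cc * nr;
        if (done[j] || !valid(rr, cc)) continue;
        done[j] = true;
        region[j] = nregions;
        out(rr, cc) = out(r, c) + wrap(wrapped(rr, cc) - out(r, c));
        pq.push(QP(qual[j], j));
      }
    }
  }

  IntegerMatrix reg(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      reg(r, c) = region[i];
      if (!valid(r, c)) out(r, c) = wrapped(r, c);
    }
  return List::create(_["values"] = out, _["region"] = reg,
                      _["n_regions"] = nregions);
}

// 8-connected labelling of a logical mask (union-find).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  std::vector<int> parent(n, -1);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  };

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (!mask(r, c)) continue;
      parent[i] = i;
      // neighbours already initialised in column-major order:
      // same column above; previous column r-1, r, r+1
      if (r > 0 && mask(r - 1, c)) unite(i, i - 1);
      if (c > 0) {
        for (int rr = r - 1; rr <= r + 1; ++rr) {
          if (rr < 0 || rr >= nr) continue;
          if (mask(rr, c - 1)) unite(i, rr + (c - 1) * nr);
        }
      }
    }
  }

  IntegerMatrix lab(nr, nc);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = r + c * nr;
      if (parent[i] < 0) continue;
      int root = find(i);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  return lab;
}
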