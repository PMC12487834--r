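#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Non-flat grayscale morphology with a hemispherical ("ball") structuring
// element of the given radius, and a topographic-prominence Find Maxima
// segmentation. These are the pixel-level primitives of the semiautomated
// SA-beta-Gal quantifier; written in C++ because they are per-pixel loops
// over a structuring-element window.

struct BallOffset {
  int dr, dc;
  double h; // structuring element height at this offset
};

static std::vector<BallOffset> ball_offsets(int radius) {
  std::vector<BallOffset> off;
  double r2 = (double)radius * radius;
  for (int dr = -radius; dr <= radius; ++dr) {
    for (int dc = -radius; dc <= radius; ++dc) {
      double d2 = (double)dr * dr + (double)dc * dc;
      if (d2 <= r2) off.push_back({dr, dc, std::sqrt(r2 - d2)});
    }
  }
  return off;
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_erode(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<BallOffset> off = ball_offsets(radius);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_PosInf;
      for (size_t i = 0; i < off.size(); ++i) {
        int rr = r + off[i].dr, cc = c + off[i].dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc) - off[i].h;
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_dilate(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<BallOffset> off = ball_offsets(radius);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (size_t i = 0; i < off.size(); ++i) {
        int rr = r + off[i].dr, cc = c + off[i].dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc) + off[i].h;
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// union-find with path compression
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Find local maxima by flooding in decreasing intensity order. A maximum
// survives as its own region only if it exceeds the saddle to any higher
// region by at least `prominence`; otherwise it is merged into the higher
// region at the saddle. Pixels below `min_threshold` are background (label 0).
// Returns an integer label matrix (one region per accepted maximum, labelled
// in decreasing peak order) and a peaks matrix (row, col, value; 1-based).
// [[Rcpp::export]]
List cpp_find_maxima(NumericMatrix img, double prominence, double min_threshold) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i)
    if (img[i] >= min_threshold) idx.push_back(i);
  // decreasing value, ties broken by linear index for determinism
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (img[a] != img[b]) return img[a] > img[b];
    return a < b;
  });

  std::vector<int> parent(n, -1);     // -1 = unprocessed
  std::vector<double> peakval(n, 0);  // valid at roots
  std::vector<int> peakidx(n, -1);    // valid at roots

  const int drs[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dcs[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  std::vector<int> roots;
  for (size_t k = 0; k < idx.size(); ++k) {
    int p = idx[k];
    int r = p % nr, c = p / nr;
    double v = img[p];
    roots.clear();
    for (int j = 0; j < 8; ++j) {
      int rr = r + drs[j], cc = c + dcs[j];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int q = rr + cc * nr;
      if (parent[q] == -1) continue;
      int rt = uf_find(parent, q);
      if (std::find(roots.begin(), roots.end(), rt) == roots.end())
        roots.push_back(rt);
    }
    if (roots.empty()) {
      parent[p] = p;
      peakval[p] = v;
      peakidx[p] = p;
    } else {
      // attach to the root with the highest peak; merge non-prominent others
      int hi = roots[0];
      for (size_t j = 1; j < roots.size(); ++j)
        if (peakval[roots[j]] > peakval[hi]) hi = roots[j];
      parent[p] = hi;
      for (size_t j = 0; j < roots.size(); ++j) {
        int rt = roots[j];
        if (rt == hi) continue;
        if (peakval[rt] - v < prominence) parent[rt] = hi; // absorbed at saddle
      }
    }
  }

  // collect surviving roots, label in decreasing peak order
  std::vector<int> final_roots;
  for (size_t k = 0; k < idx.size(); ++k) {
    int p = idx[k];
    if (uf_find(parent, p) == p) final_roots.push_back(p);
  }
  std::stable_sort(final_roots.begin(), final_roots.end(), [&](int a, int b) {
    if (peakval[a] != peakval[b]) return peakval[a] > peakval[b];
    return a < b;
  });
  std::vector<int> labof(n, 0);
  for (size_t k = 0; k < final_roots.size(); ++k)
    labof[final_roots[k]] = (int)k + 1;

  IntegerMatrix labels(nr, nc);
  for (size_t k = 0; k < idx.size(); ++k) {
    int p = idx[k];
    labels[p] = labof[uf_find(parent, p)];
  }
  int K = final_roots.size();
  NumericMatrix peaks(K, 3);
  for (int k = 0; k < K; ++k) {
    int p = peakidx[final_roots[k]];
    peaks(k, 0) = (p % nr) + 1;
    peaks(k, 1) = (p / nr) + 1;
    peaks(k, 2) = img[p];
  }
  colnames(peaks) = CharacterVector::create("row", "col", "value");
  return List::create(_["labels"] = labels, _["peaks"] = peaks);
}
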