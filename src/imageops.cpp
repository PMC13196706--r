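// Low-level image and point-cloud kernels.
// These are the hot loops of the pipeline (per-slice filtering, labeling,
// distance transforms, brute-force kNN); everything else lives in R.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <utility>
#include <vector>

using namespace Rcpp;

// Square-window median filter with edge truncation (window clipped at the
// image border, median of the remaining pixels).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, const int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> win;
  win.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      win.clear();
      for (int dj = -radius; dj <= radius; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -radius; di <= radius; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          win.push_back(img(ii, jj));
        }
      }
      const size_t m = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + m, win.end());
      double med = win[m];
      if (win.size() % 2 == 0) {
        med = 0.5 * (med + *std::max_element(win.begin(), win.begin() + m));
      }
      out(i, j) = med;
    }
  }
  return out;
}

// 8-connected component labeling; labels are 1..n in scan order, 0 background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<std::pair<int, int> > todo;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++cur;
      todo.push_back(std::make_pair(i, j));
      while (!todo.empty()) {
        const std::pair<int, int> p = todo.back();
        todo.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = cur;
              todo.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Felzenszwalb & Huttenlocher 1-D lower-envelope squared distance transform.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  const double w2) {
  const int n = static_cast<int>(f.size());
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (physical units) from every TRUE pixel to the
// nearest FALSE pixel; FALSE pixels get 0. Pixels are anisotropic
// (sp_row x sp_col). The image border is not treated as background.
// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(const LogicalMatrix& mask,
                                     const double sp_row, const double sp_col) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e30;
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) g(i, j) = mask(i, j) ? BIG : 0.0;
  std::vector<double> f(nr), d(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    edt1d(f, d, sp_row * sp_row);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  std::vector<double> f2(nc), d2(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f2[j] = g(i, j);
    edt1d(f2, d2, sp_col * sp_col);
    for (int j = 0; j < nc; ++j) g(i, j) = std::sqrt(std::min(d2[j], BIG));
  }
  return g;
}

static std::vector<std::pair<int, int> > disk_offsets(const double radius) {
  std::vector<std::pair<int, int> > off;
  const int r = static_cast<int>(std::floor(radius));
  for (int dj = -r; dj <= r; ++dj)
    for (int di = -r; di <= r; ++di)
      if (di * di + dj * dj <= radius * radius + 1e-9)
        off.push_back(std::make_pair(di, dj));
  return off;
}

// [[Rcpp::export]]
LogicalMatrix cpp_binary_dilate(const LogicalMatrix& mask, const double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const std::vector<std::pair<int, int> > off = disk_offsets(radius);
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      for (size_t m = 0; m < off.size(); ++m) {
        const int ii = i + off[m].first, jj = j + off[m].second;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(ii, jj) = true;
      }
    }
  }
  return out;
}

// Erosion with out-of-image treated as foreground, so that closing
// (dilate o erode) remains extensive at the border.
// [[Rcpp::export]]
LogicalMatrix cpp_binary_erode(const LogicalMatrix& mask, const double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const std::vector<std::pair<int, int> > off = disk_offsets(radius);
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool keep = mask(i, j);
      for (size_t m = 0; keep && m < off.size(); ++m) {
        const int ii = i + off[m].first, jj = j + off[m].second;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && !mask(ii, jj))
          keep = false;
      }
      out(i, j) = keep;
    }
  }
  return out;
}

// Brute-force k nearest neighbours (self excluded) for an N x 3 point set.
// Returns 1-based neighbour indices and Euclidean distances, both N x k.
// [[Rcpp::export]]
List cpp_knn(const NumericMatrix& pts, const int k) {
  const int n = pts.nrow();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < N");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  for (int i = 0; i < n; ++i) {
    cand.clear();
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi,
                   dz = pts(j, 2) - zi;
      cand.push_back(std::make_pair(dx * dx + dy * dy + dz * dz, j));
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = cand[m].second + 1;
      dist(i, m) = std::sqrt(cand[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Hybrid (line-preserving) median: median of {median of the plus-shaped
// window, median of the X-shaped window, center pixel}. Removes impulses
// like the square median but preserves one-pixel-wide bright bands, which
// the shell produces at the resolution limit.
// [[Rcpp::export]]
NumericMatrix cpp_hybrid_median_filter(const NumericMatrix& img,
                                       const int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> plus, cross, trio;
  plus.reserve(4 * radius + 1);
  cross.reserve(4 * radius + 1);
  trio.reserve(3);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      plus.clear();
      cross.clear();
      plus.push_back(img(i, j));
      cross.push_back(img(i, j));
      for (int d = 1; d <= radius; ++d) {
        if (i - d >= 0) plus.push_back(img(i - d, j));
        if (i + d < nr) plus.push_back(img(i + d, j));
        if (j - d >= 0) plus.push_back(img(i, j - d));
        if (j + d < nc) plus.push_back(img(i, j + d));
        if (i - d >= 0 && j - d >= 0) cross.push_back(img(i - d, j - d));
        if (i - d >= 0 && j + d < nc) cross.push_back(img(i - d, j + d));
        if (i + d < nr && j - d >= 0) cross.push_back(img(i + d, j - d));
        if (i + d < nr && j + d < nc) cross.push_back(img(i + d, j + d));
      }
      std::nth_element(plus.begin(), plus.begin() + plus.size() / 2,
                       plus.end());
      std::nth_element(cross.begin(), cross.begin() + cross.size() / 2,
                       cross.end());
      trio.clear();
      trio.push_back(plus[plus.size() / 2]);
      trio.push_back(cross[cross.size() / 2]);
      trio.push_back(img(i, j));
      std::nth_element(trio.begin(), trio.begin() + 1, trio.end());
      out(i, j) = trio[1];
    }
  }
  return out;
}

// Separable square-window grayscale erosion / dilation (window truncated at
// the border). Used for the white top-hat that flattens extended background
// before thresholding.
static NumericMatrix running_extreme(const NumericMatrix& img,
                                     const int radius, const bool take_min,
                                     const bool by_rows) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  if (by_rows) {
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        double v = img(i, j);
        const int lo = std::max(0, j - radius), hi = std::min(nc - 1, j + radius);
        for (int jj = lo; jj <= hi; ++jj) {
          const double x = img(i, jj);
          v = take_min ? std::min(v, x) : std::max(v, x);
        }
        out(i, j) = v;
      }
    }
  } else {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double v = img(i, j);
        const int lo = std::max(0, i - radius), hi = std::min(nr - 1, i + radius);
        for (int ii = lo; ii <= hi; ++ii) {
          const double x = img(ii, j);
          v = take_min ? std::min(v, x) : std::max(v, x);
        }
        out(i, j) = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode_sq(const NumericMatrix& img, const int radius) {
  return running_extreme(running_extreme(img, radius, true, true), radius,
                         true, false);
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate_sq(const NumericMatrix& img, const int radius) {
  return running_extreme(running_extreme(img, radius, false, true), radius,
                         false, false);
}
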