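#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-neighbour offsets, clockwise from north: P2..P9 in thinning notation.
static const int DY8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DX8[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline bool at(const std::vector<char> &m, int nr, int nc, int y, int x) {
  if (y < 0 || x < 0 || y >= nr || x >= nc) return false;
  return m[(size_t)x * nr + y] != 0;
}

// Connected-component labelling of a binary mask, 8- or 4-connectivity.
// Labels are assigned in raster (column-major) discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m((size_t)nr * nc);
  for (size_t i = 0; i < m.size(); ++i) m[i] = mask[i] == TRUE;
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 4) ? 4 : 8;
  static const int DY4[4] = {-1, 1, 0, 0};
  static const int DX4[4] = {0, 0, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      size_t i = (size_t)x * nr + y;
      if (!m[i] || lab[i] != 0) continue;
      ++next;
      lab[i] = next;
      stack.clear();
      stack.push_back((int)i);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cy = cur % nr, cx = cur / nr;
        for (int k = 0; k < nnb; ++k) {
          int ny = cy + (connectivity == 4 ? DY4[k] : DY8[k]);
          int nx = cx + (connectivity == 4 ? DX4[k] : DX8[k]);
          if (ny < 0 || nx < 0 || ny >= nr || nx >= nc) continue;
          size_t j = (size_t)nx * nr + ny;
          if (m[j] && lab[j] == 0) {
            lab[j] = next;
            stack.push_back((int)j);
          }
        }
      }
    }
  }
  return lab;
}

// Number of foreground 8-neighbours of every pixel (pixels outside the image
// count as background).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m((size_t)nr * nc);
  for (size_t i = 0; i < m.size(); ++i) m[i] = mask[i] == TRUE;
  IntegerMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      int c = 0;
      for (int k = 0; k < 8; ++k)
        if (at(m, nr, nc, y + DY8[k], x + DX8[k])) ++c;
      out[(size_t)x * nr + y] = c;
    }
  return out;
}

// Zhang-Suen thinning to a 1-px, 8-connected skeleton. Out-of-image
// neighbours are background.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m((size_t)nr * nc);
  for (size_t i = 0; i < m.size(); ++i) m[i] = mask[i] == TRUE;
  std::vector<size_t> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int x = 0; x < nc; ++x) {
        for (int y = 0; y < nr; ++y) {
          size_t i = (size_t)x * nr + y;
          if (!m[i]) continue;
          bool p[8];
          int b = 0;
          for (int k = 0; k < 8; ++k) {
            p[k] = at(m, nr, nc, y + DY8[k], x + DX8[k]);
            if (p[k]) ++b;
          }
          if (b < 2 || b > 6) continue;
          int a = 0;
          for (int k = 0; k < 8; ++k)
            if (!p[k] && p[(k + 1) % 8]) ++a;
          if (a != 1) continue;
          // p[0]=P2(N), p[2]=P4(E), p[4]=P6(S), p[6]=P8(W)
          if (pass == 0) {
            if ((p[0] && p[2] && p[4]) || (p[2] && p[4] && p[6])) continue;
          } else {
            if ((p[0] && p[2] && p[6]) || (p[0] && p[4] && p[6])) continue;
          }
          del.push_back(i);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) m[del[k]] = 0;
      }
    }
  }
  // Staircase cleanup: sequentially delete redundant pixels (exactly one
  // run of foreground neighbours, degree >= 2). Removes the 2x2 corner
  // blocks parallel thinning leaves on shallow diagonals, so endpoints and
  // junctions can be read off neighbour counts. Topology is preserved:
  // only simple (crossing number 1) non-endpoint pixels are deleted, one
  // at a time.
  changed = true;
  while (changed) {
    changed = false;
    for (int x = 0; x < nc; ++x) {
      for (int y = 0; y < nr; ++y) {
        size_t i = (size_t)x * nr + y;
        if (!m[i]) continue;
        bool p[8];
        int b = 0;
        for (int k = 0; k < 8; ++k) {
          p[k] = at(m, nr, nc, y + DY8[k], x + DX8[k]);
          if (p[k]) ++b;
        }
        if (b < 2 || b == 8) continue;
        // Count connected groups of foreground ring neighbours. Ring cells
        // are mutually adjacent when consecutive, and orthogonal cells
        // flanking a corner (N-E etc.) are adjacent even when the corner
        // between them is empty.
        int comp[8];
        for (int k = 0; k < 8; ++k) comp[k] = p[k] ? k : -1;
        bool merged = true;
        while (merged) {
          merged = false;
          for (int k = 0; k < 8; ++k) {
            if (comp[k] < 0) continue;
            int nxt = (k + 1) % 8, skp = (k + 2) % 8;
            if (comp[nxt] >= 0 && comp[nxt] != comp[k]) {
              int lo = comp[k] < comp[nxt] ? comp[k] : comp[nxt];
              int hi = comp[k] < comp[nxt] ? comp[nxt] : comp[k];
              for (int j = 0; j < 8; ++j) if (comp[j] == hi) comp[j] = lo;
              merged = true;
            }
            if (k % 2 == 0 && comp[skp] >= 0 && comp[skp] != comp[k]) {
              int lo = comp[k] < comp[skp] ? comp[k] : comp[skp];
              int hi = comp[k] < comp[skp] ? comp[skp] : comp[k];
              for (int j = 0; j < 8; ++j) if (comp[j] == hi) comp[j] = lo;
              merged = true;
            }
          }
        }
        int ncomp = 0;
        for (int k = 0; k < 8; ++k)
          if (comp[k] == k) ++ncomp;
        if (ncomp == 1) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (size_t i = 0; i < m.size(); ++i) out[i] = m[i] != 0;
  return out;
}

// Separable Gaussian blur with reflective boundary handling; kernel
// truncated at 4 sigma and renormalised, so total intensity is conserved.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  // reflect index into [0, n-1]; half-sample symmetry (edge repeated:
  // -1 -> 0), the variant under which convolution conserves total mass
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - 1 - i;
    }
    return i;
  };
  std::vector<int> ytab(nr + 2 * rad), xtab(nc + 2 * rad);
  for (int i = 0; i < nr + 2 * rad; ++i) ytab[i] = refl(i - rad, nr);
  for (int i = 0; i < nc + 2 * rad; ++i) xtab[i] = refl(i - rad, nc);
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *src = REAL(img);
  double *ptmp = REAL(tmp), *pout = REAL(out);
  for (int x = 0; x < nc; ++x) {
    const double *col = src + (size_t)x * nr;
    double *tcol = ptmp + (size_t)x * nr;
    for (int y = 0; y < nr; ++y) {
      double v = 0;
      for (int i = 0; i <= 2 * rad; ++i)
        v += k[i] * col[ytab[y + i]];
      tcol[y] = v;
    }
  }
  for (int x = 0; x < nc; ++x) {
    double *ocol = pout + (size_t)x * nr;
    for (int i = 0; i <= 2 * rad; ++i) {
      const double *tcol = ptmp + (size_t)xtab[x + i] * nr;
      double ki = k[i];
      if (i == 0) {
        for (int y = 0; y < nr; ++y) ocol[y] = ki * tcol[y];
      } else {
        for (int y = 0; y < nr; ++y) ocol[y] += ki * tcol[y];
      }
    }
  }
  return out;
}
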