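#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Texture-matrix construction kernels. All take a matrix of integer gray
// levels in 1..ng (no missing values: patches are full squares) and return
// raw count matrices; normalisation and feature formulas live in R.

// Symmetric gray-level co-occurrence counts for a single offset (dr, dc).
// Each ordered pair is counted in both directions.
// [[Rcpp::export]]
IntegerMatrix glcm_counts(const IntegerMatrix& lev, int ng, int dr, int dc) {
  int nr = lev.nrow(), nc = lev.ncol();
  IntegerMatrix out(ng, ng);
  for (int r = 0; r < nr; ++r) {
    int r2 = r + dr;
    if (r2 < 0 || r2 >= nr) continue;
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      int i = lev(r, c) - 1, j = lev(r2, c2) - 1;
      out(i, j)++;
      out(j, i)++;
    }
  }
  return out;
}

// Gray-level run-length counts along direction (dr, dc). A run is a maximal
// set of collinear pixels sharing one level. Rows index levels, columns run
// length (1 .. max possible).
// [[Rcpp::export]]
IntegerMatrix glrlm_counts(const IntegerMatrix& lev, int ng, int dr, int dc) {
  int nr = lev.nrow(), nc = lev.ncol();
  int maxlen = std::max(nr, nc);
  IntegerMatrix out(ng, maxlen);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // start of a line: predecessor out of bounds
      int rp = r - dr, cp = c - dc;
      if (rp >= 0 && rp < nr && cp >= 0 && cp < nc) continue;
      int rr = r, cc = c;
      int cur = lev(rr, cc), len = 0;
      while (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
        int v = lev(rr, cc);
        if (v == cur) {
          ++len;
        } else {
          out(cur - 1, len - 1)++;
          cur = v;
          len = 1;
        }
        rr += dr;
        cc += dc;
      }
      out(cur - 1, len - 1)++;
    }
  }
  return out;
}

// 8-connected constant-level zones. Returns a two-column matrix: zone gray
// level and zone size, one row per zone (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix glszm_zones(const IntegerMatrix& lev) {
  int nr = lev.nrow(), nc = lev.ncol();
  std::vector<char> seen(nr * nc, 0);
  std::vector<int> zlev, zsize, stack;
  stack.reserve(nr * nc);
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int idx0 = c0 * nr + r0;
      if (seen[idx0]) continue;
      int v = lev(r0, c0);
      int size = 0;
      stack.clear();
      stack.push_back(idx0);
      seen[idx0] = 1;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        ++size;
        int r = idx % nr, c = idx / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int r2 = r + dr, c2 = c + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            int idx2 = c2 * nr + r2;
            if (!seen[idx2] && lev(r2, c2) == v) {
              seen[idx2] = 1;
              stack.push_back(idx2);
            }
          }
        }
      }
      zlev.push_back(v);
      zsize.push_back(size);
    }
  }
  int nz = (int)zlev.size();
  IntegerMatrix out(nz, 2);
  for (int i = 0; i < nz; ++i) {
    out(i, 0) = zlev[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// Gray-level dependence counts. Dependence of a pixel = 1 + number of its
// 8-neighbours whose |level difference| <= alpha (the centre counts itself).
// Rows index levels, columns dependence 1..9.
// [[Rcpp::export]]
IntegerMatrix gldm_counts(const IntegerMatrix& lev, int ng, int alpha) {
  int nr = lev.nrow(), nc = lev.ncol();
  IntegerMatrix out(ng, 9);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int v = lev(r, c), dep = 1;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (std::abs(lev(r2, c2) - v) <= alpha) ++dep;
        }
      }
      out(v - 1, dep - 1)++;
    }
  }
  return out;
}

// Neighbourhood gray-tone difference accumulators: for each level i, the
// pixel count n_i and s_i = sum over pixels of |x - mean(valid 8-neighbours)|.
// Returns ng x 2 (n_i, s_i).
// [[Rcpp::export]]
NumericMatrix ngtdm_stats(const IntegerMatrix& lev, int ng) {
  int nr = lev.nrow(), nc = lev.ncol();
  NumericMatrix out(ng, 2);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int v = lev(r, c);
      double sum = 0.0;
      int n = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          sum += lev(r2, c2);
          ++n;
        }
      }
      out(v - 1, 0) += 1.0;
      if (n > 0) out(v - 1, 1) += std::fabs((double)v - sum / n);
    }
  }
  return out;
}
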