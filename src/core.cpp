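#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
// Templates start at i = 0 .. n-m-1 (0-based) for BOTH lengths, so the
// length-(m+1) extension always exists and a <= b by construction.
// Mirrored pairs (i,j) and (j,i) are both counted; self-matches excluded.
// Chebyshev distance, inclusive boundary (<= r counts as a match).
// m = 1 and m = 2 (the study grid) have unrolled inner loops.
static void sampen_counts(const double* x, int n, int m, double r,
                          double& a_out, double& b_out) {
  long long a = 0, b = 0;
  const int nt = n - m;  // number of templates
  if (m == 1) {
    for (int i = 0; i < nt; ++i) {
      const double xi0 = x[i], xi1 = x[i + 1];
      for (int j = i + 1; j < nt; ++j) {
        if (std::fabs(xi0 - x[j]) > r) continue;
        ++b;
        if (std::fabs(xi1 - x[j + 1]) <= r) ++a;
      }
    }
  } else if (m == 2) {
    for (int i = 0; i < nt; ++i) {
      const double xi0 = x[i], xi1 = x[i + 1], xi2 = x[i + 2];
      for (int j = i + 1; j < nt; ++j) {
        if (std::fabs(xi0 - x[j]) > r) continue;
        if (std::fabs(xi1 - x[j + 1]) > r) continue;
        ++b;
        if (std::fabs(xi2 - x[j + 2]) <= r) ++a;
      }
    }
  } else {
    for (int i = 0; i < nt; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        bool match = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
        }
        if (match) {
          ++b;
          if (std::fabs(x[i + m] - x[j + m]) <= r) ++a;
        }
      }
    }
  }
  a_out = 2.0 * static_cast<double>(a);
  b_out = 2.0 * static_cast<double>(b);
}

// Standardize every column to mean 0, population SD 1, in one pass each.
// Columns with zero SD are left unchanged and reported.
// [[Rcpp::export]]
LogicalVector scale_cols_core(NumericMatrix x) {
  const int n = x.nrow(), v = x.ncol();
  LogicalVector ok(v);
  for (int j = 0; j < v; ++j) {
    double* col = &x(0, j);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    const double mu = s / n;
    const double var = s2 / n - mu * mu;
    if (var > 0.0) {
      const double inv = 1.0 / std::sqrt(var);
      for (int i = 0; i < n; ++i) col[i] = (col[i] - mu) * inv;
      ok[j] = TRUE;
    } else {
      ok[j] = FALSE;
    }
  }
  return ok;
}

// [[Rcpp::export]]
List sampen_core(NumericVector x, int m, double r_abs) {
  const int n = x.size();
  double a, b;
  sampen_counts(REAL(x), n, m, r_abs, a, b);
  double se = NA_REAL;
  if (a > 0.0 && b > 0.0) se = -std::log(a / b);
  return List::create(_["se"] = se, _["a_count"] = a, _["b_count"] = b);
}

// Per-voxel MSE over a time-by-voxel matrix. Coarse-grains each column at
// each scale, then computes sample entropy with the fixed absolute
// tolerance r_abs (referenced to the original, scale-1 series).
// Returns the entropy matrix (voxels x scales) plus per-scale counts of
// voxels whose entropy is undefined (zero match counts).
// [[Rcpp::export]]
List mse_map_core(NumericMatrix ts, int m, double r_abs, IntegerVector scales) {
  const int T = ts.nrow(), V = ts.ncol(), S = scales.size();
  NumericMatrix se(V, S);
  IntegerVector n_undef(S);
  std::vector<double> buf(T);
  for (int v = 0; v < V; ++v) {
    const double* col = &ts(0, v);
    bool finite_col = true;
    for (int t = 0; t < T; ++t) {
      if (!R_finite(col[t])) { finite_col = false; break; }
    }
    for (int s = 0; s < S; ++s) {
      const int l = scales[s];
      const int nl = (l >= 1) ? T / l : 0;
      if (!finite_col || l < 1 || nl <= m + 1) { se(v, s) = NA_REAL; continue; }
      const double* series = col;
      if (l > 1) {
        for (int j = 0; j < nl; ++j) {
          double acc = 0.0;
          for (int k = 0; k < l; ++k) acc += col[j * l + k];
          buf[j] = acc / l;
        }
        series = buf.data();
      }
      double a, b;
      sampen_counts(series, nl, m, r_abs, a, b);
      if (a > 0.0 && b > 0.0) {
        se(v, s) = -std::log(a / b);
      } else {
        se(v, s) = NA_REAL;
        ++n_undef[s];
      }
    }
  }
  return List::create(_["se"] = se, _["n_undefined"] = n_undef);
}

// One-pass match counts for m = 1 and m = 2 at a single tolerance.
// Same conventions as sampen_counts; avoids a second sweep over all
// template pairs for the large-N white-noise reference.
// [[Rcpp::export]]
List sampen_m12_core(NumericVector x, double r) {
  const int n = x.size();
  const double* p = REAL(x);
  long long a1 = 0, b1 = 0, a2 = 0, b2 = 0;
  const int nt1 = n - 1;  // m = 1 templates
  const int nt2 = n - 2;  // m = 2 templates
  for (int i = 0; i < nt1; ++i) {
    for (int j = i + 1; j < nt1; ++j) {
      if (std::fabs(p[i] - p[j]) > r) continue;
      ++b1;
      if (std::fabs(p[i + 1] - p[j + 1]) > r) continue;
      ++a1;
      if (j < nt2) {
        ++b2;
        if (std::fabs(p[i + 2] - p[j + 2]) <= r) ++a2;
      }
    }
  }
  return List::create(
    _["a1"] = 2.0 * a1, _["b1"] = 2.0 * b1,
    _["a2"] = 2.0 * a2, _["b2"] = 2.0 * b2);
}

// IIR direct-form II transposed filter along each column, with supplied
// initial state (zi is scaled by the first sample by the caller).
static void lfilter_col(const std::vector<double>& b, const std::vector<double>& a,
                        const double* x, double* y, int n,
                        const std::vector<double>& zi, double x0) {
  const int nf = static_cast<int>(b.size());  // b and a padded to same length
  std::vector<double> z(nf - 1);
  for (int k = 0; k < nf - 1; ++k) z[k] = zi[k] * x0;
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = b[k + 1] * xt + z[k + 1] - a[k + 1] * yt;
    z[nf - 2] = b[nf - 1] * xt - a[nf - 1] * yt;
    y[t] = yt;
  }
}

// Zero-phase forward-backward IIR filtering of each column of x, with
// odd-symmetric edge extension of length npad and steady-state initial
// conditions zi (as computed for unit step input).
// [[Rcpp::export]]
NumericMatrix filtfilt_core(NumericVector b, NumericVector a,
                            NumericVector zi, NumericMatrix x, int npad) {
  const int T = x.nrow(), V = x.ncol();
  const int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), zz(nf - 1);
  for (int k = 0; k < b.size(); ++k) bb[k] = b[k];
  for (int k = 0; k < a.size(); ++k) aa[k] = a[k];
  for (int k = 0; k < nf - 1; ++k) zz[k] = zi[k];
  if (npad > T - 1) npad = T - 1;
  const int ne = T + 2 * npad;
  NumericMatrix out(T, V);
  std::vector<double> ext(ne), y1(ne), y2(ne);
  for (int v = 0; v < V; ++v) {
    const double* col = &x(0, v);
    // odd extension about the end points
    for (int k = 0; k < npad; ++k) ext[k] = 2.0 * col[0] - col[npad - k];
    for (int t = 0; t < T; ++t) ext[npad + t] = col[t];
    for (int k = 0; k < npad; ++k)
      ext[npad + T + k] = 2.0 * col[T - 1] - col[T - 2 - k];
    lfilter_col(bb, aa, ext.data(), y1.data(), ne, zz, ext[0]);
    std::reverse(y1.begin(), y1.end());
    lfilter_col(bb, aa, y1.data(), y2.data(), ne, zz, y1[0]);
    std::reverse(y2.begin(), y2.end());
    for (int t = 0; t < T; ++t) out(t, v) = y2[npad + t];
  }
  return out;
}

// Connected-component labeling of a 3-D logical array under
// 6-connectivity (faces only). Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_clusters_core(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (mask[idx] != TRUE || lab[idx] != 0) continue;
    ++next_label;
    stack.push_back(idx);
    lab[idx] = next_label;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int x = cur % nx;
      const int y = (cur / nx) % ny;
      const int z = cur / (static_cast<R_xlen_t>(nx) * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        const int xx = x + dx[d], yy = y + dy[d], zz2 = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz2 < 0 || zz2 >= nz)
          continue;
        const R_xlen_t nb = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz2);
        if (mask[nb] == TRUE && lab[nb] == 0) {
          lab[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
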