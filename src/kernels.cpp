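#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect an index into [0, G) (mirror without edge repetition beyond one).
static inline int refl(int i, int G) {
  if (i < 0) return -1 - i;
  if (i >= G) return 2 * G - 1 - i;
  return i;
}

// Squared patch differences between each pixel and its neighborhood
// offsets, Delta_rho(j, o) = sum_p (f[j + p] - f[j + o + p])^2 over the
// (2*patch_radius+1)^2 aligned patch pixels, reflect padding.
// Offsets enumerated dx (columns) outer, dy (rows) inner; the center
// offset column is identically zero. Computed per offset as a box filter
// of the shifted squared-difference plane (separable running sums).
// [[Rcpp::export]]
NumericMatrix patch_diff_field_cpp(NumericMatrix f, int patch_radius,
                                   int nbhd_radius) {
  const int G = f.nrow();
  const int nr = nbhd_radius, pr = patch_radius;
  const int side = 2 * nr + 1, noff = side * side;
  const int J = G * G;
  NumericMatrix D(J, noff);
  std::vector<double> E((size_t)J), S((size_t)J);

  int o = 0;
  for (int dx = -nr; dx <= nr; ++dx) {
    for (int dy = -nr; dy <= nr; ++dy, ++o) {
      if (dx == 0 && dy == 0) continue; // center: zero by definition
      // squared difference plane
      for (int col = 0; col < G; ++col) {
        int c2 = refl(col + dx, G);
        for (int row = 0; row < G; ++row) {
          int r2 = refl(row + dy, G);
          double d = f(row, col) - f(r2, c2);
          E[(size_t)col * G + row] = d * d;
        }
      }
      // vertical box sum (over rows), reflect
      for (int col = 0; col < G; ++col) {
        for (int row = 0; row < G; ++row) {
          double acc = 0.0;
          for (int d = -pr; d <= pr; ++d)
            acc += E[(size_t)col * G + refl(row + d, G)];
          S[(size_t)col * G + row] = acc;
        }
      }
      // horizontal box sum (over columns), reflect
      for (int col = 0; col < G; ++col) {
        for (int row = 0; row < G; ++row) {
          double acc = 0.0;
          for (int d = -pr; d <= pr; ++d)
            acc += S[(size_t)refl(col + d, G) * G + row];
          D((size_t)col * G + row, o) = acc;
        }
      }
    }
  }
  return D;
}

// Surrogate coefficients of the per-pixel quadratic image update.
// Median mode (local = false): penalty psi(f_j - t_{j'}), t the median
// image; a_j = sum_o W(j,o) omega(f_j - t_{j2}),
// s_j = sum_o W(j,o) omega(f_j - t_{j2}) t_{j2}.
// Local mode (local = true): pairwise penalty sum_j sum_o psi(f_j - f_{j2})
// (each unordered pair counted in both directions) majorized by De Pierro
// pair splitting; both directions deposit a half-parabola on pixel j, so
// a_j = sum_o 4 W omega(xi), s_j = sum_o 2 W omega(xi) (f_j + f_{j2}),
// with xi = f_j - f_{j2}.
// quad = true uses psi(xi) = xi^2/2, i.e. omega = 1.
// [[Rcpp::export]]
List prior_coeffs_cpp(NumericVector f, NumericVector t, NumericMatrix W,
                      IntegerVector ody, IntegerVector odx, int G,
                      double eps, bool quad, bool local) {
  const int J = G * G, noff = ody.size();
  NumericVector a(J), s(J);
  for (int o = 0; o < noff; ++o) {
    int dy = ody[o], dx = odx[o];
    for (int col = 0; col < G; ++col) {
      int c2 = refl(col + dx, G);
      for (int row = 0; row < G; ++row) {
        int r2 = refl(row + dy, G);
        int j = col * G + row, j2 = c2 * G + r2;
        double w = W(j, o);
        if (local) {
          double xi = f[j] - f[j2];
          double om = quad ? 1.0 : 1.0 / std::sqrt(xi * xi + eps);
          a[j] += 4.0 * w * om;
          s[j] += 2.0 * w * om * (f[j] + f[j2]);
        } else {
          double xi = f[j] - t[j2];
          double om = quad ? 1.0 : 1.0 / std::sqrt(xi * xi + eps);
          a[j] += w * om;
          s[j] += w * om * t[j2];
        }
      }
    }
  }
  return List::create(_["a"] = a, _["s"] = s);
}

// One Jacobi sweep of the iteratively reweighted median-image update:
// m_j <- sum_{j' in N_j} w_{j'j} omega(f_{j'} - m_j) f_{j'}
//        / sum_{j' in N_j} w_{j'j} omega(f_{j'} - m_j),
// accumulated in transposed form (source pixel j contributes to its
// neighbor m_{j2} with its own row weight W(j, o)).
// [[Rcpp::export]]
NumericVector m_sweep_cpp(NumericVector f, NumericVector m, NumericMatrix W,
                          IntegerVector ody, IntegerVector odx, int G,
                          double eps) {
  const int J = G * G, noff = ody.size();
  std::vector<double> num((size_t)J, 0.0), den((size_t)J, 0.0);
  for (int o = 0; o < noff; ++o) {
    int dy = ody[o], dx = odx[o];
    for (int col = 0; col < G; ++col) {
      int c2 = refl(col + dx, G);
      for (int row = 0; row < G; ++row) {
        int r2 = refl(row + dy, G);
        int j = col * G + row, j2 = c2 * G + r2;
        double xi = f[j] - m[j2];
        double w = W(j, o) / std::sqrt(xi * xi + eps);
        num[j2] += w * f[j];
        den[j2] += w;
      }
    }
  }
  NumericVector out(J);
  for (int j = 0; j < J; ++j) out[j] = num[j] / den[j];
  return out;
}

// Value of the penalty R for the current state:
// median mode: sum_j sum_o W(j,o) psi(f_j - t_{j2}), t = median image;
// local mode:  sum_j sum_o W(j,o) psi(f_j - f_{j2}).
// psi(xi) = sqrt(xi^2 + eps), or xi^2/2 when quad = true.
// [[Rcpp::export]]
double penalty_value_cpp(NumericVector f, NumericVector t, NumericMatrix W,
                         IntegerVector ody, IntegerVector odx, int G,
                         double eps, bool quad, bool local) {
  const int noff = ody.size();
  double acc = 0.0;
  for (int o = 0; o < noff; ++o) {
    int dy = ody[o], dx = odx[o];
    for (int col = 0; col < G; ++col) {
      int c2 = refl(col + dx, G);
      for (int row = 0; row < G; ++row) {
        int r2 = refl(row + dy, G);
        int j = col * G + row, j2 = c2 * G + r2;
        double xi = local ? (f[j] - f[j2]) : (f[j] - t[j2]);
        double p = quad ? 0.5 * xi * xi : std::sqrt(xi * xi + eps);
        acc += W(j, o) * p;
      }
    }
  }
  return acc;
}

// Separable convolution with a symmetric 1-D kernel, valid region only
// (output shrinks by 2 * floor(length(k)/2) in each dimension).
// [[Rcpp::export]]
NumericMatrix sepconv_valid_cpp(NumericMatrix img, NumericVector k) {
  const int nk = k.size(), h = nk / 2;
  const int nr = img.nrow(), nc = img.ncol();
  const int vr = nr - 2 * h, vc = nc - 2 * h;
  if (vr <= 0 || vc <= 0) stop("image smaller than kernel");
  NumericMatrix tmp(vr, nc), out(vr, vc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < vr; ++r) {
      double acc = 0.0;
      for (int d = 0; d < nk; ++d) acc += k[d] * img(r + d, c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < vc; ++c)
    for (int r = 0; r < vr; ++r) {
      double acc = 0.0;
      for (int d = 0; d < nk; ++d) acc += k[d] * tmp(r, c + d);
      out(r, c) = acc;
    }
  return out;
}

// Convert CSC slots (dgCMatrix over pixels) to CSR over sinogram rows.
// [[Rcpp::export]]
List csc_to_csr_cpp(IntegerVector p, IntegerVector i, NumericVector x,
                    int nrow, int ncol) {
  const R_xlen_t nnz = i.size();
  IntegerVector rp(nrow + 1);
  IntegerVector cj((R_xlen_t)nnz);
  NumericVector vx((R_xlen_t)nnz);
  std::vector<int> cnt((size_t)nrow, 0);
  for (R_xlen_t k = 0; k < nnz; ++k) cnt[i[k]]++;
  rp[0] = 0;
  for (int r = 0; r < nrow; ++r) rp[r + 1] = rp[r] + cnt[r];
  std::vector<int> pos((size_t)nrow);
  for (int r = 0; r < nrow; ++r) pos[r] = rp[r];
  for (int c = 0; c < ncol; ++c) {
    for (int k = p[c]; k < p[c + 1]; ++k) {
      int r = i[k], q = pos[r]++;
      cj[q] = c;
      vx[q] = x[k];
    }
  }
  return List::create(_["rp"] = rp, _["cj"] = cj, _["vx"] = vx);
}

// Fused COSEM subset pass: for every listed sinogram row, compute the
// mean projection gbar_i = <H_i, f> + r_i and immediately back-project
// g_i / gbar_i into the per-pixel accumulator basis B_j, reusing the row
// while it is cache-resident. Returns B (the complete-data accumulator
// for this subset is f * B) and a model-mismatch flag (observed counts
// on a zero-mean row).
// [[Rcpp::export]]
List cosem_subset_pass_cpp(IntegerVector rp, IntegerVector cj,
                           NumericVector vx, IntegerVector rows,
                           NumericVector g_l, NumericVector r_l,
                           NumericVector f, int J) {
  NumericVector B(J);
  bool mismatch = false;
  const int nr = rows.size();
  for (int k = 0; k < nr; ++k) {
    int row = rows[k];
    double acc = 0.0;
    for (int q = rp[row]; q < rp[row + 1]; ++q) acc += vx[q] * f[cj[q]];
    double gbar = acc + r_l[k];
    double gi = g_l[k];
    if (gi > 0) {
      if (gbar <= 1e-15) { mismatch = true; continue; }
      double y = gi / gbar;
      for (int q = rp[row]; q < rp[row + 1]; ++q) B[cj[q]] += vx[q] * y;
    }
  }
  return List::create(_["B"] = B, _["mismatch"] = mismatch);
}

// Single-precision CSR copy of the system matrix, held in C++ memory and
// handed to R as an external pointer (rebuilt lazily if the pointer does
// not survive, e.g. across serialization).
struct CSRf {
  std::vector<int> rp, cj;
  std::vector<unsigned short> cj16; // used instead of cj when ncol <= 65536
  bool small = false;
  std::vector<float> vx;
  std::vector<float> fbuf, bbuf; // per-pass working buffers
};

// [[Rcpp::export]]
SEXP build_csrf_cpp(IntegerVector p, IntegerVector i, NumericVector x,
                    int nrow, int ncol) {
  XPtr<CSRf> ptr(new CSRf(), true);
  const R_xlen_t nnz = i.size();
  ptr->small = ncol <= 65536;
  ptr->rp.assign((size_t)nrow + 1, 0);
  if (ptr->small) ptr->cj16.resize((size_t)nnz); else ptr->cj.resize((size_t)nnz);
  ptr->vx.resize((size_t)nnz);
  for (R_xlen_t k = 0; k < nnz; ++k) ptr->rp[(size_t)i[k] + 1]++;
  for (int r = 0; r < nrow; ++r) ptr->rp[(size_t)r + 1] += ptr->rp[r];
  std::vector<int> pos(ptr->rp.begin(), ptr->rp.end() - 1);
  for (int c = 0; c < ncol; ++c) {
    for (int k = p[c]; k < p[c + 1]; ++k) {
      int q = pos[(size_t)i[k]]++;
      if (ptr->small) ptr->cj16[(size_t)q] = (unsigned short)c;
      else ptr->cj[(size_t)q] = c;
      ptr->vx[(size_t)q] = (float)x[k];
    }
  }
  return ptr;
}

// [[Rcpp::export]]
bool xptr_valid_cpp(SEXP ptr) { return R_ExternalPtrAddr(ptr) != NULL; }

// Fused COSEM subset pass on the single-precision CSR (accumulation in
// double); same contract as cosem_subset_pass_cpp.
// [[Rcpp::export]]
List cosem_subset_pass_f_cpp(SEXP ptrsexp, IntegerVector rows,
                             NumericVector g_l, NumericVector r_l,
                             NumericVector f, int J) {
  XPtr<CSRf> ptr(ptrsexp);
  NumericVector B(J);
  bool mismatch = false;
  const int nr = rows.size();
  const int *rp = ptr->rp.data(), *cj = ptr->cj.data();
  const float *vx = ptr->vx.data();
  for (int k = 0; k < nr; ++k) {
    int row = rows[k];
    double acc = 0.0;
    for (int q = rp[row]; q < rp[row + 1]; ++q)
      acc += (double)vx[q] * f[cj[q]];
    double gbar = acc + r_l[k];
    double gi = g_l[k];
    if (gi > 0) {
      if (gbar <= 1e-15) { mismatch = true; continue; }
      double y = gi / gbar;
      for (int q = rp[row]; q < rp[row + 1]; ++q) B[cj[q]] += (double)vx[q] * y;
    }
  }
  return List::create(_["B"] = B, _["mismatch"] = mismatch);
}

// Stable nonnegative root of a f^2 + b f - c = 0 per pixel (a >= 0,
// c >= 0); a below threshold falls back to the EM limit c / b.
// status: 0 ok, 1 degenerate (vanishing curvature, nonpositive slope,
// positive counts).
// [[Rcpp::export]]
List quad_root_cpp(NumericVector a, NumericVector b, NumericVector csum,
                   LogicalVector active) {
  const R_xlen_t J = a.size();
  NumericVector f(J);
  int status = 0;
  for (R_xlen_t j = 0; j < J; ++j) {
    if (!active[j]) { f[j] = 0.0; continue; }
    double aj = a[j], bj = b[j], cj = csum[j];
    double athr = 1e-12 * (std::fabs(bj) > 1 ? std::fabs(bj) : 1.0);
    if (aj <= athr) {
      if (cj <= 0) { f[j] = 0.0; continue; }
      if (bj <= 0) { status = 1; f[j] = 0.0; continue; }
      f[j] = cj / bj;
    } else {
      double disc = std::sqrt(bj * bj + 4.0 * aj * cj);
      if (bj >= 0)
        f[j] = cj > 0 ? 2.0 * cj / (bj + disc) : 0.0;
      else
        f[j] = (disc - bj) / (2.0 * aj);
    }
  }
  return List::create(_["f"] = f, _["status"] = status);
}

// Single-precision pass with float image/accumulator working buffers
// (kept inside the CSR object to avoid reallocation); halves the gather
// working set. Row dot products accumulate in double.
// [[Rcpp::export]]
List cosem_subset_pass_f2_cpp(SEXP ptrsexp, IntegerVector rows,
                              NumericVector g_l, NumericVector r_l,
                              NumericVector f, int J) {
  XPtr<CSRf> ptr(ptrsexp);
  ptr->fbuf.resize((size_t)J);
  ptr->bbuf.assign((size_t)J, 0.0f);
  float *ff = ptr->fbuf.data(), *bb = ptr->bbuf.data();
  for (int j = 0; j < J; ++j) ff[j] = (float)f[j];
  bool mismatch = false;
  const int nr = rows.size();
  const int *rp = ptr->rp.data();
  const float *vx = ptr->vx.data();
  const int *cj = ptr->cj.data();
  const unsigned short *cj16 = ptr->cj16.data();
  const bool small = ptr->small;
  for (int k = 0; k < nr; ++k) {
    int row = rows[k];
    double acc = 0.0;
    if (small)
      for (int q = rp[row]; q < rp[row + 1]; ++q)
        acc += (double)vx[q] * ff[cj16[q]];
    else
      for (int q = rp[row]; q < rp[row + 1]; ++q)
        acc += (double)vx[q] * ff[cj[q]];
    double gbar = acc + r_l[k];
    double gi = g_l[k];
    if (gi > 0) {
      if (gbar <= 1e-15) { mismatch = true; continue; }
      float y = (float)(gi / gbar);
      if (small)
        for (int q = rp[row]; q < rp[row + 1]; ++q) bb[cj16[q]] += vx[q] * y;
      else
        for (int q = rp[row]; q < rp[row + 1]; ++q) bb[cj[q]] += vx[q] * y;
    }
  }
  NumericVector B(J);
  for (int j = 0; j < J; ++j) B[j] = (double)bb[j];
  return List::create(_["B"] = B, _["mismatch"] = mismatch);
}

// Exponential similarity weights from the squared patch differences,
// normalized to row sums of one, in one pass.
// [[Rcpp::export]]
NumericMatrix weights_from_diff_cpp(NumericMatrix D, double delta2) {
  const int J = D.nrow(), noff = D.ncol();
  NumericMatrix W(J, noff);
  std::vector<double> rs((size_t)J, 0.0);
  for (int o = 0; o < noff; ++o)
    for (int j = 0; j < J; ++j) {
      double w = std::exp(-D(j, o) / delta2);
      W(j, o) = w;
      rs[j] += w;
    }
  for (int o = 0; o < noff; ++o)
    for (int j = 0; j < J; ++j) W(j, o) /= rs[j];
  return W;
}

// prior_coeffs / m_sweep variants for spatially uniform weights (weight
// value passed as a scalar; avoids streaming the weight matrix).
// [[Rcpp::export]]
List prior_coeffs_u_cpp(NumericVector f, NumericVector t, double w,
                        IntegerVector ody, IntegerVector odx, int G,
                        double eps, bool quad, bool local) {
  const int J = G * G, noff = ody.size();
  NumericVector a(J), s(J);
  for (int o = 0; o < noff; ++o) {
    int dy = ody[o], dx = odx[o];
    for (int col = 0; col < G; ++col) {
      int c2 = refl(col + dx, G);
      for (int row = 0; row < G; ++row) {
        int r2 = refl(row + dy, G);
        int j = col * G + row, j2 = c2 * G + r2;
        if (local) {
          double xi = f[j] - f[j2];
          double om = quad ? 1.0 : 1.0 / std::sqrt(xi * xi + eps);
          a[j] += 4.0 * w * om;
          s[j] += 2.0 * w * om * (f[j] + f[j2]);
        } else {
          double xi = f[j] - t[j2];
          double om = quad ? 1.0 : 1.0 / std::sqrt(xi * xi + eps);
          a[j] += w * om;
          s[j] += w * om * t[j2];
        }
      }
    }
  }
  return List::create(_["a"] = a, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector m_sweep_u_cpp(NumericVector f, NumericVector m, double w,
                            IntegerVector ody, IntegerVector odx, int G,
                            double eps) {
  const int J = G * G, noff = ody.size();
  std::vector<double> num((size_t)J, 0.0), den((size_t)J, 0.0);
  for (int o = 0; o < noff; ++o) {
    int dy = ody[o], dx = odx[o];
    for (int col = 0; col < G; ++col) {
      int c2 = refl(col + dx, G);
      for (int row = 0; row < G; ++row) {
        int r2 = refl(row + dy, G);
        int j = col * G + row, j2 = c2 * G + r2;
        double xi = f[j] - m[j2];
        double ww = w / std::sqrt(xi * xi + eps);
        num[j2] += ww * f[j];
        den[j2] += ww;
      }
    }
  }
  NumericVector out(J);
  for (int j = 0; j < J; ++j) out[j] = num[j] / den[j];
  return out;
}
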