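#include <Rcpp.h>
using namespace Rcpp;

// Unit-magnitude random-phase complex draws from R's RNG stream (used by the
// spectral synthesizer; much faster than exp(2i*pi*runif(n)) at R level).
// [[Rcpp::export(name = ".random_phases_c")]]
ComplexMatrix random_phases_c(int nb, int m) {
  ComplexMatrix z(nb, m);
  GetRNGstate();
  Rcomplex* p = z.begin();
  const R_xlen_t len = (R_xlen_t)nb * m;
  for (R_xlen_t i = 0; i < len; ++i) {
    const double th = 2.0 * M_PI * unif_rand();
    p[i].r = std::cos(th);
    p[i].i = std::sin(th);
  }
  PutRNGstate();
  return z;
}

// Cascaded biquad (second-order-section) filter, direct form II transposed.
// sos: n_sections x 6 matrix, columns b0 b1 b2 a0 a1 a2 with a0 == 1.
// Filters each column of x independently, single forward pass, zero initial
// state (callers handle padding for transients).
// [[Rcpp::export(name = ".sosfilt_c")]]
NumericMatrix sosfilt_c(NumericMatrix sos, NumericMatrix x) {
  const int ns = sos.nrow();
  const int n = x.nrow();
  const int m = x.ncol();
  NumericMatrix y(n, m);
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    const double a0 = sos(s, 3);
    b0[s] = sos(s, 0) / a0;
    b1[s] = sos(s, 1) / a0;
    b2[s] = sos(s, 2) / a0;
    a1[s] = sos(s, 4) / a0;
    a2[s] = sos(s, 5) / a0;
  }
  std::copy(x.begin(), x.end(), y.begin());
  // columns are processed in blocks of four with independent filter states,
  // breaking the serial dependency chain across columns
  for (int j0 = 0; j0 < m; j0 += 4) {
    const int nb = std::min(4, m - j0);
    double* col[4];
    for (int b = 0; b < nb; ++b) col[b] = y.begin() + (R_xlen_t)(j0 + b) * n;
    for (int s = 0; s < ns; ++s) {
      const double c0 = b0[s], c1 = b1[s], c2 = b2[s];
      const double d1 = a1[s], d2 = a2[s];
      if (nb == 4) {
        double z10 = 0, z20 = 0, z11 = 0, z21 = 0,
               z12 = 0, z22 = 0, z13 = 0, z23 = 0;
        double *y0 = col[0], *y1 = col[1], *y2 = col[2], *y3 = col[3];
        for (int i = 0; i < n; ++i) {
          const double v0 = y0[i], v1 = y1[i], v2 = y2[i], v3 = y3[i];
          const double o0 = c0 * v0 + z10;
          const double o1 = c0 * v1 + z11;
          const double o2 = c0 * v2 + z12;
          const double o3 = c0 * v3 + z13;
          z10 = c1 * v0 - d1 * o0 + z20; z20 = c2 * v0 - d2 * o0;
          z11 = c1 * v1 - d1 * o1 + z21; z21 = c2 * v1 - d2 * o1;
          z12 = c1 * v2 - d1 * o2 + z22; z22 = c2 * v2 - d2 * o2;
          z13 = c1 * v3 - d1 * o3 + z23; z23 = c2 * v3 - d2 * o3;
          y0[i] = o0; y1[i] = o1; y2[i] = o2; y3[i] = o3;
        }
      } else {
        for (int b = 0; b < nb; ++b) {
          double z1 = 0.0, z2 = 0.0;
          double* yj = col[b];
          for (int i = 0; i < n; ++i) {
            const double v = yj[i];
            const double out = c0 * v + z1;
            z1 = c1 * v - d1 * out + z2;
            z2 = c2 * v - d2 * out;
            yj[i] = out;
          }
        }
      }
    }
  }
  return y;
}

#include <R_ext/BLAS.h>

// Convolution layers run on channels-first matrices: activations are
// (C x H*W*N) with columns ordered h fastest, then w, then sample. im2col
// gathers (with implicit zero padding) go into a workspace reused across
// calls, and the GEMMs run through R's BLAS. Patch rows are ordered
// (c fastest, then kh, then kw), matching the weight matrix layout
// (out_channels x C*k*k).

static std::vector<double>& workspace() {
  static std::vector<double> buf;
  return buf;
}

static void im2col_cf(const double* x, int H, int W, int C, int N, int k,
                      double* out) {
  const int p = (k - 1) / 2;
  const int K = C * k * k;
  const int run = C * k;  // one (c, kh) block: contiguous in src and dst
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (R_xlen_t)n * C * H * W;
    double* on = out + (R_xlen_t)n * H * W * K;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* dst = on + ((R_xlen_t)w * H + h) * K;
        const bool h_in = (h - p >= 0) && (h + p < H);
        for (int kw = 0; kw < k; ++kw) {
          const int ww = w + kw - p;
          double* dkw = dst + kw * run;
          if (ww < 0 || ww >= W) {
            std::fill(dkw, dkw + run, 0.0);
          } else if (h_in) {
            const double* s = xn + ((R_xlen_t)ww * H + h - p) * C;
            std::copy(s, s + run, dkw);
          } else {
            for (int kh = 0; kh < k; ++kh) {
              const int hh = h + kh - p;
              double* d = dkw + kh * C;
              if (hh < 0 || hh >= H) std::fill(d, d + C, 0.0);
              else {
                const double* s = xn + ((R_xlen_t)ww * H + hh) * C;
                std::copy(s, s + C, d);
              }
            }
          }
        }
      }
    }
  }
}

// forward: y = Wmat %*% im2col(x) + bias
// [[Rcpp::export(name = ".conv_fwd_c")]]
NumericMatrix conv_fwd_c(NumericMatrix x, int H, int W, int N, int k,
                         NumericMatrix Wmat, NumericVector bias) {
  const int C = x.nrow();
  const int cout = Wmat.nrow();
  const int K = C * k * k;
  const int M = H * W * N;
  const double one = 1.0, zero = 0.0;
  NumericMatrix y(cout, M);
  if (k == 1) {  // 1x1 convolution: plain GEMM, no gather
    F77_CALL(dgemm)("N", "N", &cout, &M, &K, &one, Wmat.begin(), &cout,
                    x.begin(), &K, &zero, y.begin(), &cout FCONE FCONE);
  } else {
    std::vector<double>& buf = workspace();
    if ((R_xlen_t)buf.size() < (R_xlen_t)K * M) buf.resize((R_xlen_t)K * M);
    im2col_cf(x.begin(), H, W, C, N, k, buf.data());
    F77_CALL(dgemm)("N", "N", &cout, &M, &K, &one, Wmat.begin(), &cout,
                    buf.data(), &K, &zero, y.begin(), &cout FCONE FCONE);
  }
  double* yp = y.begin();
  for (int j = 0; j < M; ++j)
    for (int c = 0; c < cout; ++c) yp[(R_xlen_t)j * cout + c] += bias[c];
  return y;
}

// backward: dW = dy %*% t(im2col(x)), db = rowSums(dy),
// dx = col2im(t(Wmat) %*% dy) when want_dx
// [[Rcpp::export(name = ".conv_bwd_c")]]
List conv_bwd_c(NumericMatrix x, NumericMatrix dy, int H, int W, int N, int k,
                NumericMatrix Wmat, bool want_dx) {
  const int C = x.nrow();
  const int cout = Wmat.nrow();
  const int K = C * k * k;
  const int M = H * W * N;
  const int p = (k - 1) / 2;
  NumericMatrix dW(cout, K);
  NumericVector db(cout);
  const double one = 1.0, zero = 0.0;
  if (k == 1) {
    F77_CALL(dgemm)("N", "T", &cout, &K, &M, &one, dy.begin(), &cout,
                    x.begin(), &K, &zero, dW.begin(), &cout FCONE FCONE);
  } else {
    std::vector<double>& buf = workspace();
    if ((R_xlen_t)buf.size() < (R_xlen_t)K * M) buf.resize((R_xlen_t)K * M);
    im2col_cf(x.begin(), H, W, C, N, k, buf.data());
    F77_CALL(dgemm)("N", "T", &cout, &K, &M, &one, dy.begin(), &cout,
                    buf.data(), &K, &zero, dW.begin(), &cout FCONE FCONE);
  }
  const double* dyp = dy.begin();
  for (int j = 0; j < M; ++j)
    for (int c = 0; c < cout; ++c) db[c] += dyp[(R_xlen_t)j * cout + c];
  List out = List::create(Named("dW") = dW, Named("db") = db);
  if (want_dx && k == 1) {
    NumericMatrix dx(C, M);
    F77_CALL(dgemm)("T", "N", &K, &M, &cout, &one, Wmat.begin(), &cout,
                    dy.begin(), &cout, &zero, dx.begin(), &K FCONE FCONE);
    out["dx"] = dx;
  } else if (want_dx) {
    static std::vector<double> colbuf;
    if ((R_xlen_t)colbuf.size() < (R_xlen_t)K * M)
      colbuf.resize((R_xlen_t)K * M);
    F77_CALL(dgemm)("T", "N", &K, &M, &cout, &one, Wmat.begin(), &cout,
                    dy.begin(), &cout, &zero, colbuf.data(), &K FCONE FCONE);
    NumericMatrix dx(C, M);
    double* dxp = dx.begin();
    for (int n = 0; n < N; ++n) {
      double* dxn = dxp + (R_xlen_t)n * C * H * W;
      const double* cn = colbuf.data() + (R_xlen_t)n * H * W * K;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          const double* src = cn + ((R_xlen_t)w * H + h) * K;
          for (int kw = 0; kw < k; ++kw) {
            const int ww = w + kw - p;
            if (ww < 0 || ww >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hh = h + kh - p;
              if (hh < 0 || hh >= H) continue;
              double* d = dxn + ((R_xlen_t)ww * H + hh) * C;
              const double* s = src + (kw * k + kh) * C;
              for (int c = 0; c < C; ++c) d[c] += s[c];
            }
          }
        }
      }
    }
    out["dx"] = dx;
  }
  return out;
}
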