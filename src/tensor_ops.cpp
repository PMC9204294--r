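// Minimal 3D tensor kernels for the convolutional backbone.
//
// Layout convention (matches R column-major arrays):
//   activations: dim = c(d1, d2, d3, C, N), first axis fastest
//   conv weights: dim = c(3, 3, 3, C_in, C_out)
// Convolutions are fixed at kernel 3, stride 1, zero padding 1 ("same");
// pooling is kernel 2, stride 2, ceil mode (odd extents padded on the
// high side), the convention that maps 80 -> 40 -> 20 -> 10 -> 5 -> 3.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t vox(int i, int j, int k, int d1, int d2) {
  return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * (R_xlen_t)k);
}

// Build the transposed im2col matrix (V x 27*Cin) for one sample, so
// each kernel-offset/channel pair fills one contiguous column.  Column
// index r = di + 3*dj + 9*dk + 27*c matches the flattening of a
// (3,3,3,Cin) weight block in column-major order.
static void im2col3(const double* x, int d1, int d2, int d3, int Cin,
                    arma::mat& col) {
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (R_xlen_t)c * V;
    for (int dk = 0; dk < 3; ++dk) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = di + 3 * dj + 9 * dk + 27 * c;
          double* ccol = col.colptr(r);
          const int oi = di - 1, oj = dj - 1, ok = dk - 1;
          const int i0 = std::max(0, -oi), i1 = std::min(d1, d1 - oi);
          const int j0 = std::max(0, -oj), j1 = std::min(d2, d2 - oj);
          const int k0 = std::max(0, -ok), k1 = std::min(d3, d3 - ok);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              double* dst = ccol + vox(i0, j, k, d1, d2);
              const double* src = xc + vox(i0 + oi, j + oj, k + ok, d1, d2);
              std::copy(src, src + (i1 - i0), dst);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector dims,
                                 NumericVector w, NumericVector b) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], Cin = dims[3],
            N = dims[4];
  const int Cout = b.size();
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  NumericVector y((R_xlen_t)V * Cout * N);
  y.attr("dim") = IntegerVector::create(d1, d2, d3, Cout, N);

  arma::mat W(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat col(V, 27 * Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (R_xlen_t)n * V * Cin, d1, d2, d3, Cin, col);
    arma::mat out(y.begin() + (R_xlen_t)n * V * Cout, V, Cout, false, true);
    out = col * W;
    for (int c = 0; c < Cout; ++c) out.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(NumericVector x, IntegerVector dims,
                         NumericVector w, int Cout, NumericVector gy) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], Cin = dims[3],
            N = dims[4];
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;

  NumericVector dx((R_xlen_t)V * Cin * N);
  dx.attr("dim") = dims;
  NumericVector dw(27 * (R_xlen_t)Cin * Cout);
  dw.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  NumericVector db(Cout);

  arma::mat W(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat dW(dw.begin(), 27 * Cin, Cout, false, true);
  arma::mat col(V, 27 * Cin);
  arma::mat dcol(V, 27 * Cin);

  for (int n = 0; n < N; ++n) {
    arma::mat G(gy.begin() + (R_xlen_t)n * V * Cout, V, Cout, false, true);
    im2col3(x.begin() + (R_xlen_t)n * V * Cin, d1, d2, d3, Cin, col);
    dW += col.t() * G;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(G.col(c));
    dcol = G * W.t();
    // scatter dcol back (col2im), transpose of im2col
    double* dxn = dx.begin() + (R_xlen_t)n * V * Cin;
    for (int c = 0; c < Cin; ++c) {
      double* dxc = dxn + (R_xlen_t)c * V;
      for (int dk = 0; dk < 3; ++dk) {
        for (int dj = 0; dj < 3; ++dj) {
          for (int di = 0; di < 3; ++di) {
            const int r = di + 3 * dj + 9 * dk + 27 * c;
            const double* ccol = dcol.colptr(r);
            const int oi = di - 1, oj = dj - 1, ok = dk - 1;
            const int i0 = std::max(0, -oi), i1 = std::min(d1, d1 - oi);
            const int j0 = std::max(0, -oj), j1 = std::min(d2, d2 - oj);
            const int k0 = std::max(0, -ok), k1 = std::min(d3, d3 - ok);
            for (int k = k0; k < k1; ++k) {
              for (int j = j0; j < j1; ++j) {
                const double* src = ccol + vox(i0, j, k, d1, d2);
                double* dst = dxc + vox(i0 + oi, j + oj, k + ok, d1, d2);
                for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward_cpp(NumericVector x, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3],
            N = dims[4];
  const int o1 = (d1 + 1) / 2, o2 = (d2 + 1) / 2, o3 = (d3 + 1) / 2;
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t Vo = (R_xlen_t)o1 * o2 * o3;

  NumericVector y(Vo * C * N);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  IntegerVector arg(Vo * C * N); // 1-based flat index into x

  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((R_xlen_t)n * C + c) * V;
      const R_xlen_t base = ((R_xlen_t)n * C + c) * V;
      for (int k = 0; k < o3; ++k) {
        for (int j = 0; j < o2; ++j) {
          for (int i = 0; i < o1; ++i, ++p) {
            double best = R_NegInf;
            R_xlen_t bidx = -1;
            for (int kk = 2 * k; kk < std::min(2 * k + 2, d3); ++kk)
              for (int jj = 2 * j; jj < std::min(2 * j + 2, d2); ++jj)
                for (int ii = 2 * i; ii < std::min(2 * i + 2, d1); ++ii) {
                  const R_xlen_t v = vox(ii, jj, kk, d1, d2);
                  if (xc[v] > best) { best = xc[v]; bidx = v; }
                }
            y[p] = best;
            arg[p] = (int)(base + bidx) + 1;
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward_cpp(NumericVector gy, IntegerVector argmax,
                                     IntegerVector dims) {
  R_xlen_t nin = 1;
  for (int a = 0; a < dims.size(); ++a) nin *= dims[a];
  NumericVector dx(nin);
  dx.attr("dim") = dims;
  for (R_xlen_t p = 0; p < gy.size(); ++p) dx[argmax[p] - 1] += gy[p];
  return dx;
}

// Fused per-channel batch norm + ReLU.  Returns the activation y, the
// normalized pre-scale values xhat and per-channel sd (cached for
// backward), and the advanced running statistics.
// [[Rcpp::export(name = ".bn_relu_forward")]]
List bn_relu_forward_cpp(NumericVector x, IntegerVector dims,
                         NumericVector gamma, NumericVector beta,
                         NumericVector run_mean, NumericVector run_var,
                         bool training, double momentum, double eps) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3],
            N = dims[4];
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  const double m = (double)V * N;

  NumericVector mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((R_xlen_t)n * C + c) * V;
        for (R_xlen_t v = 0; v < V; ++v) { s += xc[v]; s2 += xc[v] * xc[v]; }
      }
      mu[c] = s / m;
      var[c] = std::max(s2 / m - mu[c] * mu[c], 0.0);
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = run_mean[c]; var[c] = run_var[c]; }
  }

  NumericVector y(x.size()), xhat(training ? x.size() : 0), sd_c(C);
  y.attr("dim") = dims;
  for (int c = 0; c < C; ++c) sd_c[c] = std::sqrt(var[c] + eps);

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * V;
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      const double inv = 1.0 / sd_c[c], g = gamma[c], b = beta[c],
                   mc = mu[c];
      if (training) {
        double* hc = xhat.begin() + off;
        for (R_xlen_t v = 0; v < V; ++v) {
          const double h = (xc[v] - mc) * inv;
          hc[v] = h;
          const double val = g * h + b;
          yc[v] = val > 0 ? val : 0;
        }
      } else {
        for (R_xlen_t v = 0; v < V; ++v) {
          const double val = g * (xc[v] - mc) * inv + b;
          yc[v] = val > 0 ? val : 0;
        }
      }
    }
  }

  NumericVector nrm(C), nrv(C);
  if (training) {
    const double unb = m > 1 ? m / (m - 1) : 1;
    for (int c = 0; c < C; ++c) {
      nrm[c] = (1 - momentum) * run_mean[c] + momentum * mu[c];
      nrv[c] = (1 - momentum) * run_var[c] + momentum * var[c] * unb;
    }
  } else {
    nrm = run_mean; nrv = run_var;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sd"] = sd_c,
                      _["run_mean"] = nrm, _["run_var"] = nrv);
}

// Training-mode backward through ReLU and batch norm (batch statistics).
// [[Rcpp::export(name = ".bn_relu_backward")]]
List bn_relu_backward_cpp(NumericVector gy, NumericVector y,
                          NumericVector xhat, NumericVector sd_c,
                          NumericVector gamma, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3],
            N = dims[4];
  const R_xlen_t V = (R_xlen_t)d1 * d2 * d3;
  const double m = (double)V * N;

  NumericVector dgamma(C), dbeta(C), dx(gy.size());
  dx.attr("dim") = dims;

  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * V;
      const double* gc = gy.begin() + off;
      const double* yc = y.begin() + off;
      const double* hc = xhat.begin() + off;
      for (R_xlen_t v = 0; v < V; ++v) {
        if (yc[v] > 0) { sg += gc[v]; sgx += gc[v] * hc[v]; }
      }
    }
    dgamma[c] = sgx; dbeta[c] = sg;
    const double mg = sg / m, mgx = sgx / m, scale = gamma[c] / sd_c[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * V;
      const double* gc = gy.begin() + off;
      const double* yc = y.begin() + off;
      const double* hc = xhat.begin() + off;
      double* dc = dx.begin() + off;
      for (R_xlen_t v = 0; v < V; ++v) {
        const double g = yc[v] > 0 ? gc[v] : 0;
        dc[v] = scale * (g - mg - hc[v] * mgx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
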