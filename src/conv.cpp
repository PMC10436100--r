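// Convolution, pooling and batch-norm kernels for the dual-branch
// feature extractors.
//
// A batch tensor is an (H*W*N) x C double matrix whose rows are ordered h
// fastest, then w, then sample n, so a K-tap "same"-padded convolution
// along either axis decomposes into contiguous row ranges and every tap
// becomes a BLAS product on shifted views -- no im2col buffers and no
// per-tap temporaries. This matters because the activations (tens of MB
// per layer at batch size 64) are far larger than cache, making the
// layers memory-bound.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <malloc.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static int first_offset(const int K) { return -((K + 1) / 2 - 1); }

// valid dst range [a, b] (0-based) for Y[i] += P[i + o] on an axis of
// length L
static inline void valid_range(const int L, const int o, int& a, int& b) {
  a = std::max(0, -o);
  b = std::min(L - 1, L - 1 - o);
}

// Forward convolution along one axis with optional fused ReLU:
//   Y[i] = b + sum_k X[i + o_k (along axis)] * W_k, then max(Y, 0).
// Because rows order h fastest, the valid shifted range of every segment
// is one contiguous run of rows, so each (segment, tap) contribution is a
// single BLAS dgemm on views of X and Y (leading dimension = total rows):
// no im2col, no per-tap temporaries. Small-channel cases (the first EEG
// block reads one input channel) take a fused stencil loop instead, where
// dgemm call overhead would dominate.

static void gemm_nn(const int M, const int N, const int K,
                    const double* A, const int lda, const double* B,
                    const int ldb, const double beta, double* C,
                    const int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)("N", "N", &M, &N, &K, &one, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

static void gemm_nt(const int M, const int N, const int K,
                    const double* A, const int lda, const double* B,
                    const int ldb, const double beta, double* C,
                    const int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)("N", "T", &M, &N, &K, &one, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

static void gemm_tn(const int M, const int N, const int K,
                    const double* A, const int lda, const double* B,
                    const int ldb, const double beta, double* C,
                    const int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)("T", "N", &M, &N, &K, &one, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const int H, const int W,
                       const int N, const Rcpp::List& Wk,
                       const arma::vec& b, const bool axisH,
                       const bool relu = false) {
  const int K = Wk.size();
  const int o0 = first_offset(K);
  std::vector<mat> Wm(K);
  for (int k = 0; k < K; ++k) Wm[k] = Rcpp::as<mat>(Wk[k]);
  const int Cin = X.n_cols, Cout = b.n_elem;
  const int S = axisH ? H : W;        // length of the shifted axis
  const int T = axisH ? 1 : H;        // rows per step along that axis
  const int nseg = axisH ? W * N : N; // independent segments
  const int B = S * T;                // rows per segment
  const int R = X.n_rows;
  mat Y(R, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* y = Y.colptr(co);
    const double bias = b[co];
    for (int i = 0; i < R; ++i) y[i] = bias;
  }
  for (int k = 0; k < K; ++k) {
    const int o = o0 + k;
    int a, e;
    valid_range(S, o, a, e);
    if (e < a) continue;
    if (axisH) {
      // Many short segments (one per w, n): one full-matrix product per
      // tap ignoring segment boundaries, then undo the cross-boundary
      // contamination (|o| rows per segment) with plain loops.
      const int A = std::max(0, -o), E = R - 1 - std::max(0, o);
      gemm_nn(E - A + 1, Cout, Cin, X.colptr(0) + A + o, R,
              Wm[k].memptr(), Cin, 1.0, Y.colptr(0) + A, R);
      for (int s = 0; s < nseg; ++s) {
        const int base = s * H;
        for (int h = 0; h < H; ++h) {
          if (h >= a && h <= e) continue;          // valid dst
          const int dst = base + h;
          if (dst < A || dst > E) continue;        // untouched by the gemm
          const int src = dst + o;
          for (int co = 0; co < Cout; ++co) {
            double acc = 0.0;
            for (int ci = 0; ci < Cin; ++ci)
              acc += X(src, ci) * Wm[k](ci, co);
            Y(dst, co) -= acc;
          }
        }
      }
    } else {
      // Few long segments (one per sample): one product per segment on
      // contiguous views.
      const int len = (e - a + 1) * T;
      for (int s = 0; s < nseg; ++s) {
        const int base = s * B;
        gemm_nn(len, Cout, Cin, X.colptr(0) + base + (a + o) * T, R,
                Wm[k].memptr(), Cin, 1.0, Y.colptr(0) + base + a * T, R);
      }
    }
  }
  if (relu) {
    double* y = Y.memptr();
    const size_t n_el = (size_t)R * Cout;
    for (size_t i = 0; i < n_el; ++i) y[i] = y[i] > 0 ? y[i] : 0;
  }
  return Y;
}

// Backward of the (optionally ReLU-fused) convolution. `G` is the
// gradient w.r.t. the layer output; when the forward fused a ReLU, pass
// its output `Yout` so the mask is applied on the fly. Returns dW (per
// tap), db and dX.
// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::mat& X, const arma::mat& G, const int H,
                        const int W, const int N, const Rcpp::List& Wk,
                        const bool axisH,
                        Rcpp::Nullable<Rcpp::NumericMatrix> Yout =
                          R_NilValue) {
  const int K = Wk.size();
  const int o0 = first_offset(K);
  std::vector<mat> Wm(K);
  for (int k = 0; k < K; ++k) Wm[k] = Rcpp::as<mat>(Wk[k]);
  const int Cin = X.n_cols, Cout = G.n_cols;
  const int S = axisH ? H : W;
  const int T = axisH ? 1 : H;
  const int nseg = axisH ? W * N : N;
  const int B = S * T;
  const int R = X.n_rows;
  mat dX(R, Cin, fill::zeros);
  std::vector<mat> dW(K);
  for (int k = 0; k < K; ++k) dW[k].zeros(Cin, Cout);
  vec db(Cout, fill::zeros);
  const bool masked = Yout.isNotNull();
  // masked gradient (ReLU fused in the forward); db comes along for free
  mat Gm;
  const mat* Gp = &G;
  if (masked) {
    const double* Ym = Rcpp::NumericMatrix(Yout.get()).begin();
    Gm.set_size(R, Cout);
    for (int co = 0; co < Cout; ++co) {
      const double* g = G.colptr(co);
      const double* yo = Ym + (size_t)co * R;
      double* gs = Gm.colptr(co);
      double sb = 0.0;
      for (int i = 0; i < R; ++i) {
        gs[i] = yo[i] > 0 ? g[i] : 0.0;
        sb += gs[i];
      }
      db[co] = sb;
    }
    Gp = &Gm;
  } else {
    for (int co = 0; co < Cout; ++co) {
      const double* g = G.colptr(co);
      double sb = 0.0;
      for (int i = 0; i < R; ++i) sb += g[i];
      db[co] = sb;
    }
  }
  const mat& Gr = *Gp;
  for (int k = 0; k < K; ++k) {
    const int o = o0 + k;
    int a, e;
    valid_range(S, o, a, e);
    if (e < a) continue;
    if (axisH) {
      // full-matrix products per tap + boundary corrections (see forward)
      const int A = std::max(0, -o), E = R - 1 - std::max(0, o);
      const int len = E - A + 1;
      // dX[dst + o] += G[dst] * t(W_k)
      gemm_nt(len, Cin, Cout, Gr.colptr(0) + A, R, Wm[k].memptr(), Cin,
              1.0, dX.colptr(0) + A + o, R);
      // dW_k += t(X[dst + o]) * G[dst]
      gemm_tn(Cin, Cout, len, X.colptr(0) + A + o, R, Gr.colptr(0) + A, R,
              1.0, dW[k].memptr(), Cin);
      double* dwk = dW[k].memptr();
      for (int s = 0; s < nseg; ++s) {
        const int base = s * H;
        for (int h = 0; h < H; ++h) {
          if (h >= a && h <= e) continue;
          const int dst = base + h;
          if (dst < A || dst > E) continue;
          const int src = dst + o;
          for (int co = 0; co < Cout; ++co) {
            const double gv = Gr(dst, co);
            for (int ci = 0; ci < Cin; ++ci) {
              dX(src, ci) -= gv * Wm[k](ci, co);
              dwk[ci + (size_t)co * Cin] -= X(src, ci) * gv;
            }
          }
        }
      }
    } else {
      const int len = (e - a + 1) * T;
      for (int s = 0; s < nseg; ++s) {
        const int base = s * B;
        gemm_nt(len, Cin, Cout, Gr.colptr(0) + base + a * T, R,
                Wm[k].memptr(), Cin, 1.0,
                dX.colptr(0) + base + (a + o) * T, R);
        gemm_tn(Cin, Cout, len, X.colptr(0) + base + (a + o) * T, R,
                Gr.colptr(0) + base + a * T, R, 1.0, dW[k].memptr(), Cin);
      }
    }
  }
  Rcpp::List dWl(K);
  for (int k = 0; k < K; ++k) dWl[k] = dW[k];
  return Rcpp::List::create(Rcpp::Named("w") = dWl,
                            Rcpp::Named("b") = db,
                            Rcpp::Named("dx") = dX);
}

// Batch normalization over all rows, per column. Training mode returns
// the batch statistics used; inference applies the supplied running
// statistics. One output allocation, two read passes.
// [[Rcpp::export]]
Rcpp::List cpp_bn_fwd(const arma::mat& X, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& mean_in,
                      const arma::vec& var_in, const bool training,
                      const double eps) {
  const uword m = X.n_rows, C = X.n_cols;
  vec mu(C), va(C);
  if (training) {
    mu = mean(X, 0).t();
    for (uword c = 0; c < C; ++c) {
      const double* x = X.colptr(c);
      double s = 0.0, d;
      for (uword i = 0; i < m; ++i) { d = x[i] - mu[c]; s += d * d; }
      va[c] = s / m;
    }
  } else {
    mu = mean_in;
    va = var_in;
  }
  vec inv = 1.0 / sqrt(va + eps);
  mat Y(m, C);
  for (uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    const double a = gamma[c] * inv[c];
    const double b = beta[c] - mu[c] * a;
    for (uword i = 0; i < m; ++i) y[i] = a * x[i] + b;
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("mu") = mu,
                            Rcpp::Named("var") = va,
                            Rcpp::Named("inv") = inv);
}

// Batch-norm backward; recomputes the normalized input from the cached
// layer input instead of storing it.
// [[Rcpp::export]]
Rcpp::List cpp_bn_bwd(const arma::mat& X, const arma::mat& G,
                      const arma::vec& gamma, const arma::vec& mu,
                      const arma::vec& inv) {
  const uword m = X.n_rows, C = X.n_cols;
  vec dgamma(C), dbeta(C);
  mat dX(m, C);
  for (uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    const double* g = G.colptr(c);
    double* dx = dX.colptr(c);
    const double ic = inv[c], mc = mu[c];
    double sg = 0.0, sgx = 0.0;
    for (uword i = 0; i < m; ++i) {
      const double xh = (x[i] - mc) * ic;
      sg += g[i];
      sgx += g[i] * xh;
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    const double gm = gamma[c];
    const double c1 = sg / m, c2 = sgx / m;
    for (uword i = 0; i < m; ++i) {
      const double xh = (x[i] - mc) * ic;
      dx[i] = gm * ic * (g[i] - c1 - xh * c2);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta,
                            Rcpp::Named("dx") = dX);
}

// size-2 temporal max pool (argmax kept for the backward pass)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::mat& X, const int H, const int W,
                            const int N) {
  const int H2 = H / 2;
  const int nblk = W * N;
  mat Y(H2 * nblk, X.n_cols);
  umat takeA(H2 * nblk, X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    uword* tc = takeA.colptr(c);
    for (int blk = 0; blk < nblk; ++blk) {
      const double* xb = xc + blk * H;
      double* yb = yc + blk * H2;
      uword* tb = tc + blk * H2;
      for (int h = 0; h < H2; ++h) {
        const double a = xb[2 * h], bb = xb[2 * h + 1];
        const bool ta = a >= bb;
        yb[h] = ta ? a : bb;
        tb[h] = ta ? 1u : 0u;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = Y,
                            Rcpp::Named("take_a") = takeA);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::mat& dY, const arma::umat& takeA,
                           const int H, const int W, const int N) {
  const int H2 = H / 2;
  const int nblk = W * N;
  mat dX(H * nblk, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const double* gc = dY.colptr(c);
    const uword* tc = takeA.colptr(c);
    double* xc = dX.colptr(c);
    for (int blk = 0; blk < nblk; ++blk) {
      const double* gb = gc + blk * H2;
      const uword* tb = tc + blk * H2;
      double* xb = xc + blk * H;
      for (int h = 0; h < H2; ++h)
        xb[2 * h + (tb[h] ? 0 : 1)] = gb[h];
    }
  }
  return dX;
}

// Runtime tuning applied once at package load. Large R temporaries
// otherwise get mmap()ed and munmap()ed per allocation, re-faulting every
// page on each batch; serving them from the reusable heap removes that
// cost. If the BLAS thread pool was initialized before this package
// loaded, the environment variables set in .onLoad no longer apply, so
// the OpenBLAS entry point is resolved dynamically as a fallback.
#include <dlfcn.h>
// [[Rcpp::export]]
bool cpp_tune_runtime(const bool pin_blas_thread) {
#ifdef M_MMAP_THRESHOLD
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
  if (pin_blas_thread) {
    typedef void (*set_threads_t)(int);
    void* self = dlopen(nullptr, RTLD_NOW | RTLD_GLOBAL);
    if (self) {
      set_threads_t f = reinterpret_cast<set_threads_t>(
        dlsym(self, "openblas_set_num_threads"));
      if (f) f(1);
    }
  }
  return true;
}
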