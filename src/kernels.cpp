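// Batched attention kernels.  Conventions:
//  - a batch of B samples, each with n slots and H heads;
//  - attention tensors are cubes (n, n, B*H) with slice s = (b-1)*H + h,
//    entry (i, j) = query i, key j;
//  - per-slot states are matrices (B*n, H*dh), sample b occupying rows
//    (b-1)*n + 1 .. b*n, head h occupying columns (h-1)*dh + 1 .. h*dh;
//  - pairwise quantities are matrices (B*n^2, H), rows ordered (i, j, b)
//    with i fastest: p = b*n*n + j*n + i.
//
// Outputs are allocated as R objects and written through arma views, so no
// copy is made on return.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static Rcpp::NumericMatrix alloc_mat(int nr, int nc) {
  return Rcpp::NumericMatrix(nr, nc);
}

static Rcpp::NumericVector alloc_cube(int n1, int n2, int n3) {
  Rcpp::NumericVector v(static_cast<R_xlen_t>(n1) * n2 * n3);
  v.attr("dim") = Rcpp::IntegerVector::create(n1, n2, n3);
  return v;
}

// X*W + bias (optionally ReLU), fused.
// [[Rcpp::export]]
Rcpp::NumericMatrix dense_fwd(const arma::mat& X, const arma::mat& W,
                              const arma::vec& b, bool relu) {
  Rcpp::NumericMatrix outR = alloc_mat(X.n_rows, W.n_cols);
  mat out(outR.begin(), X.n_rows, W.n_cols, false, true);
  out = X * W;
  out.each_row() += b.t();
  if (relu) {
    double* p = out.memptr();
    const uword m = out.n_elem;
    for (uword i = 0; i < m; ++i) if (p[i] < 0) p[i] = 0;
  }
  return outR;
}

// out_{b,h} = P_{b,h} %*% V_{b,h}  (transpose = true uses P^T)
// [[Rcpp::export]]
Rcpp::NumericMatrix attn_apply(const arma::cube& P, const arma::mat& V,
                               int H, bool transpose = false) {
  const int n = P.n_rows;
  const int S = P.n_slices;
  const int B = S / H;
  const int dh = V.n_cols / H;
  Rcpp::NumericMatrix outR = alloc_mat(V.n_rows, V.n_cols);
  mat out(outR.begin(), V.n_rows, V.n_cols, false, true);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const mat& Ps = P.slice(b * H + h);
      const mat Vs = V.submat(b * n, h * dh, (b + 1) * n - 1, (h + 1) * dh - 1);
      if (transpose)
        out.submat(b * n, h * dh, (b + 1) * n - 1, (h + 1) * dh - 1) = Ps.t() * Vs;
      else
        out.submat(b * n, h * dh, (b + 1) * n - 1, (h + 1) * dh - 1) = Ps * Vs;
    }
  }
  return outR;
}

// slice (b,h) = X_{b,h} %*% Y_{b,h}^T  -> cube (n, n, B*H)
// [[Rcpp::export]]
Rcpp::NumericVector attn_outer_n(const arma::mat& X, const arma::mat& Y,
                                 int H, int n) {
  const int B = X.n_rows / n;
  const int dh = X.n_cols / H;
  Rcpp::NumericVector outR = alloc_cube(n, n, B * H);
  cube out(outR.begin(), n, n, B * H, false, true);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const mat Xs = X.submat(b * n, h * dh, (b + 1) * n - 1, (h + 1) * dh - 1);
      const mat Ys = Y.submat(b * n, h * dh, (b + 1) * n - 1, (h + 1) * dh - 1);
      out.slice(b * H + h) = Xs * Ys.t();
    }
  }
  return outR;
}

// Row-wise softmax over keys with key-validity masking (column-sweep
// order).  Invalid keys get zero weight; if a sample has no valid key every
// row is uniform over all keys; a row whose finite mass underflows falls
// back to uniform over the valid keys.
static void softmax_rows(const double* A, double* out, int n,
                         const uvec& valid) {
  std::vector<double> mx(n, -std::numeric_limits<double>::infinity());
  std::vector<double> den(n, 0.0);
  if (valid.n_elem == 0) {
    for (int k = 0; k < n * n; ++k) out[k] = 1.0 / n;
    return;
  }
  for (uword v = 0; v < valid.n_elem; ++v) {
    const double* col = A + valid[v] * n;
    for (int i = 0; i < n; ++i) if (col[i] > mx[i]) mx[i] = col[i];
  }
  std::fill(out, out + n * n, 0.0);
  for (uword v = 0; v < valid.n_elem; ++v) {
    const double* col = A + valid[v] * n;
    double* oc = out + valid[v] * n;
    for (int i = 0; i < n; ++i) {
      const double e = std::isfinite(mx[i]) ? std::exp(col[i] - mx[i]) : 0.0;
      oc[i] = e;
      den[i] += e;
    }
  }
  for (uword v = 0; v < valid.n_elem; ++v) {
    double* oc = out + valid[v] * n;
    for (int i = 0; i < n; ++i) {
      if (den[i] > 0) oc[i] /= den[i];
      else oc[i] = 1.0 / valid.n_elem;
    }
  }
}

// Masked softmax over an explicit logit cube; mask is (n, B), nonzero =
// valid key.
// [[Rcpp::export]]
Rcpp::NumericVector masked_softmax(const arma::cube& A, const arma::mat& mask,
                                   int H) {
  const int n = A.n_rows;
  const int S = A.n_slices;
  Rcpp::NumericVector outR = alloc_cube(n, n, S);
  cube out(outR.begin(), n, n, S, false, true);
  for (int s = 0; s < S; ++s) {
    const uvec valid = find(mask.col(s / H) != 0.0);
    softmax_rows(A.slice(s).memptr(), out.slice(s).memptr(), n, valid);
  }
  return outR;
}

// Backward of row-wise softmax: dA = P % (dP - rowsum(P % dP)).
// [[Rcpp::export]]
Rcpp::NumericVector softmax_bwd(const arma::cube& P, const arma::cube& dP) {
  const int n = P.n_rows;
  const int nc = P.n_cols;
  const int S = P.n_slices;
  Rcpp::NumericVector outR = alloc_cube(n, nc, S);
  cube out(outR.begin(), n, nc, S, false, true);
  std::vector<double> rs(n);
  for (int s = 0; s < S; ++s) {
    const double* Ps = P.slice(s).memptr();
    const double* dPs = dP.slice(s).memptr();
    double* os = out.slice(s).memptr();
    std::fill(rs.begin(), rs.end(), 0.0);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < n; ++i) rs[i] += Ps[j * n + i] * dPs[j * n + i];
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < n; ++i)
        os[j * n + i] = Ps[j * n + i] * (dPs[j * n + i] - rs[i]);
  }
  return outR;
}

// Fused channel construction: the three channel matrices (Np x H, padding
// pairs zeroed) plus squeezed residue descriptors z_c (n x B),
// z_c(j, b) = sum_i sum_h a_c(p(i,j,b), h).
// [[Rcpp::export]]
Rcpp::List channels_forward(const arma::mat& rbf, const arma::mat& Wr,
                            const arma::ivec& ccode, const arma::mat& Wc,
                            const arma::ivec& scode, const arma::mat& Ws,
                            const arma::ivec& pcode, const arma::mat& Wp,
                            const arma::ivec& pairvalid, int n, int B) {
  const int H = Wr.n_cols;
  const int Np = rbf.n_rows;
  Rcpp::NumericMatrix a1R = alloc_mat(Np, H), a2R = alloc_mat(Np, H),
    a3R = alloc_mat(Np, H);
  Rcpp::NumericMatrix z1R = alloc_mat(n, B), z2R = alloc_mat(n, B),
    z3R = alloc_mat(n, B);
  mat a1(a1R.begin(), Np, H, false, true);
  mat a2(a2R.begin(), Np, H, false, true);
  mat a3(a3R.begin(), Np, H, false, true);
  a1 = rbf * Wr;
  const int* cc = ccode.memptr();
  const int* sc = scode.memptr();
  const int* pc = pcode.memptr();
  const int* pvp = pairvalid.memptr();
  double* z1p = z1R.begin();
  double* z2p = z2R.begin();
  double* z3p = z3R.begin();
  for (int h = 0; h < H; ++h) {
    double* a1c = a1.colptr(h);
    double* a2c = a2.colptr(h);
    double* a3c = a3.colptr(h);
    const double* WcP = Wc.colptr(h);
    const double* WsP = Ws.colptr(h);
    const double* WpP = Wp.colptr(h);
    for (int p = 0; p < Np; ++p) {
      if (!pvp[p]) {
        a1c[p] = 0.0; a2c[p] = 0.0; a3c[p] = 0.0;
      } else {
        a2c[p] = WcP[cc[p] - 1];
        a3c[p] = WsP[sc[p] - 1] + WpP[pc[p] - 1];
        const int jb = p / n;
        z1p[jb] += a1c[p];
        z2p[jb] += a2c[p];
        z3p[jb] += a3c[p];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("a1") = a1R, Rcpp::Named("a2") = a2R,
                            Rcpp::Named("a3") = a3R, Rcpp::Named("z1") = z1R,
                            Rcpp::Named("z2") = z2R, Rcpp::Named("z3") = z3R);
}

// Fused recalibration + masked softmax: A = c1*a1 - c2*a2 + c3*a3 per
// sample, then row-wise softmax over valid keys -> cube (n, n, B*H).
// [[Rcpp::export]]
Rcpp::NumericVector recal_softmax(const arma::mat& a1, const arma::mat& a2,
                                  const arma::mat& a3, const arma::vec& c1,
                                  const arma::vec& c2, const arma::vec& c3,
                                  const arma::mat& mask, int n, int H) {
  const int B = c1.n_elem;
  Rcpp::NumericVector outR = alloc_cube(n, n, B * H);
  cube out(outR.begin(), n, n, B * H, false, true);
  std::vector<double> A(n * n);
  for (int b = 0; b < B; ++b) {
    const uvec valid = find(mask.col(b) != 0.0);
    const double g1 = c1[b], g2 = c2[b], g3 = c3[b];
    const int off = b * n * n;
    for (int h = 0; h < H; ++h) {
      const double* a1c = a1.colptr(h) + off;
      const double* a2c = a2.colptr(h) + off;
      const double* a3c = a3.colptr(h) + off;
      for (int k = 0; k < n * n; ++k)
        A[k] = g1 * a1c[k] - g2 * a2c[k] + g3 * a3c[k];
      softmax_rows(A.data(), out.slice(b * H + h).memptr(), n, valid);
    }
  }
  return outR;
}

// Backward of recal_softmax: softmax backward per slice, split into
// channel gradients (coefficient-scaled) and per-sample coefficient
// gradients dc_c = sum over (i,j,h) of dA * a_c.
// [[Rcpp::export]]
Rcpp::List recal_softmax_bwd(const arma::cube& P, const arma::cube& dP,
                             const arma::mat& a1, const arma::mat& a2,
                             const arma::mat& a3, const arma::vec& c1,
                             const arma::vec& c2, const arma::vec& c3,
                             int n, int H) {
  const int B = c1.n_elem;
  const int Np = a1.n_rows;
  Rcpp::NumericMatrix d1R = alloc_mat(Np, H), d2R = alloc_mat(Np, H),
    d3R = alloc_mat(Np, H);
  Rcpp::NumericVector dc1R(B), dc2R(B), dc3R(B);
  mat da1(d1R.begin(), Np, H, false, true);
  mat da2(d2R.begin(), Np, H, false, true);
  mat da3(d3R.begin(), Np, H, false, true);
  std::vector<double> rs(n);
  for (int b = 0; b < B; ++b) {
    const int off = b * n * n;
    const double g1 = c1[b], g2 = c2[b], g3 = c3[b];
    double s1 = 0, s2 = 0, s3 = 0;
    for (int h = 0; h < H; ++h) {
      const double* Ps = P.slice(b * H + h).memptr();
      const double* dPs = dP.slice(b * H + h).memptr();
      const double* a1c = a1.colptr(h) + off;
      const double* a2c = a2.colptr(h) + off;
      const double* a3c = a3.colptr(h) + off;
      double* d1c = da1.colptr(h) + off;
      double* d2c = da2.colptr(h) + off;
      double* d3c = da3.colptr(h) + off;
      std::fill(rs.begin(), rs.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        const double* Pc = Ps + j * n;
        const double* dPc = dPs + j * n;
        for (int i = 0; i < n; ++i) rs[i] += Pc[i] * dPc[i];
      }
      for (int j = 0; j < n; ++j) {
        const double* Pc = Ps + j * n;
        const double* dPc = dPs + j * n;
        double* d1 = d1c + j * n;
        double* d2 = d2c + j * n;
        double* d3 = d3c + j * n;
        const double* b1 = a1c + j * n;
        const double* b2 = a2c + j * n;
        const double* b3 = a3c + j * n;
        for (int i = 0; i < n; ++i) {
          const double dA = Pc[i] * (dPc[i] - rs[i]);
          d1[i] = g1 * dA;
          d2[i] = -g2 * dA;
          d3[i] = g3 * dA;
          s1 += dA * b1[i];
          s2 -= dA * b2[i];
          s3 += dA * b3[i];
        }
      }
    }
    dc1R[b] = s1; dc2R[b] = s2; dc3R[b] = s3;
  }
  return Rcpp::List::create(
    Rcpp::Named("da1") = d1R, Rcpp::Named("da2") = d2R,
    Rcpp::Named("da3") = d3R, Rcpp::Named("dc1") = dc1R,
    Rcpp::Named("dc2") = dc2R, Rcpp::Named("dc3") = dc3R);
}

// Parameter gradients of the channel maps.  dz_c (n x B) carries the
// squeeze-path gradient, spread over the first residue axis and heads;
// padding pairs contribute nothing.
// [[Rcpp::export]]
Rcpp::List channels_bwd(const arma::mat& da1, const arma::mat& da2,
                        const arma::mat& da3, const arma::mat& dz1,
                        const arma::mat& dz2, const arma::mat& dz3,
                        const arma::mat& rbf, const arma::ivec& ccode,
                        const arma::ivec& scode, const arma::ivec& pcode,
                        const arma::ivec& pairvalid, int n, int B,
                        int n_s, int n_p) {
  const int H = da1.n_cols;
  const int K = rbf.n_cols;
  const int Np = da1.n_rows;
  mat dWr(K, H, fill::zeros), dWc(2, H, fill::zeros);
  mat dWs(n_s, H, fill::zeros), dWp(n_p, H, fill::zeros);
  const int* cc = ccode.memptr();
  const int* sc = scode.memptr();
  const int* pc = pcode.memptr();
  const int* pvp = pairvalid.memptr();
  std::vector<double> g1(H);
  for (int p = 0; p < Np; ++p) {
    if (!pvp[p]) continue;
    const int jb = p / n;
    for (int h = 0; h < H; ++h) {
      g1[h] = da1(p, h) + dz1[jb];
      const double v2 = da2(p, h) + dz2[jb];
      const double v3 = da3(p, h) + dz3[jb];
      dWc(cc[p] - 1, h) += v2;
      dWs(sc[p] - 1, h) += v3;
      dWp(pc[p] - 1, h) += v3;
    }
    for (int k = 0; k < K; ++k) {
      const double r = rbf(p, k);
      if (r != 0.0) for (int h = 0; h < H; ++h) dWr(k, h) += r * g1[h];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dWr") = dWr,
                            Rcpp::Named("dWc") = dWc,
                            Rcpp::Named("dWs") = dWs,
                            Rcpp::Named("dWp") = dWp);
}
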