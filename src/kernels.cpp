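// Volumetric network kernels: 3x3x3 same-padding convolution (im2col + GEMM),
// 2x2x2 max pooling, and a brute-force kNN mean-distance used by the outlier
// filter. Feature maps are stored as (V, C, B) cubes with V = D^3 voxels in
// column-major (i fastest) order, matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Columns are laid out as c*27 + o where o enumerates the 27 offsets
// (di fastest). Weight matrices must use the same (27*Cin, Cout) layout.
static void im2col3(const mat& Xs, int D, int Cin, mat& cols) {
  const int V = D * D * D;
  cols.zeros(V, 27 * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = Xs.colptr(c);
    for (int o = 0; o < 27; ++o) {
      const int di = o % 3 - 1, dj = (o / 3) % 3 - 1, dk = o / 9 - 1;
      double* dst = cols.colptr(c * 27 + o);
      for (int k = 0; k < D; ++k) {
        const int kk = k + dk;
        if (kk < 0 || kk >= D) continue;
        for (int j = 0; j < D; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= D) continue;
          const int i0 = std::max(0, -di), i1 = std::min(D, D - di);
          const double* src = xc + (i0 + di) + D * (jj + D * kk);
          double* d = dst + i0 + D * (j + D * k);
          std::copy(src, src + (i1 - i0), d);
        }
      }
    }
  }
}

// Transpose of im2col3: scatter-add column gradients back onto the grid.
static void col2im3(const mat& cols, int D, int Cin, mat& dX) {
  const int V = D * D * D;
  dX.zeros(V, Cin);
  for (int c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    for (int o = 0; o < 27; ++o) {
      const int di = o % 3 - 1, dj = (o / 3) % 3 - 1, dk = o / 9 - 1;
      const double* src0 = cols.colptr(c * 27 + o);
      for (int k = 0; k < D; ++k) {
        const int kk = k + dk;
        if (kk < 0 || kk >= D) continue;
        for (int j = 0; j < D; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= D) continue;
          const int i0 = std::max(0, -di), i1 = std::min(D, D - di);
          const double* s = src0 + i0 + D * (j + D * k);
          double* d = xc + (i0 + di) + D * (jj + D * kk);
          for (int t = 0; t < i1 - i0; ++t) d[t] += s[t];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv3d_fwd_cpp(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, int D) {
  const int Cin = X.n_cols, B = X.n_slices, V = D * D * D, Cout = W.n_cols;
  if ((int)X.n_rows != V) Rcpp::stop("conv3d_fwd: V != D^3");
  if ((int)W.n_rows != 27 * Cin) Rcpp::stop("conv3d_fwd: weight shape mismatch");
  cube Y(V, Cout, B);
  mat cols;
  for (int s = 0; s < B; ++s) {
    im2col3(X.slice(s), D, Cin, cols);
    Y.slice(s) = cols * W;
    Y.slice(s).each_row() += b.t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bwd_cpp(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, int D, bool need_dx) {
  const int Cin = X.n_cols, B = X.n_slices, Cout = W.n_cols;
  mat dW(W.n_rows, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  cube dX(need_dx ? X.n_rows : 1, need_dx ? Cin : 1,
          need_dx ? B : 1, fill::zeros);
  mat cols, dXs;
  for (int s = 0; s < B; ++s) {
    im2col3(X.slice(s), D, Cin, cols);
    dW += cols.t() * dY.slice(s);
    db += sum(dY.slice(s), 0).t();
    if (need_dx) {
      mat dcols = dY.slice(s) * W.t();
      col2im3(dcols, D, Cin, dXs);
      dX.slice(s) = dXs;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool3d_fwd_cpp(const arma::cube& X, int D) {
  const int C = X.n_cols, B = X.n_slices, Do = D / 2, Vo = Do * Do * Do;
  if (D % 2 != 0) Rcpp::stop("maxpool3d: D must be even");
  cube Y(Vo, C, B);
  cube idx(Vo, C, B);  // 0-based argmax voxel index within the input slice
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* xc = X.slice(s).colptr(c);
      double* yc = Y.slice(s).colptr(c);
      double* ic = idx.slice(s).colptr(c);
      for (int ko = 0; ko < Do; ++ko)
        for (int jo = 0; jo < Do; ++jo)
          for (int io = 0; io < Do; ++io) {
            double best = -std::numeric_limits<double>::infinity();
            int barg = 0;
            for (int dk = 0; dk < 2; ++dk)
              for (int dj = 0; dj < 2; ++dj)
                for (int di = 0; di < 2; ++di) {
                  const int v = (2 * io + di) + D * ((2 * jo + dj) + D * (2 * ko + dk));
                  if (xc[v] > best) { best = xc[v]; barg = v; }
                }
            const int vo = io + Do * (jo + Do * ko);
            yc[vo] = best;
            ic[vo] = (double)barg;
          }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool3d_bwd_cpp(const arma::cube& idx, const arma::cube& dY, int D) {
  const int C = dY.n_cols, B = dY.n_slices, V = D * D * D, Vo = dY.n_rows;
  cube dX(V, C, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* ic = idx.slice(s).colptr(c);
      const double* dyc = dY.slice(s).colptr(c);
      double* dxc = dX.slice(s).colptr(c);
      for (int vo = 0; vo < Vo; ++vo) dxc[(int)ic[vo]] += dyc[vo];
    }
  return dX;
}

// Mean Euclidean distance from each point to its k nearest neighbours
// (self excluded). Brute force; adequate for the cloud sizes used here.
// [[Rcpp::export]]
arma::vec knn_mean_dist_cpp(const arma::mat& P, int k) {
  const int K = P.n_rows;
  if (k < 1 || k > K - 1) Rcpp::stop("knn_mean_dist: need 1 <= k <= K-1");
  vec out(K);
  std::vector<double> d(K);
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < K; ++j) {
      const double dx = P(i, 0) - P(j, 0);
      const double dy = P(i, 1) - P(j, 1);
      const double dz = P(i, 2) - P(j, 2);
      d[j] = dx * dx + dy * dy + dz * dz;
    }
    d[i] = std::numeric_limits<double>::infinity();
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    double s = 0;
    for (int t = 0; t < k; ++t) s += std::sqrt(d[t]);
    out(i) = s / k;
  }
  return out;
}
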