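#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Node-to-center combined distance matrix, the hot path of the alternating
// minimization: D[i,k] = rho * d(y_i, c_k) + xi * d(p_i, lambda_k), with d the
// squared Euclidean (metric 0), Manhattan (metric 1) or cosine (metric 2)
// distance. Cosine convention: a zero vector has cosine 0 with anything, so
// its distance is 1.

static arma::mat space_dist(const arma::mat& X, const arma::mat& C, int metric) {
  const arma::uword n = X.n_rows, k = C.n_rows;
  arma::mat D(n, k);
  if (metric == 0) {
    for (arma::uword j = 0; j < k; ++j)
      D.col(j) = arma::sum(arma::square(X.each_row() - C.row(j)), 1);
  } else if (metric == 1) {
    // column-major single pass; avoids an N x V temporary per cluster
    D.zeros();
    for (arma::uword j = 0; j < k; ++j) {
      double* d = D.colptr(j);
      for (arma::uword v = 0; v < X.n_cols; ++v) {
        const double c = C(j, v);
        const double* x = X.colptr(v);
        for (arma::uword i = 0; i < n; ++i) d[i] += std::abs(x[i] - c);
      }
    }
  } else {
    arma::vec nx = arma::sqrt(arma::sum(arma::square(X), 1));
    arma::vec nc = arma::sqrt(arma::sum(arma::square(C), 1));
    nx.replace(0.0, 1.0);  // zero rows: dot product is 0, cosine ends up 0
    nc.replace(0.0, 1.0);
    arma::mat cosm = (X * C.t());
    cosm.each_col() /= nx;
    cosm.each_row() /= nc.t();
    cosm = arma::clamp(cosm, -1.0, 1.0);
    D = 1.0 - cosm;
  }
  return D;
}

// [[Rcpp::export]]
arma::mat combined_distance_matrix_cpp(const arma::mat& Y, const arma::mat& P,
                                       const arma::mat& C, const arma::mat& L,
                                       double rho, double xi, int metric) {
  if (Y.n_rows != P.n_rows)
    Rcpp::stop("feature and network matrices disagree on the number of nodes");
  if (C.n_rows != L.n_rows)
    Rcpp::stop("feature and network centers disagree on K");
  if (Y.n_cols != C.n_cols || P.n_cols != L.n_cols)
    Rcpp::stop("center dimensions do not match the data");
  return rho * space_dist(Y, C, metric) + xi * space_dist(P, L, metric);
}
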