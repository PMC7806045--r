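// Compiled hot paths for SPD geometry: batched tangent projection and the
// Frechet-mean fixed-point iteration. Semantics mirror the R-level
// operations exactly (same vectorization ordering, same validation policy:
// eigenvalues below 1e-12 * max are an error, never clipped).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void check_spd(const vec& eval, const char* what) {
  if (eval.min() <= 1e-12 * eval.max())
    Rcpp::stop(std::string(what) +
               " is not positive definite (smallest eigenvalue " +
               std::to_string(eval.min()) + ")");
}

// inverse square root via the symmetric eigendecomposition
static mat inv_sqrt(const mat& C, const char* what) {
  vec eval; mat evec;
  eig_sym(eval, evec, symmatu(C));
  check_spd(eval, what);
  return evec * diagmat(1.0 / sqrt(eval)) * evec.t();
}

// Tangent vectors of every slice of Cs at reference Cref:
// row k = vec(logm(Cref^{-1/2} Cs_k Cref^{-1/2})) with the diagonal first,
// then the upper triangle row-major scaled by sqrt(2).
// [[Rcpp::export(name = ".tangent_features_cpp")]]
arma::mat tangent_features_cpp(const arma::cube& Cs, const arma::mat& Cref) {
  const int n = Cref.n_rows;
  const int K = Cs.n_slices;
  const int d = n * (n + 1) / 2;
  mat isq = inv_sqrt(Cref, "reference");
  mat out(K, d);
  vec ev; mat Q;
  for (int k = 0; k < K; ++k) {
    mat W = isq * Cs.slice(k) * isq;
    eig_sym(ev, Q, symmatu(0.5 * (W + W.t())));
    check_spd(ev, "whitened covariance");
    mat L = Q * diagmat(log(ev)) * Q.t();
    int c = 0;
    for (int i = 0; i < n; ++i) out(k, c++) = L(i, i);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) out(k, c++) = M_SQRT2 * L(i, j);
  }
  return out;
}

// Fixed-point Frechet mean under the affine-invariant metric, initialized
// at the arithmetic mean; stops when the Frobenius norm of the mean
// tangent drops below tol.
// [[Rcpp::export(name = ".frechet_mean_cpp")]]
Rcpp::List frechet_mean_cpp(const arma::cube& Cs, double tol, int max_iter) {
  const int n = Cs.n_rows;
  const int K = Cs.n_slices;
  mat M = mean(Cs, 2);
  double res = 0.0;
  bool converged = false;
  vec ev; mat Q;
  for (int it = 0; it < max_iter; ++it) {
    eig_sym(ev, Q, symmatu(0.5 * (M + M.t())));
    check_spd(ev, "current mean estimate");
    mat sq = Q * diagmat(sqrt(ev)) * Q.t();
    mat isq = Q * diagmat(1.0 / sqrt(ev)) * Q.t();
    mat T(n, n, fill::zeros);
    vec e2; mat Q2;
    for (int k = 0; k < K; ++k) {
      mat W = isq * Cs.slice(k) * isq;
      eig_sym(e2, Q2, symmatu(0.5 * (W + W.t())));
      check_spd(e2, "whitened input");
      T += Q2 * diagmat(log(e2)) * Q2.t();
    }
    T /= K;
    res = norm(T, "fro");
    vec e3; mat Q3;
    eig_sym(e3, Q3, symmatu(0.5 * (T + T.t())));
    M = sq * (Q3 * diagmat(exp(e3)) * Q3.t()) * sq;
    M = 0.5 * (M + M.t());
    if (res < tol) { converged = true; break; }
  }
  return Rcpp::List::create(Rcpp::Named("mean") = M,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("residual") = res);
}

// Augment every window with the filtered prototypes and return its
// Ledoit-Wolf shrunk covariance over time. `proto_rows` holds the four
// constant prototype rows (filters already applied); wins is
// channels x times x K.
// [[Rcpp::export(name = ".augmented_lw_covs_cpp")]]
arma::cube augmented_lw_covs_cpp(const arma::cube& wins,
                                 const arma::mat& proto_rows,
                                 const arma::mat& Wt, const arma::mat& Wnt) {
  const int K = wins.n_slices;
  const int nt = wins.n_cols;
  const int p = proto_rows.n_rows + Wt.n_rows + Wnt.n_rows;
  cube out(p, p, K);
  for (int k = 0; k < K; ++k) {
    mat Xa = join_cols(proto_rows,
                       join_cols(Wt * wins.slice(k), Wnt * wins.slice(k)));
    Xa.each_col() -= mean(Xa, 1);              // center over time
    mat S = Xa * Xa.t() / nt;
    double mu = trace(S) / p;
    mat D = S; D.diag() -= mu;
    double d2 = accu(D % D) / p;
    double shrink = 0.0;
    if (d2 > DBL_EPSILON) {
      vec nrm2 = sum(Xa % Xa, 0).t();          // ||x_t||^2 per time point
      double b2bar = (accu(nrm2 % nrm2) - nt * accu(S % S)) /
        (double(nt) * nt * p);
      shrink = std::min(b2bar, d2) / d2;
    }
    mat Sh = (1.0 - shrink) * S;
    Sh.diag() += shrink * mu;
    out.slice(k) = 0.5 * (Sh + Sh.t());
  }
  return out;
}
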