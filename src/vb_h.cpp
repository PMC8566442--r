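#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-voxel Gaussian posterior update for the shared spatial source matrix.
// M0   : L x L common precision part, sum_k nu_k * E[lambda_k] * E[A_k' A_k]
// C    : L x N data part, sum_k nu_k * E[lambda_k] * E[A_k]' Y_k
// Beta : L x N element-wise prior precisions from the mixture responsibilities
// Returns posterior means (L x N), marginal variances (L x N), the sum of
// the per-voxel covariance matrices (L x L) and the summed log-determinant
// of the covariances (needed for the entropy term of the free energy).
// [[Rcpp::export]]
Rcpp::List vb_update_H(const arma::mat& M0, const arma::mat& C,
                       const arma::mat& Beta) {
    const uword L = M0.n_rows, N = C.n_cols;
    mat Mu(L, N), V(L, N), S(L, L, fill::zeros);
    double logdetSum = 0.0;
    mat P(L, L), Cov(L, L);
    for (uword j = 0; j < N; ++j) {
        P = M0;
        P.diag() += Beta.col(j);
        if (!inv_sympd(Cov, P))
            Cov = pinv(P);
        S += Cov;
        double val, sign;
        log_det(val, sign, Cov);
        logdetSum += val;
        Mu.col(j) = Cov * C.col(j);
        V.col(j) = Cov.diag();
    }
    return Rcpp::List::create(Rcpp::Named("mu") = Mu,
                              Rcpp::Named("var") = V,
                              Rcpp::Named("S") = S,
                              Rcpp::Named("logdet") = logdetSum);
}
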