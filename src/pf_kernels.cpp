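// Hot path of the grid-based psychometric fits: the lambda-marginalised
// (three-parameter) posterior summaries used by the power simulations.
// For each lambda node the log-likelihood over the (alpha, beta) cell grid
// is one BLAS product; the exp/accumulate pass is fused per fit to avoid
// large temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// K1: n_fits x n_levels counts of "further"; ntot: per-level totals
// (identical across fits); A1/A0: n_levels x n_cells x n_lambda log tables;
// cell_* are cell metadata; lambda/lambda_w the quadrature nodes/weights.
// Returns an n_fits x 4 matrix: alpha, beta, lambda, boundary mass.
// [[Rcpp::export]]
NumericMatrix pf_free_lambda_kernel(const arma::mat& K1,
                                    const arma::rowvec& ntot,
                                    const arma::cube& A1,
                                    const arma::cube& A0,
                                    const arma::vec& cell_w,
                                    const arma::vec& cell_b,
                                    const arma::vec& cell_a,
                                    const arma::vec& cell_hi,
                                    const arma::vec& lambda,
                                    const arma::vec& lambda_w) {
  const arma::uword n = K1.n_rows;
  const arma::uword nc = A1.n_cols;
  const arma::uword nl = A1.n_slices;

  arma::vec wb = cell_w % cell_b;
  arma::vec wa = cell_w % cell_a;
  arma::vec whi = cell_w % cell_hi;

  arma::vec accw(n, arma::fill::zeros), accb(n, arma::fill::zeros),
    acca(n, arma::fill::zeros), acchi(n, arma::fill::zeros),
    accl(n, arma::fill::zeros);
  arma::vec mx(n);
  mx.fill(-arma::datum::inf);

  arma::mat K1t = K1.t();               // n_levels x n_fits

  for (arma::uword k = 0; k < nl; ++k) {
    arma::mat D = (A1.slice(k) - A0.slice(k)).t();   // nc x n_levels
    arma::vec c0 = A0.slice(k).t() * ntot.t();        // nc
    arma::mat Lt = D * K1t;                           // nc x n_fits
    const double lw = lambda_w(k), lk = lambda(k);
    for (arma::uword i = 0; i < n; ++i) {
      const double* Li = Lt.colptr(i);
      double m = -arma::datum::inf;
      for (arma::uword j = 0; j < nc; ++j) {
        const double v = Li[j] + c0(j);
        if (v > m) m = v;
      }
      const double mnew = (mx(i) > m) ? mx(i) : m;
      const double resc = std::exp(mx(i) - mnew);
      accw(i) *= resc; accb(i) *= resc; acca(i) *= resc;
      acchi(i) *= resc; accl(i) *= resc;
      double sw = 0.0, sb = 0.0, sa = 0.0, shi = 0.0;
      for (arma::uword j = 0; j < nc; ++j) {
        const double v = Li[j] + c0(j) - mnew;
        if (v <= -36.0) continue;  // exp(v) below double precision of the sums
        const double e = std::exp(v);
        sw += cell_w(j) * e;
        sb += wb(j) * e;
        sa += wa(j) * e;
        shi += whi(j) * e;
      }
      accw(i) += lw * sw;
      accb(i) += lw * sb;
      acca(i) += lw * sa;
      acchi(i) += lw * shi;
      accl(i) += lw * lk * sw;
      mx(i) = mnew;
    }
  }

  NumericMatrix out(n, 4);
  for (arma::uword i = 0; i < n; ++i) {
    out(i, 0) = acca(i) / accw(i);
    out(i, 1) = accb(i) / accw(i);
    out(i, 2) = accl(i) / accw(i);
    out(i, 3) = acchi(i) / accw(i);
  }
  return out;
}
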