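#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Univariate MCP thresholding rule for a unit-norm coordinate:
// argmin_b 1/2 (z - b)^2 + P_{lam,gamma}(|b|).
static inline double mcp_rule(double z, double lam, double gamma) {
  double az = std::fabs(z);
  if (az <= lam) return 0.0;
  if (az <= gamma * lam) {
    double s = (az - lam) / (1.0 - 1.0 / gamma);
    return z > 0 ? s : -s;
  }
  return z;
}

// Coordinate-descent solution path for MCP-penalized least squares.
// Columns are centered and scaled to unit L2 norm internally; coefficients
// are returned on the original scale with an unpenalized intercept.
// [[Rcpp::export]]
List cpp_mcp_path(const arma::mat& X, const arma::vec& y, double gamma,
                  const arma::vec& lambdas, double tol, int max_sweeps) {
  const int n = X.n_rows;
  const int d = X.n_cols;
  const int L = lambdas.n_elem;

  arma::rowvec xm = arma::mean(X, 0);
  arma::mat Xs = X.each_row() - xm;
  arma::vec scale(d);
  for (int j = 0; j < d; ++j) {
    double s = arma::norm(Xs.col(j));
    if (s < 1e-12) {
      scale(j) = 0.0;            // constant column: stays out of the model
      Xs.col(j).zeros();
    } else {
      scale(j) = s;
      Xs.col(j) /= s;
    }
  }
  double ym = arma::mean(y);
  arma::vec yc = y - ym;

  arma::vec b(d, arma::fill::zeros);
  arma::vec r = yc;

  arma::mat beta(d, L, arma::fill::zeros);
  arma::vec intercept(L), rss(L);
  arma::ivec df(L), converged(L);

  std::vector<char> active(d, 0);

  // one coordinate-descent sweep over the given index set; returns max change
  auto cd_sweep = [&](bool full, double lam) {
    double maxchg = 0.0;
    for (int j = 0; j < d; ++j) {
      if (scale(j) == 0.0) continue;
      if (!full && !active[j]) continue;
      double z = b(j) + arma::dot(Xs.col(j), r);
      double bn = mcp_rule(z, lam, gamma);
      double delta = bn - b(j);
      if (delta != 0.0) {
        r -= Xs.col(j) * delta;
        b(j) = bn;
        double a = std::fabs(delta);
        if (a > maxchg) maxchg = a;
      }
      active[j] = (b(j) != 0.0);
    }
    return maxchg;
  };

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas(l);
    bool ok = false;
    int sweeps = 0;
    while (sweeps < max_sweeps) {
      // converge on the current active set, then verify with a full sweep
      while (sweeps < max_sweeps) {
        ++sweeps;
        if (cd_sweep(false, lam) <= tol) break;
      }
      if (sweeps >= max_sweeps) break;
      ++sweeps;
      if (cd_sweep(true, lam) <= tol) { ok = true; break; }
    }
    converged(l) = ok ? 1 : 0;

    int nnz = 0;
    for (int j = 0; j < d; ++j) {
      if (b(j) != 0.0 && scale(j) > 0.0) {
        beta(j, l) = b(j) / scale(j);
        ++nnz;
      }
    }
    df(l) = nnz;
    double ic = ym;
    for (int j = 0; j < d; ++j) ic -= beta(j, l) * xm(j);
    intercept(l) = ic;
    rss(l) = arma::dot(r, r);
  }

  return List::create(_["beta"] = beta, _["intercept"] = intercept,
                      _["rss"] = rss, _["df"] = df,
                      _["converged"] = converged, _["n"] = n);
}
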