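#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multivariate-normal EM on an incomplete, column-standardized matrix.
// X: n x p with zeros at unobserved cells; obs: n x p 0/1 mask.
// Each E-step fills every row's missing block with its conditional mean
// given the observed block under N(mu, sigma) and accumulates the
// conditional covariance; the M-step is the 1/n maximum-likelihood update
// plus `ridge` on the diagonal. Stops when the observed-data
// log-likelihood changes by less than `tol`, or after `max_iter` steps.
// [[Rcpp::export]]
Rcpp::List em_fit_cpp(const arma::mat& X, const arma::umat& obs,
                      arma::vec mu, arma::mat sigma,
                      const double tol, const int max_iter,
                      const double ridge) {
  const uword n = X.n_rows, p = X.n_cols;
  const double log2pi = std::log(2.0 * M_PI);

  // per-row observed / missing index vectors, computed once
  std::vector<uvec> o_idx(n), m_idx(n);
  for (uword i = 0; i < n; ++i) {
    o_idx[i] = find(obs.row(i).t() == 1);
    m_idx[i] = find(obs.row(i).t() == 0);
  }

  std::vector<double> ll_trace;
  bool converged = false;
  mat Xc(n, p);
  mat Csum(p, p);

  for (int it = 0; it < max_iter; ++it) {
    Xc = X;
    Csum.zeros();
    double ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      const uvec& o = o_idx[i];
      const uvec& m = m_idx[i];
      if (o.n_elem == 0) {
        for (uword j = 0; j < m.n_elem; ++j) Xc(i, m(j)) = mu(m(j));
        Csum += sigma;
        continue;
      }
      mat ch = chol(sigma.submat(o, o), "lower");
      vec dev = X.row(i).t();
      dev = dev.elem(o) - mu.elem(o);
      vec z = solve(trimatl(ch), dev);
      ll += -0.5 * (o.n_elem * log2pi + 2.0 * sum(log(ch.diag())) +
                    dot(z, z));
      if (m.n_elem > 0) {
        mat Som = sigma.submat(o, m);
        mat B = solve(trimatu(ch.t()), solve(trimatl(ch), Som));
        rowvec xm = mu.elem(m).t() + dev.t() * B;
        for (uword j = 0; j < m.n_elem; ++j) Xc(i, m(j)) = xm(j);
        Csum.submat(m, m) += sigma.submat(m, m) - Som.t() * B;
      }
    }
    ll_trace.push_back(ll);
    if (it > 0 && std::abs(ll - ll_trace[it - 1]) < tol) {
      converged = true;
      break;
    }
    mu = mean(Xc, 0).t();
    mat devc = Xc.each_row() - mu.t();
    sigma = (devc.t() * devc + Csum) / double(n);
    sigma.diag() += ridge;
  }

  return Rcpp::List::create(Rcpp::Named("mu") = mu,
                            Rcpp::Named("sigma") = sigma,
                            Rcpp::Named("loglik") = ll_trace,
                            Rcpp::Named("converged") = converged);
}
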