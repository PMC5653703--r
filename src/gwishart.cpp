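// G-Wishart sampling and Gaussian graphical model structure MCMC.
//
// All randomness is drawn through R's RNG (unif_rand / norm_rand / R::rchisq)
// so set.seed() on the R side makes every draw reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Wishart draw K ~ W_d(nu, V) by Bartlett decomposition.
// cholV_lower is the lower Cholesky factor of the scale V (E[K] = nu * V).
static arma::mat rwish_bartlett(double nu, const arma::mat &cholV_lower) {
  const arma::uword d = cholV_lower.n_rows;
  arma::mat A(d, d, arma::fill::zeros);
  for (arma::uword i = 0; i < d; ++i)
    A(i, i) = std::sqrt(R::rchisq(nu - static_cast<double>(i)));
  for (arma::uword i = 1; i < d; ++i)
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  arma::mat L = cholV_lower * A;
  return L * L.t();
}

// Direct G-Wishart sampler: draw from the unconstrained Wishart that the
// density reduces to on the complete graph, then complete the covariance so
// that the implied precision vanishes off the graph (iterating weighted
// regressions per node until the column updates stabilise).
// Target density: p(K) propto |K|^((delta-2)/2) exp(-tr(D K)/2) on M+(G).
static arma::mat rgwish_impl(const arma::umat &G, double delta,
                             const arma::mat &cholDinv_lower, double tol,
                             int max_sweeps, bool &converged) {
  const arma::uword d = G.n_rows;
  arma::mat K = rwish_bartlett(delta + static_cast<double>(d) - 1.0,
                               cholDinv_lower);
  arma::mat Sigma = arma::inv_sympd(K);
  arma::mat W = Sigma;

  std::vector<arma::uvec> nbrs(d);
  bool complete = true;
  for (arma::uword j = 0; j < d; ++j) {
    nbrs[j] = arma::find(G.col(j));
    if (nbrs[j].n_elem < d - 1) complete = false;
  }
  if (complete) {  // completion is the identity on the complete graph
    converged = true;
    return K;
  }

  converged = false;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxdiff = 0.0;
    for (arma::uword j = 0; j < d; ++j) {
      const arma::uvec &nb = nbrs[j];
      arma::vec newcol(d, arma::fill::zeros);
      if (nb.n_elem > 0) {
        arma::vec sj = Sigma.col(j);
        arma::vec beta = arma::solve(W.submat(nb, nb), sj.elem(nb),
                                     arma::solve_opts::likely_sympd);
        newcol = W.cols(nb) * beta;
      }
      for (arma::uword i = 0; i < d; ++i) {
        if (i == j) continue;
        double diff = std::abs(newcol(i) - W(i, j));
        if (diff > maxdiff) maxdiff = diff;
        W(i, j) = newcol(i);
        W(j, i) = newcol(i);
      }
    }
    if (maxdiff < tol) {
      converged = true;
      break;
    }
  }

  arma::mat Kout = arma::inv_sympd(W);
  for (arma::uword j = 1; j < d; ++j)
    for (arma::uword i = 0; i < j; ++i)
      if (G(i, j) == 0) {
        Kout(i, j) = 0.0;
        Kout(j, i) = 0.0;
      }
  return Kout;
}

// Log of the conditional Bayes factor integral for edge (i, j), freeing
// (K_ij, K_jj) and conditioning on every other element of K.  With
// A = (K_{-j,-j}^{-1})_{ii} and B the cross-term from the fixed entries of
// column j, integrating the G-Wishart kernel with parameters (.., Dt) over
// K_ij (Gaussian) relative to the point K_ij = 0 gives
//   sqrt(2*pi / (Dt_jj * A)) * exp((Dt_ij + Dt_jj * B)^2 / (2 * Dt_jj * A)).
// The shared Gamma integral over the Schur complement cancels.
static double log_cond_bf(const arma::mat &K, arma::uword i, arma::uword j,
                          const arma::mat &Dt) {
  const arma::uword d = K.n_rows;
  arma::uvec keep(d - 1);
  arma::uword c = 0;
  for (arma::uword l = 0; l < d; ++l)
    if (l != j) keep(c++) = l;
  arma::mat K11inv = arma::inv_sympd(K.submat(keep, keep));
  arma::uword ipos = (i < j) ? i : i - 1;
  double A = K11inv(ipos, ipos);
  arma::vec k1 = K.col(j);
  k1 = k1.elem(keep);
  double B = arma::dot(K11inv.row(ipos), k1) - A * k1(ipos);
  double Djj = Dt(j, j), Dij = Dt(i, j);
  double lin = Dij + Djj * B;
  return 0.5 * std::log(2.0 * M_PI / (Djj * A)) +
         lin * lin / (2.0 * Djj * A);
}

// [[Rcpp::export]]
arma::mat rgwish_cpp(const arma::umat &G, double delta, const arma::mat &D,
                     double tol, int max_sweeps) {
  bool conv = false;
  arma::mat cholDinv = arma::chol(arma::inv_sympd(D), "lower");
  arma::mat K = rgwish_impl(G, delta, cholDinv, tol, max_sweeps, conv);
  if (!conv)
    stop("G-Wishart completion did not reach tolerance %g within %d sweeps",
         tol, max_sweeps);
  return K;
}

// Structure-learning MCMC over (G, K).  Each iteration proposes toggling one
// uniformly chosen edge, accepting via the conditional Bayes factor under the
// posterior combined with an exchange-style auxiliary draw from the proposed
// graph's prior (which stands in for the intractable ratio of G-Wishart
// normalising constants), then resamples K | G, data from WG(delta+n, D+S).
// [[Rcpp::export]]
List ggm_mcmc_cpp(const arma::mat &S, int n, const arma::umat &G_init,
                  double delta, const arma::mat &Dprior, double edge_prior,
                  int n_iter, int burn_in, int thinning, double ips_tol,
                  int ips_max) {
  const arma::uword d = S.n_rows;
  const arma::uword m = d * (d - 1) / 2;
  arma::mat Dstar = Dprior + S;
  double dstar = delta + static_cast<double>(n);
  arma::mat cholDinv = arma::chol(arma::inv_sympd(Dprior), "lower");
  arma::mat cholDstarinv = arma::chol(arma::inv_sympd(Dstar), "lower");

  std::vector<std::pair<arma::uword, arma::uword> > pairs;
  pairs.reserve(m);
  for (arma::uword jj = 1; jj < d; ++jj)
    for (arma::uword ii = 0; ii < jj; ++ii)
      pairs.push_back(std::make_pair(ii, jj));

  arma::umat G = G_init;
  bool conv = false;
  int nonconv = 0;
  arma::mat K = rgwish_impl(G, dstar, cholDstarinv, ips_tol, ips_max, conv);
  if (!conv) ++nonconv;

  arma::mat edge_sum(d, d, arma::fill::zeros);
  arma::mat partial_sum(d, d, arma::fill::zeros);
  arma::mat prop_count(d, d, arma::fill::zeros);
  arma::mat acc_count(d, d, arma::fill::zeros);
  std::vector<double> dens_trace;
  double log_odds_in = std::log(edge_prior / (1.0 - edge_prior));

  for (int it = 1; it <= n_iter; ++it) {
    arma::uword e = static_cast<arma::uword>(unif_rand() * m);
    if (e >= m) e = m - 1;
    arma::uword i = pairs[e].first, j = pairs[e].second;
    bool present = G(i, j) > 0;

    double logN_post = log_cond_bf(K, i, j, Dstar);
    arma::umat Gp = G;
    Gp(i, j) = Gp(j, i) = present ? 0u : 1u;
    arma::mat Ktil = rgwish_impl(Gp, delta, cholDinv, ips_tol, ips_max, conv);
    if (!conv) ++nonconv;
    double logN_pri = log_cond_bf(Ktil, i, j, Dprior);

    double logR = present ? (-log_odds_in + logN_pri - logN_post)
                          : (log_odds_in + logN_post - logN_pri);
    prop_count(i, j) += 1.0;
    if (std::log(unif_rand()) < logR) {
      G = Gp;
      acc_count(i, j) += 1.0;
    }

    K = rgwish_impl(G, dstar, cholDstarinv, ips_tol, ips_max, conv);
    if (!conv) ++nonconv;

    if (it > burn_in && ((it - burn_in) % thinning == 0)) {
      arma::uword n_edges = 0;
      for (arma::uword jj = 1; jj < d; ++jj)
        for (arma::uword ii = 0; ii < jj; ++ii)
          if (G(ii, jj) > 0) ++n_edges;
      dens_trace.push_back(static_cast<double>(n_edges) /
                           static_cast<double>(m));
      edge_sum += arma::conv_to<arma::mat>::from(G);
      arma::vec dg = K.diag();
      for (arma::uword jj = 0; jj < d; ++jj)
        for (arma::uword ii = 0; ii < d; ++ii)
          if (ii != jj)
            partial_sum(ii, jj) += -K(ii, jj) / std::sqrt(dg(ii) * dg(jj));
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  const double nret = static_cast<double>(dens_trace.size());
  arma::mat edge_prob = edge_sum / std::max(nret, 1.0);
  arma::mat partials = partial_sum / std::max(nret, 1.0);
  partials.diag().ones();

  return List::create(
      _["edge_probability"] = edge_prob, _["expected_partials"] = partials,
      _["density_trace"] = dens_trace, _["proposal_count"] = prop_count,
      _["accept_count"] = acc_count,
      _["n_retained"] = static_cast<int>(dens_trace.size()),
      _["n_ips_nonconverged"] = nonconv,
      _["final_graph"] = arma::conv_to<arma::imat>::from(G));
}
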