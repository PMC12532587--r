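// Numerical core: REML objective/gradient for the unstructured-covariance
// repeated-measures model, and the multivariate-normal data-augmentation
// chain used by the MCMC multiple imputation. Subject contributions are
// pre-aggregated by missingness pattern in R (sufficient statistics
// S_ab = sum_i x_ia x_ib', etc.), so each objective evaluation is
// independent of the number of subjects.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log-Cholesky: first d log-diagonal entries, then column-major strictly
// lower-triangular entries of L; Sigma = L L'
static arma::mat theta_to_chol(const arma::vec& theta, int d) {
  arma::mat L(d, d, arma::fill::zeros);
  int idx = 0;
  for (int j = 0; j < d; ++j) L(j, j) = std::exp(theta(idx++));
  for (int j = 0; j < d; ++j)
    for (int i = j + 1; i < d; ++i) L(i, j) = theta(idx++);
  return L;
}

struct PatStats {
  arma::uvec J;     // 0-based visit indices
  double n;         // subjects in pattern
  arma::mat Sxx;    // q^2 x k^2, column (a,b) = vec(sum_i x_ia x_ib')
  arma::mat Sxy;    // q x k^2,   column (a,b) = sum_i x_ia y_ib
  arma::vec Syy;    // k^2,       entry (a,b)  = sum_i y_ia y_ib
};

static std::vector<PatStats> unpack_stats(const List& stats) {
  std::vector<PatStats> out;
  out.reserve(stats.size());
  for (int p = 0; p < stats.size(); ++p) {
    List s = stats[p];
    PatStats ps;
    ps.J = as<arma::uvec>(s["J"]) - 1;
    ps.n = as<double>(s["n"]);
    ps.Sxx = as<arma::mat>(s["Sxx"]);
    ps.Sxy = as<arma::mat>(s["Sxy"]);
    ps.Syy = as<arma::vec>(s["Syy"]);
    out.push_back(ps);
  }
  return out;
}

// core assembly shared by value, components and gradient
static bool assemble(const arma::vec& theta, const std::vector<PatStats>& st,
                     int q, int d,
                     std::vector<arma::mat>& Wp, double& logdet_sum,
                     arma::mat& XtWX, arma::vec& XtWy, double& yWy) {
  arma::mat L = theta_to_chol(theta, d);
  arma::mat Sigma = L * L.t();
  XtWX.zeros(q, q);
  XtWy.zeros(q);
  yWy = 0.0;
  logdet_sum = 0.0;
  Wp.clear();
  for (size_t p = 0; p < st.size(); ++p) {
    arma::mat SigJ = Sigma(st[p].J, st[p].J);
    arma::mat ch;
    if (!arma::chol(ch, SigJ)) return false;
    // invert through the Cholesky factor already computed (never throws)
    arma::mat Rinv;
    if (!arma::inv(Rinv, arma::trimatu(ch))) return false;
    arma::mat W = Rinv * Rinv.t();
    Wp.push_back(W);
    logdet_sum += st[p].n * 2.0 * arma::accu(arma::log(ch.diag()));
    arma::vec w = arma::vectorise(W);
    XtWX += arma::reshape(st[p].Sxx * w, q, q);
    XtWy += st[p].Sxy * w;
    yWy += arma::dot(st[p].Syy, w);
  }
  XtWX = 0.5 * (XtWX + XtWX.t());
  return XtWX.is_finite() && std::isfinite(yWy);
}

// [[Rcpp::export]]
double reml_neg2ll(const arma::vec& theta, const List& stats, int q,
                   bool reml = true, int d = 4) {
  std::vector<PatStats> st = unpack_stats(stats);
  std::vector<arma::mat> Wp;
  double ld, yWy;
  arma::mat XtWX;
  arma::vec XtWy;
  if (!assemble(theta, st, q, d, Wp, ld, XtWX, XtWy, yWy)) return 1e10;
  arma::mat chx;
  if (!arma::chol(chx, XtWX)) return 1e10;
  arma::vec beta = arma::solve(arma::trimatu(chx),
                               arma::solve(arma::trimatl(chx.t()), XtWy,
                                           arma::solve_opts::fast),
                               arma::solve_opts::fast);
  double quad = yWy - arma::dot(beta, XtWy);
  double val = ld + quad;
  if (reml) val += 2.0 * arma::accu(arma::log(chx.diag()));
  if (!std::isfinite(val)) return 1e10;
  return val;
}

// analytic gradient of reml_neg2ll w.r.t. theta
// [[Rcpp::export]]
arma::vec reml_neg2ll_grad(const arma::vec& theta, const List& stats, int q,
                           bool reml = true, int d = 4) {
  std::vector<PatStats> st = unpack_stats(stats);
  std::vector<arma::mat> Wp;
  double ld, yWy;
  arma::mat XtWX;
  arma::vec XtWy;
  int npar = theta.n_elem;
  arma::vec grad(npar, arma::fill::zeros);
  if (!assemble(theta, st, q, d, Wp, ld, XtWX, XtWy, yWy)) return grad;
  arma::mat G;
  if (!arma::inv_sympd(G, XtWX)) return grad;
  arma::vec beta = G * XtWy;

  arma::mat L = theta_to_chol(theta, d);
  // dSigma/dtheta_k = dL L' + L dL'
  std::vector<arma::mat> Dk(npar);
  {
    int idx = 0;
    for (int j = 0; j < d; ++j) {
      arma::mat dL(d, d, arma::fill::zeros);
      dL(j, j) = L(j, j);  // chain rule through exp
      Dk[idx++] = dL * L.t() + L * dL.t();
    }
    for (int j = 0; j < d; ++j)
      for (int i = j + 1; i < d; ++i) {
        arma::mat dL(d, d, arma::fill::zeros);
        dL(i, j) = 1.0;
        Dk[idx++] = dL * L.t() + L * dL.t();
      }
  }

  for (size_t p = 0; p < st.size(); ++p) {
    const arma::uvec& J = st[p].J;
    int k = J.n_elem;
    const arma::mat& W = Wp[p];
    // residual cross-products R_ab = sum_i r_ia r_ib from sufficient stats
    arma::mat R(k, k);
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b) {
        int ab = a + b * k;       // column for pair (a,b)
        int ba = b + a * k;
        arma::mat Sab = arma::reshape(st[p].Sxx.col(ab), q, q);
        R(a, b) = st[p].Syy(ab)
          - arma::dot(beta, st[p].Sxy.col(ab))
          - arma::dot(beta, st[p].Sxy.col(ba))
          + arma::as_scalar(beta.t() * Sab * beta);
      }
    for (int m = 0; m < npar; ++m) {
      arma::mat DJ = Dk[m](J, J);
      arma::mat WDW = W * DJ * W;
      // d logdet term
      double g = st[p].n * arma::trace(W * DJ);
      // d quadratic term: - r' W D W r
      g -= arma::accu(WDW % R);
      if (reml) {
        // d logdet(X'WX): -tr(G * sum_i X_i' WDW X_i)
        arma::vec wv = arma::vectorise(WDW);
        arma::mat XtDX = arma::reshape(st[p].Sxx * wv, q, q);
        g -= arma::accu(G % XtDX);
      }
      grad(m) += g;
    }
  }
  return grad;
}

// [[Rcpp::export]]
List reml_components(const arma::vec& theta, const List& stats, int q,
                     bool reml = true, int d = 4) {
  std::vector<PatStats> st = unpack_stats(stats);
  std::vector<arma::mat> Wp;
  double ld, yWy;
  arma::mat XtWX;
  arma::vec XtWy;
  if (!assemble(theta, st, q, d, Wp, ld, XtWX, XtWy, yWy)) {
    return List::create(Named("ok") = false);
  }
  arma::mat G;
  if (!arma::inv_sympd(G, XtWX)) return List::create(Named("ok") = false);
  arma::vec beta = G * XtWy;
  double quad = yWy - arma::dot(beta, XtWy);
  arma::mat chx = arma::chol(XtWX);
  double val = ld + quad;
  if (reml) val += 2.0 * arma::accu(arma::log(chx.diag()));
  arma::mat L = theta_to_chol(theta, d);
  return List::create(
    Named("ok") = true,
    Named("beta") = beta,
    Named("vcov_beta") = G,
    Named("sigma") = L * L.t(),
    Named("neg2ll") = val
  );
}

// c' (X'WX)^-1 c for Satterthwaite differentiation
// [[Rcpp::export]]
double reml_cvc(const arma::vec& theta, const List& stats, int q,
                const arma::vec& cvec, int d = 4) {
  std::vector<PatStats> st = unpack_stats(stats);
  std::vector<arma::mat> Wp;
  double ld, yWy;
  arma::mat XtWX;
  arma::vec XtWy;
  if (!assemble(theta, st, q, d, Wp, ld, XtWX, XtWy, yWy)) return NA_REAL;
  arma::mat chx;
  if (!arma::chol(chx, XtWX)) return NA_REAL;
  arma::vec x = arma::solve(arma::trimatu(chx),
                            arma::solve(arma::trimatl(chx.t()), cvec,
                                        arma::solve_opts::fast),
                            arma::solve_opts::fast);
  return arma::dot(cvec, x);
}

// ---------------------------------------------------------------------------
// data augmentation for multivariate-normal regression with nonmonotone
// missing data: I-step draws missing entries from their conditional normal,
// P-step draws (B, Sigma) from the conjugate posterior under the Jeffreys
// prior |Sigma|^-(d+1)/2. Uses R's RNG so results are reproducible from
// set.seed().

static arma::mat rwishart_bartlett(int df, const arma::mat& scale_chol_lower) {
  int d = scale_chol_lower.n_rows;
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = scale_chol_lower * A;
  return LA * LA.t();
}

// [[Rcpp::export]]
arma::cube da_chain(const arma::mat& Y0, const arma::mat& X,
                    int burnin, int thin, int m) {
  int n = Y0.n_rows, d = Y0.n_cols, q = X.n_cols;
  if (n - q < d) stop("MCMC imputation needs at least %d estimation subjects "
                      "for %d covariates and %d visits; have %d",
                      q + d, q, d, n);
  arma::umat miss(n, d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) miss(i, j) = !arma::is_finite(Y0(i, j));

  // group rows by missingness pattern
  std::map<unsigned, std::vector<arma::uword> > groups;
  for (int i = 0; i < n; ++i) {
    unsigned key = 0;
    for (int j = 0; j < d; ++j) if (miss(i, j)) key |= (1u << j);
    if (key) groups[key].push_back(i);
  }

  // initialize missing entries at observed column means
  arma::mat Y = Y0;
  for (int j = 0; j < d; ++j) {
    arma::uvec obs = arma::find(miss.col(j) == 0);
    arma::vec yj = Y.col(j);
    double mu = obs.n_elem ? arma::mean(yj.elem(obs)) : 0.0;
    for (int i = 0; i < n; ++i) if (miss(i, j)) Y(i, j) = mu;
  }

  arma::mat XtXinv = arma::inv_sympd(X.t() * X);
  arma::mat A = arma::chol(XtXinv, "lower");
  arma::cube out(n, d, m);
  int total = burnin + m * thin;
  int slot = 0;

  for (int it = 1; it <= total; ++it) {
    // P-step
    arma::mat Bhat = XtXinv * (X.t() * Y);
    arma::mat Res = Y - X * Bhat;
    arma::mat S = Res.t() * Res;
    S = 0.5 * (S + S.t());
    arma::mat Sinv = arma::inv_sympd(S);
    arma::mat Ls = arma::chol(0.5 * (Sinv + Sinv.t()), "lower");
    arma::mat Wdraw = rwishart_bartlett(n - q, Ls);
    arma::mat Sigma = arma::inv_sympd(Wdraw);
    arma::mat Z(q, d);
    for (int j = 0; j < d; ++j)
      for (int i = 0; i < q; ++i) Z(i, j) = R::norm_rand();
    arma::mat B = Bhat + A * Z * arma::chol(Sigma);
    // I-step
    arma::mat Mu = X * B;
    for (std::map<unsigned, std::vector<arma::uword> >::iterator g =
           groups.begin(); g != groups.end(); ++g) {
      arma::uvec rows(g->second);
      arma::uvec patt = arma::conv_to<arma::uvec>::from(miss.row(rows(0)).t());
      arma::uvec mI = arma::find(patt == 1);
      arma::uvec oI = arma::find(patt == 0);
      int km = mI.n_elem, np = rows.n_elem;
      arma::mat Zm(np, km);
      for (int j = 0; j < km; ++j)
        for (int i = 0; i < np; ++i) Zm(i, j) = R::norm_rand();
      if (oI.n_elem == 0) {
        arma::mat Rc = arma::chol(Sigma(mI, mI));
        arma::mat draw = Mu(rows, mI) + Zm * Rc;
        for (int i = 0; i < np; ++i)
          for (int j = 0; j < km; ++j) Y(rows(i), mI(j)) = draw(i, j);
      } else {
        arma::mat Soo = Sigma(oI, oI);
        arma::mat F = arma::solve(Soo, Sigma(oI, mI),
                                  arma::solve_opts::likely_sympd);
        arma::mat condV = Sigma(mI, mI) - Sigma(mI, oI) * F;
        condV = 0.5 * (condV + condV.t());
        arma::mat Rc = arma::chol(condV);
        arma::mat Dev = Y(rows, oI) - Mu(rows, oI);
        arma::mat draw = Mu(rows, mI) + Dev * F + Zm * Rc;
        for (int i = 0; i < np; ++i)
          for (int j = 0; j < km; ++j) Y(rows(i), mI(j)) = draw(i, j);
      }
    }
    if (it > burnin && ((it - burnin) % thin == 0) && slot < m) {
      out.slice(slot++) = Y;
    }
  }
  return out;
}
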