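// Bayesian sparse linear mixed model sampler.
//
// Model (after standardization): y = X_gamma beta_gamma + u + e,
//   u ~ N(0, sigma_b^2 K), e ~ N(0, sigma_e^2 I).
// Hyperpriors: h ~ U(0,1), rho ~ U(0,1), log(pi) ~ U(log(1/L), 0),
// beta_j ~ N(0, sigma_a^2 sigma_e^2) for j in gamma, sigma_e^2 ~ 1/sigma_e^2.
// With K eigendecomposed (K = U D U') everything is evaluated in the
// rotated basis, where the marginal covariance is diagonal:
//   ytil ~ N(Xtil_gamma beta, sigma_e^2 diag(1 + lambda d_i)),
//   lambda = sigma_b^2 / sigma_e^2 = h (1 - rho) / (1 - h),
//   sigma_a^2 = h rho / ((1 - h) max(pi L, 1)).
// beta and sigma_e^2 are integrated out analytically for the
// Metropolis-within-Gibbs moves on (gamma, h, rho, log pi); per retained
// draw they are sampled back to form empirical PVE/PGE/h2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct MLCache {
  double logml;     // includes the gamma prior term
  double rss;
  double sa2;
  arma::mat R;      // chol(A), upper; empty when s == 0
  arma::vec b;      // Xg' W ytil
};

static bool log_ml(const arma::mat& Xtil, const arma::vec& ytil,
                   const arma::vec& d, const arma::uvec& gam,
                   double h, double rho, double logpi, MLCache& out) {
  const int n = ytil.n_elem;
  const int L = Xtil.n_cols;
  const int s = gam.n_elem;
  const double lambda = h * (1.0 - rho) / (1.0 - h);
  arma::vec W = 1.0 / (1.0 + lambda * d);
  const double ldetDH = arma::accu(arma::log1p(lambda * d));
  const double ytWy = arma::dot(ytil % W, ytil);
  const double pi = std::exp(logpi);

  double rss, quad_ld = 0.0;
  if (s == 0) {
    rss = ytWy;
    out.R.reset(); out.b.reset(); out.sa2 = 0.0;
  } else {
    double sa2 = h * rho / ((1.0 - h) * std::max(pi * L, 1.0));
    if (sa2 < 1e-10) sa2 = 1e-10;
    arma::mat Xg = Xtil.cols(gam);
    arma::mat A = Xg.t() * (Xg.each_col() % W);
    A.diag() += 1.0 / sa2;
    arma::mat R;
    if (!arma::chol(R, A)) return false;
    arma::vec b = Xg.t() * (W % ytil);
    arma::vec z = arma::solve(arma::trimatl(R.t()), b);
    rss = ytWy - arma::dot(z, z);
    if (rss <= 0) return false;
    quad_ld = s * std::log(sa2) + 2.0 * arma::accu(arma::log(R.diag()));
    out.R = R; out.b = b; out.sa2 = sa2;
  }
  double lprior_gam = s * logpi + (L - s) * std::log1p(-pi);
  out.logml = -0.5 * ldetDH - 0.5 * quad_ld - 0.5 * n * std::log(rss)
              + lprior_gam;
  out.rss = rss;
  return true;
}

static arma::uvec to_uvec(const std::vector<unsigned int>& v) {
  arma::uvec u(v.size());
  for (size_t i = 0; i < v.size(); ++i) u[i] = v[i];
  return u;
}

static double reflect(double x, double lo, double hi) {
  const double w = hi - lo;
  double t = (x - lo) / (2.0 * w);
  t -= std::floor(t);            // wrap into [0, 1)
  double xx = t * 2.0 * w;
  if (xx > w) xx = 2.0 * w - xx; // fold back
  return lo + xx;
}

// [[Rcpp::export(name = ".bslmm_chain")]]
List bslmm_chain(const arma::mat& X,      // n x L standardized markers
                 const arma::mat& Xtil,   // U' X
                 const arma::vec& ytil,   // U' y
                 const arma::mat& U,      // eigenvectors of K
                 const arma::vec& d,      // eigenvalues of K
                 int n_iter, int n_burnin, int thin,
                 int s_max, bool pi_fixed_zero,
                 double w_h, double w_rho, double w_pi) {
  const int n = ytil.n_elem;
  const int L = X.n_cols;
  const double logpi_lo = std::log(1.0 / L);
  const double logpi_hi = -1e-8;
  const double h_lo = 1e-4, h_hi = 1.0 - 1e-4;
  if (s_max > L) s_max = L;

  // state
  std::vector<unsigned int> gam;
  double h = 0.2, rho = 0.5;
  double logpi = std::min(std::max(std::log(5.0 / L), logpi_lo), logpi_hi);
  std::vector<bool> in_gam(L, false);

  MLCache cur;
  arma::uvec gam_u = to_uvec(gam);
  if (!log_ml(Xtil, ytil, d, gam_u, h, rho, logpi, cur))
    stop("initial likelihood evaluation failed");

  const int n_keep = (n_iter - n_burnin + thin - 1) / thin;
  arma::mat draws(n_keep, 8);  // h rho pi ngamma pve pge h2 logml
  arma::vec pip(L, arma::fill::zeros);
  int kept = 0;
  double acc_gam = 0, try_gam = 0, acc_hyp = 0, try_hyp = 0;

  auto prob_add = [&](int s) {
    if (pi_fixed_zero) return 0.0;
    if (s == 0) return 1.0;
    if (s >= s_max) return 0.0;
    return 0.4;
  };
  auto prob_rem = [&](int s) {
    if (s == 0) return 0.0;
    if (s >= s_max) return 0.8;
    return 0.4;
  };

  for (int it = 1; it <= n_iter; ++it) {
    int s = gam.size();

    // ---- gamma move ----
    if (!pi_fixed_zero) {
      try_gam += 1;
      double u = R::runif(0, 1);
      double pa = prob_add(s), pr = prob_rem(s);
      std::vector<unsigned int> prop = gam;
      double log_hastings = 0.0;
      bool valid = true;
      if (u < pa) {                       // add
        int pick = -1;
        do { pick = (int)std::floor(R::runif(0, 1) * L); }
        while (pick >= L || in_gam[pick]);
        prop.push_back(pick);
        log_hastings = std::log(prob_rem(s + 1) / (s + 1.0))
                     - std::log(pa / (L - s));
      } else if (u < pa + pr) {           // remove
        int k = (int)std::floor(R::runif(0, 1) * s);
        if (k >= s) k = s - 1;
        prop.erase(prop.begin() + k);
        log_hastings = std::log(prob_add(s - 1) / (L - (s - 1.0)))
                     - std::log(pr / (double)s);
      } else if (s > 0 && s < L) {        // swap
        int k = (int)std::floor(R::runif(0, 1) * s);
        if (k >= s) k = s - 1;
        int pick = -1;
        do { pick = (int)std::floor(R::runif(0, 1) * L); }
        while (pick >= L || in_gam[pick]);
        prop[k] = pick;
      } else valid = false;

      if (valid) {
        MLCache cand;
        arma::uvec prop_u = to_uvec(prop);
        if (log_ml(Xtil, ytil, d, prop_u, h, rho, logpi, cand)) {
          if (std::log(R::runif(0, 1)) < cand.logml - cur.logml + log_hastings) {
            if (prop.size() > gam.size()) in_gam[prop.back()] = true;
            else if (prop.size() < gam.size()) {
              // find the removed index
              std::vector<bool> mark(L, false);
              for (unsigned int j : prop) mark[j] = true;
              for (unsigned int j : gam) if (!mark[j]) in_gam[j] = false;
            } else {
              for (unsigned int j : gam) in_gam[j] = false;
              for (unsigned int j : prop) in_gam[j] = true;
            }
            gam = prop; cur = cand; acc_gam += 1;
          }
        }
      }
    }

    // ---- h and rho moves (random-walk with reflection) ----
    arma::uvec gam_now = to_uvec(gam);
    for (int which = 0; which < 2; ++which) {
      try_hyp += 1;
      double h_new = h, rho_new = rho;
      if (which == 0) h_new = reflect(h + R::runif(-w_h, w_h), h_lo, h_hi);
      else rho_new = reflect(rho + R::runif(-w_rho, w_rho), 1e-6, 1 - 1e-6);
      MLCache cand;
      if (log_ml(Xtil, ytil, d, gam_now, h_new, rho_new, logpi, cand)) {
        if (std::log(R::runif(0, 1)) < cand.logml - cur.logml) {
          h = h_new; rho = rho_new; cur = cand; acc_hyp += 1;
        }
      }
    }

    // ---- log pi move ----
    if (!pi_fixed_zero) {
      double lp_new = reflect(logpi + R::runif(-w_pi, w_pi),
                              logpi_lo, logpi_hi);
      MLCache cand;
      if (log_ml(Xtil, ytil, d, gam_now, h, rho, lp_new, cand)) {
        if (std::log(R::runif(0, 1)) < cand.logml - cur.logml) {
          logpi = lp_new; cur = cand;
        }
      }
    }

    // ---- record ----
    if (it > n_burnin && ((it - n_burnin) % thin == 0)) {
      s = gam.size();
      double sigma_e2 = cur.rss / R::rchisq((double)n);
      const double lambda = h * (1.0 - rho) / (1.0 - h);
      arma::vec xs(n, arma::fill::zeros);
      arma::vec beta;
      arma::uvec gu = to_uvec(gam);
      if (s > 0) {
        arma::vec mu = arma::solve(arma::trimatu(cur.R),
                       arma::solve(arma::trimatl(cur.R.t()), cur.b));
        arma::vec z(s);
        for (int j = 0; j < s; ++j) z[j] = R::rnorm(0, 1);
        beta = mu + std::sqrt(sigma_e2) *
               arma::solve(arma::trimatu(cur.R), z);
        xs = X.cols(gu) * beta;
      }
      // polygenic draw in rotated basis
      arma::vec resid_t = ytil;
      if (s > 0) resid_t -= Xtil.cols(gu) * beta;
      arma::vec c = (lambda * d) / (1.0 + lambda * d);
      arma::vec ut(n);
      for (int i = 0; i < n; ++i)
        ut[i] = c[i] * resid_t[i] + R::rnorm(0, std::sqrt(sigma_e2 * c[i]));
      arma::vec uu = U * ut;
      arma::vec gtot = xs + uu;
      double v_s = arma::var(xs);
      double v_g = arma::var(gtot);
      double pve = v_g / (v_g + sigma_e2);
      double pge = (v_g > 0 && s > 0) ? v_s / v_g : 0.0;
      if (pge > 1) pge = 1;
      double h2 = pve * pge;
      draws(kept, 0) = h; draws(kept, 1) = rho;
      draws(kept, 2) = std::exp(logpi);
      draws(kept, 3) = s; draws(kept, 4) = pve; draws(kept, 5) = pge;
      draws(kept, 6) = h2; draws(kept, 7) = cur.logml;
      for (unsigned int j : gam) pip[j] += 1;
      ++kept;
    }
  }
  pip /= std::max(kept, 1);
  return List::create(
    _["draws"] = draws.rows(0, kept - 1),
    _["pip"] = pip,
    _["accept_gamma"] = try_gam > 0 ? acc_gam / try_gam : NA_REAL,
    _["accept_hyper"] = try_hyp > 0 ? acc_hyp / try_hyp : NA_REAL
  );
}
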