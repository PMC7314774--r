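// Adaptive Metropolis-within-Gibbs sampler for the hierarchical robust
// Student-t regression with distributional (sigma) modelling:
//
//   y_i ~ T(nu, mu_i, sigma_i)
//   mu_i    = b0 + u[subj_i] + Xmu_i' beta
//   f(sigma_i) = g0 + Xsg_i' beta_sigma      (f = log by default)
//   u_j ~ N(0, tau),  beta, beta_sigma ~ N(0, 1)
//   b0, g0 ~ t(3, loc, scale),  tau ~ half-t(3, 0, scale),
//   nu = 1 + nu_raw,  nu_raw ~ Gamma(shape, rate)
//
// Blocks: (b0, beta) and (g0, beta_sigma) use multivariate random-walk
// Metropolis with covariance adapted during warmup (Haario-style, frozen
// afterwards); u_j, log(tau) and log(nu_raw) use scalar random walks with
// Robbins-Monro scale adaptation targeting ~0.44 acceptance. All
// randomness comes from R's RNG, so set.seed() makes runs reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// Student-t log density with location/scale
static inline double t_lpdf(double x, double df, double loc, double scale) {
  double z = (x - loc) / scale;
  return R::lgammafn((df + 1.0) / 2.0) - R::lgammafn(df / 2.0)
       - 0.5 * std::log(df * M_PI) - std::log(scale)
       - (df + 1.0) / 2.0 * std::log1p(z * z / df);
}

struct Model {
  arma::vec y;
  arma::mat Xmu, Xsg;
  arma::ivec subj;          // 0-based
  int N, J, Pm, Ps;
  bool student;             // false = gaussian likelihood
  bool log_link;            // false = identity link for sigma
  bool use_u;               // false = no subject term (u pinned at 0)
  double b0_loc, b0_scale, g0_loc, g0_scale, tau_scale;
  double nu_shape, nu_rate, beta_sd, betas_sd;
  std::vector<std::vector<int>> obs_of; // observations per subject
};

// likelihood of all observations given linear predictors
static double loglik_all(const Model& M, const arma::vec& eta_mu,
                         const arma::vec& u, const arma::vec& eta_sg,
                         double nu) {
  double ll = 0.0;
  double cst = 0.0;
  if (M.student)
    cst = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0)
        - 0.5 * std::log(nu * M_PI);
  for (int i = 0; i < M.N; ++i) {
    double sigma = M.log_link ? std::exp(eta_sg[i]) : eta_sg[i];
    if (!(sigma > 0.0)) return -INFINITY;
    double z = (M.y[i] - eta_mu[i] - u[M.subj[i]]) / sigma;
    if (M.student)
      ll += cst - std::log(sigma) - (nu + 1.0) / 2.0 * std::log1p(z * z / nu);
    else
      ll += -0.5 * LOG2PI - std::log(sigma) - 0.5 * z * z;
  }
  return ll;
}

// likelihood restricted to one subject's observations
static double loglik_subj(const Model& M, int j, const arma::vec& eta_mu,
                          double uj, const arma::vec& eta_sg, double nu) {
  double ll = 0.0;
  double cst = 0.0;
  if (M.student)
    cst = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0)
        - 0.5 * std::log(nu * M_PI);
  for (int i : M.obs_of[j]) {
    double sigma = M.log_link ? std::exp(eta_sg[i]) : eta_sg[i];
    if (!(sigma > 0.0)) return -INFINITY;
    double z = (M.y[i] - eta_mu[i] - uj) / sigma;
    if (M.student)
      ll += cst - std::log(sigma) - (nu + 1.0) / 2.0 * std::log1p(z * z / nu);
    else
      ll += -0.5 * LOG2PI - std::log(sigma) - 0.5 * z * z;
  }
  return ll;
}

static double prior_beta(const arma::vec& b, double sd) {   // N(0, sd^2) each
  return -0.5 * arma::dot(b, b) / (sd * sd)
         - b.n_elem * (std::log(sd) + 0.5 * LOG2PI);
}

// log prior of tau parametrised as log_tau (jacobian included)
static double prior_log_tau(double log_tau, double scale) {
  double tau = std::exp(log_tau);
  return std::log(2.0) + t_lpdf(tau, 3.0, 0.0, scale) + log_tau;
}

// log prior of nu_raw parametrised as log_nu_raw (jacobian included)
static double prior_log_nu(double log_nu_raw, double shape, double rate) {
  double nr = std::exp(log_nu_raw);
  return shape * std::log(rate) - R::lgammafn(shape)
       + (shape - 1.0) * std::log(nr) - rate * nr + log_nu_raw;
}

static double prior_u(const arma::vec& u, double tau) {
  return -0.5 * arma::dot(u, u) / (tau * tau)
         - double(u.n_elem) * (std::log(tau) + 0.5 * LOG2PI);
}

static Model build_model(const List& data) {
  Model M;
  M.y = as<arma::vec>(data["y"]);
  M.Xmu = as<arma::mat>(data["Xmu"]);
  M.Xsg = as<arma::mat>(data["Xsg"]);
  M.subj = as<arma::ivec>(data["subj"]);
  M.N = M.y.n_elem; M.Pm = M.Xmu.n_cols; M.Ps = M.Xsg.n_cols;
  M.J = arma::max(M.subj) + 1;
  M.student = as<bool>(data["student"]);
  M.log_link = as<bool>(data["log_link"]);
  M.use_u = as<bool>(data["use_u"]);
  M.b0_loc = as<double>(data["b0_loc"]);   M.b0_scale = as<double>(data["b0_scale"]);
  M.g0_loc = as<double>(data["g0_loc"]);   M.g0_scale = as<double>(data["g0_scale"]);
  M.tau_scale = as<double>(data["tau_scale"]);
  M.nu_shape = as<double>(data["nu_shape"]); M.nu_rate = as<double>(data["nu_rate"]);
  M.beta_sd = as<double>(data["beta_sd"]); M.betas_sd = as<double>(data["betas_sd"]);
  M.obs_of.resize(M.J);
  for (int i = 0; i < M.N; ++i) M.obs_of[M.subj[i]].push_back(i);
  return M;
}

// parameter vector layout: b0, beta[Pm], g0, betas[Ps], log_tau, log_nu_raw, u[J]
// [[Rcpp::export]]
double robt_logpost_cpp(const arma::vec& par, const List& data) {
  Model M = build_model(data);
  int k = 0;
  double b0 = par[k++];
  arma::vec beta = M.Pm > 0 ? arma::vec(par.subvec(k, k + M.Pm - 1))
                            : arma::vec(); k += M.Pm;
  double g0 = par[k++];
  arma::vec betas = M.Ps > 0 ? arma::vec(par.subvec(k, k + M.Ps - 1))
                             : arma::vec(); k += M.Ps;
  double log_tau = par[k++];
  double log_nu_raw = par[k++];
  arma::vec u = par.subvec(k, k + M.J - 1);
  double tau = std::exp(log_tau);
  double nu = 1.0 + std::exp(log_nu_raw);

  arma::vec eta_mu = b0 + M.Xmu * beta;
  arma::vec eta_sg = g0 + M.Xsg * betas;
  double lp = loglik_all(M, eta_mu, u, eta_sg, nu);
  lp += prior_beta(beta, M.beta_sd) + prior_beta(betas, M.betas_sd);
  lp += t_lpdf(b0, 3.0, M.b0_loc, M.b0_scale);
  lp += t_lpdf(g0, 3.0, M.g0_loc, M.g0_scale);
  if (M.use_u) {
    lp += prior_log_tau(log_tau, M.tau_scale);
    lp += prior_u(u, tau);
  }
  if (M.student) lp += prior_log_nu(log_nu_raw, M.nu_shape, M.nu_rate);
  return lp;
}

// multivariate normal proposal step from a Cholesky factor
static arma::vec mvn_step(const arma::mat& cholL, double lambda) {
  arma::vec z(cholL.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = R::norm_rand();
  return lambda * (cholL * z);
}

// Gibbs sampler using the normal scale-mixture representation of the
// Student-t likelihood: y_i ~ N(mu_i, sigma_i^2 / w_i) with
// w_i ~ Gamma(nu/2, nu/2). Given the weights, the mean-model
// coefficients and the subject deviations have exact gaussian
// conditionals (the t(3) intercept prior is likewise expanded with a
// Gamma(3/2, 3/2) mixing scalar); the sigma regression, tau and nu are
// updated by adaptive Metropolis steps (adaptation during warmup only).
// [[Rcpp::export]]
List robt_sample_cpp(const List& data, const arma::vec& init,
                     int n_warmup, int n_save) {
  Model M = build_model(data);
  int k = 0;
  double b0 = init[k++];
  arma::vec beta = M.Pm > 0 ? arma::vec(init.subvec(k, k + M.Pm - 1))
                            : arma::vec(); k += M.Pm;
  double g0 = init[k++];
  arma::vec betas = M.Ps > 0 ? arma::vec(init.subvec(k, k + M.Ps - 1))
                             : arma::vec(); k += M.Ps;
  double log_tau = init[k++];
  double log_nu_raw = init[k++];
  arma::vec u = init.subvec(k, k + M.J - 1);

  double tau = std::exp(log_tau);
  double nu = 1.0 + std::exp(log_nu_raw);
  arma::vec w = arma::ones(M.N);        // t mixture weights (1 if gaussian)
  double v0 = 1.0;                      // mixing scalar of the b0 t(3) prior
  double a_tau = 1.0;                   // Huang-Wand expansion scalar for tau

  arma::mat Xt(M.N, 1 + M.Pm);          // [1, Xmu]
  Xt.col(0).ones();
  if (M.Pm > 0) Xt.cols(1, M.Pm) = M.Xmu;

  arma::vec eta_sg = g0 + M.Xsg * betas;
  arma::vec sigma(M.N), prec(M.N);
  auto refresh_sigma = [&]() {
    for (int i = 0; i < M.N; ++i) {
      sigma[i] = M.log_link ? std::exp(eta_sg[i]) : eta_sg[i];
      prec[i] = w[i] / (sigma[i] * sigma[i]);
    }
  };
  refresh_sigma();
  arma::vec eta_mu = b0 + M.Xmu * beta;

  // adaptive state for the sigma block and the scalar walks
  const int ds = 1 + M.Ps;
  arma::vec mean_s = arma::zeros(ds);
  arma::mat cov_s = arma::eye(ds, ds) * 0.01;
  arma::mat chol_s = arma::chol(cov_s, "lower");
  double lam_s = 2.38 / std::sqrt((double)ds);
  arma::vec sg_scale = arma::ones(ds) * 0.3;
  double tau_step = 0.3, nu_step = 0.5;
  int nadapt = 0;

  int total = n_warmup + n_save;
  arma::mat out(n_save, 2 + M.Pm + M.Ps + 2 + M.J);

  for (int it = 0; it < total; ++it) {
    bool warm = it < n_warmup;
    double t_adapt = std::pow((double)(nadapt + 1), -0.6);

    // ---- latent t weights
    if (M.student) {
      for (int i = 0; i < M.N; ++i) {
        double z = (M.y[i] - eta_mu[i] - u[M.subj[i]]) / sigma[i];
        w[i] = R::rgamma((nu + 1.0) / 2.0, 2.0 / (nu + z * z));
        prec[i] = w[i] / (sigma[i] * sigma[i]);
      }
    }

    // ---- intercept-prior mixing scalar: b0 ~ t(3) as N(loc, scale^2/v0)
    {
      double zb = (b0 - M.b0_loc) / M.b0_scale;
      v0 = R::rgamma(2.0, 2.0 / (3.0 + zb * zb));
    }

    // ---- (b0, beta): exact gaussian conditional
    {
      arma::vec r = M.y;
      for (int i = 0; i < M.N; ++i) r[i] -= u[M.subj[i]];
      arma::mat Xw = Xt.each_col() % prec;
      arma::mat Lam = Xt.t() * Xw;                 // X' W X
      Lam(0, 0) += v0 / (M.b0_scale * M.b0_scale);
      for (int p = 1; p <= M.Pm; ++p)
        Lam(p, p) += 1.0 / (M.beta_sd * M.beta_sd);
      arma::vec rhs = Xw.t() * r;
      rhs[0] += v0 * M.b0_loc / (M.b0_scale * M.b0_scale);
      arma::mat U = arma::chol(Lam);               // upper: U'U = Lam
      arma::vec mu_post = arma::solve(arma::trimatu(U),
                          arma::solve(arma::trimatl(U.t()), rhs));
      arma::vec z(1 + M.Pm);
      for (arma::uword q = 0; q < z.n_elem; ++q) z[q] = R::norm_rand();
      arma::vec draw = mu_post + arma::solve(arma::trimatu(U), z);
      b0 = draw[0];
      if (M.Pm > 0) beta = draw.subvec(1, M.Pm);
      eta_mu = b0 + M.Xmu * beta;
    }

    // ---- subject deviations: exact gaussian conditionals
    if (M.use_u) {
      double tau2 = tau * tau;
      for (int j = 0; j < M.J; ++j) {
        double pr = 1.0 / tau2, m = 0.0;
        for (int i : M.obs_of[j]) {
          pr += prec[i];
          m += prec[i] * (M.y[i] - eta_mu[i]);
        }
        u[j] = m / pr + R::norm_rand() / std::sqrt(pr);
      }
    }

    // ---- (g0, beta_sigma): adaptive Metropolis on the weighted
    //      gaussian likelihood (exact conditional target given w)
    {
      auto cond_ll = [&](const arma::vec& eta) -> double {
        double ll = 0.0;
        for (int i = 0; i < M.N; ++i) {
          double s = M.log_link ? std::exp(eta[i]) : eta[i];
          if (!(s > 0.0)) return -INFINITY;
          double z = (M.y[i] - eta_mu[i] - u[M.subj[i]]) / s;
          ll += -std::log(s) - 0.5 * w[i] * z * z;
        }
        return ll;
      };
      auto eta_from = [&](const arma::vec& v) {
        arma::vec e(M.N); e.fill(v[0]);
        if (M.Ps > 0) e += M.Xsg * v.subvec(1, M.Ps);
        return e;
      };
      double ll_cur = cond_ll(eta_sg);
      // coordinate-wise adaptive walks: g0, then each sigma coefficient
      for (int q = 0; q < ds; ++q) {
        double step = sg_scale[q] * R::norm_rand();
        arma::vec eta_prop = eta_sg;
        if (q == 0) eta_prop += step;
        else eta_prop += step * M.Xsg.col(q - 1);
        double ll_prop = cond_ll(eta_prop);
        double lp_cur, lp_prop;
        if (q == 0) {
          lp_cur = t_lpdf(g0, 3.0, M.g0_loc, M.g0_scale);
          lp_prop = t_lpdf(g0 + step, 3.0, M.g0_loc, M.g0_scale);
        } else {
          double bq = betas[q - 1], s2 = M.betas_sd * M.betas_sd;
          lp_cur = -0.5 * bq * bq / s2;
          lp_prop = -0.5 * (bq + step) * (bq + step) / s2;
        }
        double acc = std::min(1.0, std::exp(ll_prop + lp_prop - ll_cur - lp_cur));
        if (R::unif_rand() < acc) {
          if (q == 0) g0 += step; else betas[q - 1] += step;
          eta_sg = eta_prop;
          ll_cur = ll_prop;
        }
        if (warm) sg_scale[q] *= std::exp(t_adapt * (acc - 0.44));
      }
      // occasional joint move along the adapted covariance keeps
      // correlated coefficients (e.g. intercept vs group) mobile
      {
        arma::vec cur(ds); cur[0] = g0;
        if (M.Ps > 0) cur.subvec(1, M.Ps) = betas;
        arma::vec prop = cur + mvn_step(chol_s, lam_s);
        arma::vec eta_prop = eta_from(prop);
        double ll_prop = cond_ll(eta_prop);
        double lp_cur = t_lpdf(g0, 3.0, M.g0_loc, M.g0_scale)
                      + prior_beta(betas, M.betas_sd);
        double lp_prop = t_lpdf(prop[0], 3.0, M.g0_loc, M.g0_scale)
                       + (M.Ps > 0 ? prior_beta(prop.subvec(1, M.Ps), M.betas_sd) : 0.0);
        double acc = std::min(1.0, std::exp(ll_prop + lp_prop - ll_cur - lp_cur));
        if (R::unif_rand() < acc) {
          g0 = prop[0];
          if (M.Ps > 0) betas = prop.subvec(1, M.Ps);
          eta_sg = eta_prop;
          cur = prop;
        }
        if (warm) {
          lam_s *= std::exp(t_adapt * (acc - 0.234));
          arma::vec d = cur - mean_s;
          mean_s += t_adapt * d;
          cov_s = (1.0 - t_adapt) * cov_s + t_adapt * (d * d.t());
          chol_s = arma::chol(cov_s + 1e-8 * arma::eye(ds, ds), "lower");
        }
      }
      refresh_sigma();
    }

    // ---- tau (hierarchical SD): exact conjugate updates via the
    //      Huang-Wand expansion of the half-t(3) prior
    //      tau^2 | a ~ InvGamma(3/2, 3/a), a ~ InvGamma(1/2, 1/A^2)
    if (M.use_u) {
      double A2 = M.tau_scale * M.tau_scale;
      a_tau = 1.0 / R::rgamma(2.0, 1.0 / (3.0 / (tau * tau) + 1.0 / A2));
      double sh = (3.0 + M.J) / 2.0;
      double rate = 3.0 / a_tau + 0.5 * arma::dot(u, u);
      double tau2 = 1.0 / R::rgamma(sh, 1.0 / rate);
      tau = std::sqrt(tau2);
      log_tau = std::log(tau);
    }

    // ---- nu, log(nu - 1) Metropolis against the *marginal* Student-t
    //      likelihood (weights integrated out; they are refreshed from
    //      their full conditional at the top of the next sweep before
    //      any other update uses them, so the collapsed step is valid
    //      and avoids the strong nu-w coupling)
    if (M.student) {
      auto t_ll = [&](double nuv) {
        double cst = R::lgammafn((nuv + 1.0) / 2.0) - R::lgammafn(nuv / 2.0)
                   - 0.5 * std::log(nuv * M_PI);
        double ll = 0.0;
        for (int i = 0; i < M.N; ++i) {
          double z = (M.y[i] - eta_mu[i] - u[M.subj[i]]) / sigma[i];
          ll += cst - (nuv + 1.0) / 2.0 * std::log1p(z * z / nuv);
        }
        return ll;
      };
      double prop = log_nu_raw + nu_step * R::norm_rand();
      double nu_prop = 1.0 + std::exp(prop);
      double lp_cur = t_ll(nu) + prior_log_nu(log_nu_raw, M.nu_shape, M.nu_rate);
      double lp_prop = t_ll(nu_prop) + prior_log_nu(prop, M.nu_shape, M.nu_rate);
      double acc = std::min(1.0, std::exp(lp_prop - lp_cur));
      if (R::unif_rand() < acc) { log_nu_raw = prop; nu = nu_prop; }
      if (warm) nu_step *= std::exp(t_adapt * (acc - 0.44));
    }

    if (warm) ++nadapt;
    else {
      int r = it - n_warmup, c = 0;
      out(r, c++) = b0;
      for (int p = 0; p < M.Pm; ++p) out(r, c++) = beta[p];
      out(r, c++) = g0;
      for (int p = 0; p < M.Ps; ++p) out(r, c++) = betas[p];
      out(r, c++) = tau;
      out(r, c++) = nu;
      for (int j = 0; j < M.J; ++j) out(r, c++) = u[j];
    }
  }
  return List::create(_["draws"] = out);
}
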