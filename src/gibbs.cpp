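// Blocked Gibbs / Metropolis-within-Gibbs samplers for Gaussian regression
// with weakly informative priors: normal(0,1) on coefficients, half-normal
// (0,1) on standard deviations, LKJ(1) (uniform) on the group correlation.
// The hierarchical model uses a non-centred parameterisation
//   y_i = x_i' beta + z_i' diag(tau) L w_{g(i)} + eps_i,  w_p ~ N(0, I)
// so tau enters the mean linearly (conjugate truncated-normal updates) and
// small group variances do not stall the chain. Uses R's RNG so results are
// reproducible through set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double slice_log_sigma(double sig, double n_eff, double ssr,
                              int max_step = 50) {
  // slice sampler on theta = log(sigma) for target
  //   -n_eff*theta - ssr/(2 e^{2 theta}) - e^{2 theta}/2 + theta  (Jacobian)
  auto logf = [&](double th) {
    double s2 = std::exp(2.0 * th);
    return -n_eff * th - ssr / (2.0 * s2) - s2 / 2.0 + th;
  };
  double th0 = std::log(sig);
  double ly = logf(th0) + std::log(R::runif(0.0, 1.0));
  double w = 1.0;
  double L = th0 - w * R::runif(0.0, 1.0);
  double Rr = L + w;
  for (int i = 0; i < max_step && logf(L) > ly; ++i) L -= w;
  for (int i = 0; i < max_step && logf(Rr) > ly; ++i) Rr += w;
  for (int i = 0; i < 100; ++i) {
    double th1 = R::runif(L, Rr);
    if (logf(th1) >= ly) return std::exp(th1);
    if (th1 < th0) L = th1; else Rr = th1;
  }
  return sig;
}

static double rtruncnorm_pos(double mean, double sd) {
  // N(mean, sd) truncated to [0, inf); inverse-CDF with care in the tail
  double a = -mean / sd;               // standardized lower bound
  if (a < 5.0) {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::runif(pa, 1.0);
    double z = R::qnorm(u, 0.0, 1.0, 1, 0);
    return mean + sd * z;
  }
  // deep tail: exponential rejection (Robert 1995)
  double alpha = (a + std::sqrt(a * a + 4.0)) / 2.0;
  for (int i = 0; i < 1000; ++i) {
    double e = R::exp_rand() / alpha;
    double z = a + e;
    double rho = std::exp(-(z - alpha) * (z - alpha) / 2.0);
    if (R::runif(0.0, 1.0) <= rho) return mean + sd * z;
  }
  return mean + sd * a;
}

static arma::vec rmvnorm_prec(const arma::mat& prec, const arma::vec& b) {
  // sample from N(prec^{-1} b, prec^{-1})
  arma::mat U = arma::chol(prec);                 // prec = U' U
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

// [[Rcpp::export]]
List gibbs_lm_cpp(const arma::vec& y, const arma::mat& X,
                  int n_iter, int n_warmup) {
  const int N = y.n_elem, P = X.n_cols;
  const int S = n_iter - n_warmup;
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  arma::vec beta(P, arma::fill::zeros);
  double sigma = 1.0;
  arma::mat beta_s(S, P);
  arma::vec sigma_s(S);
  for (int it = 0; it < n_iter; ++it) {
    double s2 = sigma * sigma;
    arma::mat prec = XtX / s2 + arma::eye(P, P);   // N(0,1) prior
    beta = rmvnorm_prec(prec, Xty / s2);
    arma::vec resid = y - X * beta;
    sigma = slice_log_sigma(sigma, (double)N, arma::dot(resid, resid));
    if (it >= n_warmup) {
      beta_s.row(it - n_warmup) = beta.t();
      sigma_s(it - n_warmup) = sigma;
    }
  }
  return List::create(_["beta"] = beta_s, _["sigma"] = sigma_s);
}

// [[Rcpp::export]]
List gibbs_hier_cpp(const arma::vec& y, const arma::mat& X,
                    const arma::mat& Z, const arma::ivec& g, int n_group,
                    int n_iter, int n_warmup, double omega_prop_sd) {
  const int N = y.n_elem, P = X.n_cols, K = Z.n_cols;
  const int S = n_iter - n_warmup;
  arma::mat XtX = X.t() * X;

  // per-group row indices
  std::vector<arma::uvec> rows(n_group);
  {
    std::vector<std::vector<arma::uword>> tmp(n_group);
    for (int i = 0; i < N; ++i) tmp[g(i)].push_back(i);
    for (int p = 0; p < n_group; ++p)
      rows[p] = arma::uvec(tmp[p]);
  }

  arma::vec beta(P, arma::fill::zeros);
  arma::mat W(n_group, K, arma::fill::zeros);     // non-centred group effects
  arma::vec tau(K, arma::fill::ones);
  tau *= 0.5;
  arma::mat Omega = arma::eye(K, K);
  arma::mat Lch = arma::eye(K, K);
  double sigma = 1.0;

  arma::mat beta_s(S, P), tau_s(S, K), omega_s(S, K * K);
  arma::mat u_s(S, n_group * K);
  arma::vec sigma_s(S);

  // group contribution to each observation: Z_i' diag(tau) L w_{g(i)}
  auto group_mean = [&](const arma::mat& Wm, const arma::vec& tv,
                        const arma::mat& Lm) {
    arma::mat U = Wm * Lm.t() * arma::diagmat(tv);  // n_group x K, u_p'
    arma::vec out(N);
    for (int p = 0; p < n_group; ++p) {
      const arma::uvec& r = rows[p];
      out.elem(r) = Z.rows(r) * U.row(p).t();
    }
    return out;
  };

  for (int it = 0; it < n_iter; ++it) {
    double s2 = sigma * sigma;

    // beta | rest
    arma::vec gm = group_mean(W, tau, Lch);
    arma::vec r1 = y - gm;
    arma::mat prec = XtX / s2 + arma::eye(P, P);
    beta = rmvnorm_prec(prec, X.t() * r1 / s2);

    // w_p | rest : design M_p = Z_p diag(tau) L
    arma::mat DL = arma::diagmat(tau) * Lch;       // K x K
    arma::vec rfix = y - X * beta;
    for (int p = 0; p < n_group; ++p) {
      const arma::uvec& r = rows[p];
      arma::mat M = Z.rows(r) * DL;                // n_p x K
      arma::mat pr = M.t() * M / s2 + arma::eye(K, K);
      arma::vec wp = rmvnorm_prec(pr, M.t() * rfix.elem(r) / s2);
      W.row(p) = wp.t();
    }

    // tau | rest : y - X beta = sum_k tau_k c_k + eps, c_k = Z_.k * (L w)_k
    arma::mat LW(N, K);                            // (L w_{g(i)})_k per obs
    {
      arma::mat WL = W * Lch.t();                  // n_group x K
      for (int p = 0; p < n_group; ++p) {
        const arma::uvec& r = rows[p];
        LW.rows(r) = arma::repmat(WL.row(p), r.n_elem, 1);
      }
    }
    arma::mat C = Z % LW;                          // N x K elementwise
    arma::vec rtau = rfix - C * tau;
    for (int k = 0; k < K; ++k) {
      arma::vec ck = C.col(k);
      rtau += ck * tau(k);
      double v = 1.0 / (arma::dot(ck, ck) / s2 + 1.0);  // half-N(0,1) prior
      double m = v * arma::dot(ck, rtau) / s2;
      tau(k) = rtruncnorm_pos(m, std::sqrt(v));
      rtau -= ck * tau(k);
    }

    // Omega | rest : random-walk Metropolis per off-diagonal (LKJ(1) flat)
    if (K > 1) {
      arma::vec cur_mean = group_mean(W, tau, Lch);
      arma::vec cur_res = rfix - cur_mean;
      double cur_ss = arma::dot(cur_res, cur_res);
      for (int a = 0; a < K - 1; ++a) {
        for (int b = a + 1; b < K; ++b) {
          double prop = Omega(a, b) + R::norm_rand() * omega_prop_sd;
          if (prop <= -0.999 || prop >= 0.999) continue;
          arma::mat Om2 = Omega;
          Om2(a, b) = Om2(b, a) = prop;
          arma::mat L2;
          if (!arma::chol(L2, Om2, "lower")) continue;
          arma::vec res2 = rfix - group_mean(W, tau, L2);
          double ss2 = arma::dot(res2, res2);
          double logr = -(ss2 - cur_ss) / (2.0 * s2);
          if (std::log(R::runif(0.0, 1.0)) < logr) {
            Omega = Om2; Lch = L2; cur_ss = ss2;
          }
        }
      }
    }

    // sigma | rest
    arma::vec res = rfix - group_mean(W, tau, Lch);
    sigma = slice_log_sigma(sigma, (double)N, arma::dot(res, res));

    if (it >= n_warmup) {
      int s = it - n_warmup;
      beta_s.row(s) = beta.t();
      tau_s.row(s) = tau.t();
      sigma_s(s) = sigma;
      omega_s.row(s) = arma::vectorise(Omega).t();
      arma::mat U = W * Lch.t() * arma::diagmat(tau);  // u_p (centred)
      u_s.row(s) = arma::vectorise(U).t();             // column-major: by K
    }
  }
  return List::create(_["beta"] = beta_s, _["sigma"] = sigma_s,
                      _["tau"] = tau_s, _["omega"] = omega_s,
                      _["u"] = u_s);
}
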