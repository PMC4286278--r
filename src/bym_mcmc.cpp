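#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the BYM Poisson small-area model:
//   deaths_i ~ Poisson(E_i * r_i),  log r_i = alpha + u_i + v_i,
//   u_i ~ N(0, tau_u2) iid,  v ~ ICAR(tau_v2) (sum-to-zero by re-centring),
//   tau_u2, tau_v2 ~ InvGamma(a, b),  alpha ~ N(0, alpha_sd^2).
// Single-site random-walk updates for alpha, u and v with scale adaptation
// during warmup; conjugate Gibbs draws for the two variances.  Uses R's RNG
// so set.seed() on the R side makes chains reproducible.

static inline double loglik_i(double deaths, double E, double eta) {
  return deaths * eta - E * std::exp(eta);
}

// [[Rcpp::export]]
List bym_chain_cpp(NumericVector deaths, NumericVector E,
                   IntegerVector nb_idx, IntegerVector nb_ptr,
                   int n_warmup, int n_samples, int thin,
                   double a_u, double b_u, double a_v, double b_v,
                   double alpha_sd, int icar_rank,
                   double alpha_init, NumericVector u_init,
                   NumericVector v_init,
                   double tau_u2_init, double tau_v2_init) {
  const int n = deaths.size();
  double alpha = alpha_init;
  NumericVector u = clone(u_init), v = clone(v_init);
  double tau_u2 = tau_u2_init, tau_v2 = tau_v2_init;

  const int n_iter = n_warmup + n_samples;
  const int n_keep = n_samples / thin;
  NumericVector keep_alpha(n_keep), keep_tu(n_keep), keep_tv(n_keep);
  NumericMatrix keep_u(n_keep, n), keep_v(n_keep, n);

  double s_alpha = 0.1, s_shift = 0.05, s_ru = 0.5, s_rv = 0.5, s_bx = 0.5;
  std::vector<double> s_u(n, 0.5), s_v(n, 0.5);
  std::vector<int> acc_u(n, 0), acc_v(n, 0);
  int acc_a = 0, try_a = 0, acc_s = 0, try_s = 0;
  int acc_ru = 0, try_ru = 0, acc_rv = 0, try_rv = 0;
  int acc_bx = 0, try_bx = 0;

  std::vector<int> deg(n);
  int n_free = 0;                       // non-isolated nodes carry v
  for (int i = 0; i < n; ++i) {
    deg[i] = nb_ptr[i + 1] - nb_ptr[i];
    if (deg[i] > 0) ++n_free;
  }

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // alpha: random walk against the full likelihood
    {
      double prop = alpha + R::norm_rand() * s_alpha;
      double lr = (alpha * alpha - prop * prop) / (2.0 * alpha_sd * alpha_sd);
      for (int i = 0; i < n; ++i) {
        double base = u[i] + v[i];
        lr += loglik_i(deaths[i], E[i], prop + base) -
              loglik_i(deaths[i], E[i], alpha + base);
      }
      ++try_a;
      if (std::log(R::unif_rand()) < lr) { alpha = prop; ++acc_a; }
    }

    // level-swap move: (alpha + delta, u - delta) leaves the likelihood
    // unchanged, accepted against the priors only; decouples the
    // intercept from the exchangeable effects
    {
      double delta = R::norm_rand() * s_shift;
      double a_new = alpha + delta;
      double lr = (alpha * alpha - a_new * a_new) /
                    (2.0 * alpha_sd * alpha_sd);
      for (int i = 0; i < n; ++i)
        lr += (u[i] * u[i] - (u[i] - delta) * (u[i] - delta)) /
              (2.0 * tau_u2);
      ++try_s;
      if (std::log(R::unif_rand()) < lr) {
        alpha = a_new;
        for (int i = 0; i < n; ++i) u[i] -= delta;
        ++acc_s;
      }
    }

    // u_i: conditionally independent single-site random walks
    for (int i = 0; i < n; ++i) {
      double prop = u[i] + R::norm_rand() * s_u[i];
      double lr = (u[i] * u[i] - prop * prop) / (2.0 * tau_u2) +
                  loglik_i(deaths[i], E[i], alpha + prop + v[i]) -
                  loglik_i(deaths[i], E[i], alpha + u[i] + v[i]);
      if (std::log(R::unif_rand()) < lr) { u[i] = prop; ++acc_u[i]; }
    }

    // v_i: single-site sweep against the ICAR full conditional
    // N(mean of neighbours, tau_v2 / n_i); isolated nodes stay at 0
    for (int i = 0; i < n; ++i) {
      if (deg[i] == 0) { v[i] = 0.0; continue; }
      double m = 0.0;
      for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; ++k) m += v[nb_idx[k]];
      m /= deg[i];
      double prop = v[i] + R::norm_rand() * s_v[i];
      double lr = ((v[i] - m) * (v[i] - m) - (prop - m) * (prop - m)) *
                    deg[i] / (2.0 * tau_v2) +
                  loglik_i(deaths[i], E[i], alpha + u[i] + prop) -
                  loglik_i(deaths[i], E[i], alpha + u[i] + v[i]);
      if (std::log(R::unif_rand()) < lr) { v[i] = prop; ++acc_v[i]; }
    }

    // impose the sum-to-zero constraint on the non-isolated set
    if (n_free > 0) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) if (deg[i] > 0) m += v[i];
      m /= n_free;
      for (int i = 0; i < n; ++i) if (deg[i] > 0) v[i] -= m;
    }

    // joint rescale moves: (u, tau_u2) -> (c u, c^2 tau_u2) and likewise
    // for (v, tau_v2); the Gaussian prior term cancels against the
    // Jacobian, leaving likelihood x inverse-gamma x c^2, which lets the
    // variances traverse their posteriors far faster than Gibbs alone
    {
      double eps = R::norm_rand() * s_ru;
      double c = std::exp(0.5 * eps);
      double lr = -2.0 * a_u * (0.5 * eps) -
                  b_u * (1.0 / (c * c * tau_u2) - 1.0 / tau_u2) + eps;
      for (int i = 0; i < n; ++i)
        lr += loglik_i(deaths[i], E[i], alpha + c * u[i] + v[i]) -
              loglik_i(deaths[i], E[i], alpha + u[i] + v[i]);
      ++try_ru;
      if (std::log(R::unif_rand()) < lr) {
        for (int i = 0; i < n; ++i) u[i] *= c;
        tau_u2 *= c * c;
        ++acc_ru;
      }
    }
    if (n_free > 0) {
      double eps = R::norm_rand() * s_rv;
      double c = std::exp(0.5 * eps);
      double lr = -2.0 * a_v * (0.5 * eps) -
                  b_v * (1.0 / (c * c * tau_v2) - 1.0 / tau_v2) + eps;
      for (int i = 0; i < n; ++i)
        if (deg[i] > 0)
          lr += loglik_i(deaths[i], E[i], alpha + u[i] + c * v[i]) -
                loglik_i(deaths[i], E[i], alpha + u[i] + v[i]);
      ++try_rv;
      if (std::log(R::unif_rand()) < lr) {
        for (int i = 0; i < n; ++i) if (deg[i] > 0) v[i] *= c;
        tau_v2 *= c * c;
        ++acc_rv;
      }
    }

    // balance move: (u, v) -> (u + (1-c) v, c v) leaves u + v (hence the
    // likelihood) unchanged and shifts scale between the exchangeable and
    // the ICAR layer, whose split is identified by the priors only
    if (n_free > 0) {
      double eps = R::norm_rand() * s_bx;
      double c = std::exp(eps);
      double lr = (double)icar_rank * eps;      // Jacobian on the subspace
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double un = u[i] + (1.0 - c) * v[i];
        lr += (u[i] * u[i] - un * un) / (2.0 * tau_u2);
        for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; ++k) {
          int j = nb_idx[k];
          if (j > i) sv += (v[i] - v[j]) * (v[i] - v[j]);
        }
      }
      lr -= (c * c - 1.0) * sv / (2.0 * tau_v2);
      ++try_bx;
      if (std::log(R::unif_rand()) < lr) {
        for (int i = 0; i < n; ++i) {
          u[i] += (1.0 - c) * v[i];
          v[i] *= c;
        }
        ++acc_bx;
      }
    }

    // conjugate variance updates
    {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += u[i] * u[i];
      tau_u2 = 1.0 / R::rgamma(a_u + 0.5 * n, 1.0 / (b_u + 0.5 * ss));
      double sv = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; ++k) {
          int j = nb_idx[k];
          if (j > i) sv += (v[i] - v[j]) * (v[i] - v[j]);
        }
      tau_v2 = 1.0 / R::rgamma(a_v + 0.5 * icar_rank, 1.0 / (b_v + 0.5 * sv));
    }

    // warmup scale adaptation toward ~0.44 single-site acceptance
    if (it < n_warmup && (it + 1) % 50 == 0) {
      auto tune = [](double &s, int &acc, int tries) {
        double r = tries ? (double)acc / tries : 0.44;
        if (r > 0.5) s *= 1.3; else if (r < 0.3) s /= 1.3;
        acc = 0;
      };
      tune(s_alpha, acc_a, try_a); try_a = 0;
      tune(s_shift, acc_s, try_s); try_s = 0;
      tune(s_ru, acc_ru, try_ru); try_ru = 0;
      tune(s_rv, acc_rv, try_rv); try_rv = 0;
      tune(s_bx, acc_bx, try_bx); try_bx = 0;
      for (int i = 0; i < n; ++i) {
        tune(s_u[i], acc_u[i], 50);
        tune(s_v[i], acc_v[i], 50);
      }
    }

    if (it >= n_warmup && (it - n_warmup + 1) % thin == 0 && kept < n_keep) {
      keep_alpha[kept] = alpha;
      keep_tu[kept] = tau_u2;
      keep_tv[kept] = tau_v2;
      for (int i = 0; i < n; ++i) {
        keep_u(kept, i) = u[i];
        keep_v(kept, i) = v[i];
      }
      ++kept;
    }
  }

  return List::create(_["alpha"] = keep_alpha, _["u"] = keep_u,
                      _["v"] = keep_v, _["tau_u2"] = keep_tu,
                      _["tau_v2"] = keep_tv);
}
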