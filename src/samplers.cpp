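#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs samplers for the BYM incidence model and the
// spatial excess-mortality model. Both use the intrinsic CAR prior on the
// spatial effects u (pairwise-difference form, sum-to-zero enforced by
// re-centring each sweep with the shift absorbed into the intercept) and an
// exchangeable normal prior on v. Precisions get conjugate Gamma Gibbs
// updates under gamma priors, or random-walk MH on log(sigma) under
// uniform-on-sigma priors. All randomness comes from R's RNG, so runs are
// reproducible via set.seed().

// Robbins-Monro adaptation of a log proposal scale toward ~44% acceptance
// (optimal for one-dimensional random-walk MH); frozen after burn-in.
static inline void adapt(double &ls, bool accepted, int iter, bool adapting) {
  if (!adapting) return;
  double step = 1.0 / std::pow(iter + 1.0, 0.6);
  if (step > 0.1) step = 0.1;
  ls += step * ((accepted ? 1.0 : 0.0) - 0.44);
  if (ls < -10.0) ls = -10.0;
  if (ls > 5.0) ls = 5.0;
}

// sum over unordered adjacent pairs of (u_i - u_j)^2
static double icar_quad(const NumericVector &u, const IntegerVector &nb,
                        const IntegerVector &nb_start, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) {
      int j = nb[k];
      if (j > i) {
        double d = u[i] - u[j];
        s += d * d;
      }
    }
  }
  return s;
}

// one precision update; returns new tau.
// prior_kind: 0 = Gamma(shape, rate) on tau -> Gibbs.
//             1 = Uniform(lo, hi) on sigma  -> MH on log(sigma).
// quad = the quadratic form in the Gaussian "likelihood" of tau,
// df   = its degrees of freedom (n - n_components for ICAR, n for v).
static double update_tau(double tau, int prior_kind, double p1, double p2,
                         double quad, double df, double &ls, int iter,
                         bool adapting) {
  if (prior_kind == 0) {
    double shape = p1 + 0.5 * df;
    double rate = p2 + 0.5 * quad;
    return R::rgamma(shape, 1.0 / rate);
  }
  // uniform on sigma; work on t = log(sigma), target
  // pi(t) prop tau^{df/2} exp(-tau*quad/2) * sigma * I(lo < sigma < hi),
  // with tau = exp(-2t) and the extra sigma from the Jacobian d sigma/d t.
  double sigma = 1.0 / std::sqrt(tau);
  double t = std::log(sigma);
  double t_new = t + std::exp(ls) * R::norm_rand();
  double sig_new = std::exp(t_new);
  bool acc = false;
  if (sig_new > p1 && sig_new < p2) {
    double tau_new = std::exp(-2.0 * t_new);
    double logr = 0.5 * df * (std::log(tau_new) - std::log(tau))
      - 0.5 * quad * (tau_new - tau) + (t_new - t);
    if (std::log(R::unif_rand()) < logr) {
      tau = tau_new;
      acc = true;
    }
  }
  adapt(ls, acc, iter, adapting);
  return tau;
}

// [[Rcpp::export]]
List bym_mcmc_cpp(NumericVector y, NumericVector e, IntegerVector nb,
                  IntegerVector nb_start, int n_components,
                  int tau_u_kind, double tau_u_p1, double tau_u_p2,
                  int tau_v_kind, double tau_v_p1, double tau_v_p2,
                  double alpha_var, int burn_in, int kept, int thin) {
  int n = y.size();
  int n_draws = kept / thin;
  double alpha = 0.0, tau_u = 1.0, tau_v = 1.0;
  NumericVector u(n, 0.0), v(n, 0.0);
  // proposal log-scales
  double ls_alpha = std::log(0.1), ls_tu = std::log(0.5), ls_tv = std::log(0.5);
  NumericVector ls_u(n, std::log(0.1)), ls_v(n, std::log(0.1));

  NumericVector out_alpha(n_draws), out_tau_u(n_draws), out_tau_v(n_draws);
  NumericMatrix out_u(n_draws, n), out_v(n_draws, n);
  double acc_alpha = 0.0, acc_u = 0.0, acc_v = 0.0;
  int n_total = burn_in + kept;
  int stored = 0;
  double sum_y = 0.0;
  for (int i = 0; i < n; ++i) sum_y += y[i];

  for (int iter = 0; iter < n_total; ++iter) {
    bool adapting = iter < burn_in;

    // --- alpha: random-walk MH on the Poisson likelihood + N(0, alpha_var)
    double sum_m = 0.0;  // sum_i e_i exp(u_i + v_i)
    for (int i = 0; i < n; ++i) sum_m += e[i] * std::exp(u[i] + v[i]);
    {
      double a_new = alpha + std::exp(ls_alpha) * R::norm_rand();
      double logr = sum_y * (a_new - alpha)
        - sum_m * (std::exp(a_new) - std::exp(alpha))
        - 0.5 * (a_new * a_new - alpha * alpha) / alpha_var;
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) { alpha = a_new; if (!adapting) acc_alpha += 1.0; }
      adapt(ls_alpha, acc, iter, adapting);
    }

    // --- u sweep: single-site MH, CAR prior + Poisson likelihood
    double ea = std::exp(alpha);
    for (int i = 0; i < n; ++i) {
      double ui_new = u[i] + std::exp(ls_u[i]) * R::norm_rand();
      double lam_fac = e[i] * ea * std::exp(v[i]);
      double dprior = 0.0;
      for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) {
        int j = nb[k];
        double dn = ui_new - u[j], dc = u[i] - u[j];
        dprior += dn * dn - dc * dc;
      }
      double logr = y[i] * (ui_new - u[i])
        - lam_fac * (std::exp(ui_new) - std::exp(u[i]))
        - 0.5 * tau_u * dprior;
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) { u[i] = ui_new; if (!adapting) acc_u += 1.0; }
      adapt(ls_u[i], acc, iter, adapting);
    }
    // re-centre u to the sum-to-zero constraint, absorbing the shift in alpha
    double mu_bar = 0.0;
    for (int i = 0; i < n; ++i) mu_bar += u[i];
    mu_bar /= n;
    for (int i = 0; i < n; ++i) u[i] -= mu_bar;
    alpha += mu_bar;

    // --- v sweep: single-site MH, N(0, 1/tau_v) prior
    ea = std::exp(alpha);
    for (int i = 0; i < n; ++i) {
      double vi_new = v[i] + std::exp(ls_v[i]) * R::norm_rand();
      double lam_fac = e[i] * ea * std::exp(u[i]);
      double logr = y[i] * (vi_new - v[i])
        - lam_fac * (std::exp(vi_new) - std::exp(v[i]))
        - 0.5 * tau_v * (vi_new * vi_new - v[i] * v[i]);
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) { v[i] = vi_new; if (!adapting) acc_v += 1.0; }
      adapt(ls_v[i], acc, iter, adapting);
    }

    // --- precisions
    double quad_u = icar_quad(u, nb, nb_start, n);
    tau_u = update_tau(tau_u, tau_u_kind, tau_u_p1, tau_u_p2, quad_u,
                       (double)(n - n_components), ls_tu, iter, adapting);
    double quad_v = 0.0;
    for (int i = 0; i < n; ++i) quad_v += v[i] * v[i];
    tau_v = update_tau(tau_v, tau_v_kind, tau_v_p1, tau_v_p2, quad_v,
                       (double)n, ls_tv, iter, adapting);

    // --- storage
    if (iter >= burn_in && ((iter - burn_in + 1) % thin == 0)) {
      out_alpha[stored] = alpha;
      out_tau_u[stored] = tau_u;
      out_tau_v[stored] = tau_v;
      for (int i = 0; i < n; ++i) {
        out_u(stored, i) = u[i];
        out_v(stored, i) = v[i];
      }
      ++stored;
    }
  }

  return List::create(
    _["alpha"] = out_alpha, _["u"] = out_u, _["v"] = out_v,
    _["tau_u"] = out_tau_u, _["tau_v"] = out_tau_v,
    _["accept"] = NumericVector::create(
      _["alpha"] = acc_alpha / kept,
      _["u"] = acc_u / ((double)kept * n),
      _["v"] = acc_v / ((double)kept * n)));
}

// cell log-likelihood contribution: d*log(mu) - mu, mu = dstar + y*exp(eta)
static inline double cell_ll(double d, double y, double dstar, double eta) {
  double mu = dstar + y * std::exp(eta);
  if (mu <= 0.0) return R_NegInf;
  return d * std::log(mu) - mu;
}

// [[Rcpp::export]]
List excess_mcmc_cpp(NumericVector d, NumericVector y, NumericVector dstar,
                     IntegerVector cell_j, IntegerVector cell_k,
                     IntegerVector cell_i, int n_j, int n_k, int n_area,
                     IntegerVector nb, IntegerVector nb_start, int n_components,
                     int tau_u_kind, double tau_u_p1, double tau_u_p2,
                     int tau_v_kind, double tau_v_p1, double tau_v_p2,
                     double coef_var, int burn_in, int kept, int thin) {
  int ncell = d.size();
  int n_draws = kept / thin;

  // per-group cell index lists
  std::vector<std::vector<int> > cells_j(n_j), cells_k(n_k), cells_i(n_area);
  for (int c = 0; c < ncell; ++c) {
    cells_j[cell_j[c]].push_back(c);
    cells_k[cell_k[c]].push_back(c);
    cells_i[cell_i[c]].push_back(c);
  }

  NumericVector aj(n_j, -1.0), bk(n_k, 0.0);  // bk[0] is the fixed reference
  NumericVector u(n_area, 0.0), v(n_area, 0.0);
  double tau_u = 1.0, tau_v = 1.0;
  NumericVector eta(ncell);  // current linear predictor per cell
  for (int c = 0; c < ncell; ++c)
    eta[c] = aj[cell_j[c]] + bk[cell_k[c]] + u[cell_i[c]] + v[cell_i[c]];

  NumericVector ls_aj(n_j, std::log(0.1)), ls_bk(n_k, std::log(0.1));
  NumericVector ls_u(n_area, std::log(0.2)), ls_v(n_area, std::log(0.2));
  double ls_tu = std::log(0.5), ls_tv = std::log(0.5);

  NumericMatrix out_aj(n_draws, n_j), out_bk(n_draws, n_k);
  NumericMatrix out_u(n_draws, n_area), out_v(n_draws, n_area);
  NumericVector out_tau_u(n_draws), out_tau_v(n_draws);
  int stored = 0;
  int n_total = burn_in + kept;

  // generic single-site MH over a cell group with shift `delta` in eta
  // and prior log-ratio `lpr`; returns acceptance and updates eta on accept.
  for (int iter = 0; iter < n_total; ++iter) {
    bool adapting = iter < burn_in;

    // --- alpha_j updates
    for (int j = 0; j < n_j; ++j) {
      double prop = std::exp(ls_aj[j]) * R::norm_rand();
      double a_new = aj[j] + prop;
      double logr = -0.5 * (a_new * a_new - aj[j] * aj[j]) / coef_var;
      for (size_t t = 0; t < cells_j[j].size(); ++t) {
        int c = cells_j[j][t];
        logr += cell_ll(d[c], y[c], dstar[c], eta[c] + prop)
              - cell_ll(d[c], y[c], dstar[c], eta[c]);
      }
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) {
        aj[j] = a_new;
        for (size_t t = 0; t < cells_j[j].size(); ++t) eta[cells_j[j][t]] += prop;
      }
      adapt(ls_aj[j], acc, iter, adapting);
    }

    // --- beta_k updates (k = 0 is the reference, fixed at 0)
    for (int k = 1; k < n_k; ++k) {
      double prop = std::exp(ls_bk[k]) * R::norm_rand();
      double b_new = bk[k] + prop;
      double logr = -0.5 * (b_new * b_new - bk[k] * bk[k]) / coef_var;
      for (size_t t = 0; t < cells_k[k].size(); ++t) {
        int c = cells_k[k][t];
        logr += cell_ll(d[c], y[c], dstar[c], eta[c] + prop)
              - cell_ll(d[c], y[c], dstar[c], eta[c]);
      }
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) {
        bk[k] = b_new;
        for (size_t t = 0; t < cells_k[k].size(); ++t) eta[cells_k[k][t]] += prop;
      }
      adapt(ls_bk[k], acc, iter, adapting);
    }

    // --- u sweep (CAR prior), then re-centre into the alpha_j's
    for (int i = 0; i < n_area; ++i) {
      double prop = std::exp(ls_u[i]) * R::norm_rand();
      double ui_new = u[i] + prop;
      double dprior = 0.0;
      for (int kk = nb_start[i]; kk < nb_start[i + 1]; ++kk) {
        int jj = nb[kk];
        double dn = ui_new - u[jj], dc = u[i] - u[jj];
        dprior += dn * dn - dc * dc;
      }
      double logr = -0.5 * tau_u * dprior;
      for (size_t t = 0; t < cells_i[i].size(); ++t) {
        int c = cells_i[i][t];
        logr += cell_ll(d[c], y[c], dstar[c], eta[c] + prop)
              - cell_ll(d[c], y[c], dstar[c], eta[c]);
      }
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) {
        u[i] = ui_new;
        for (size_t t = 0; t < cells_i[i].size(); ++t) eta[cells_i[i][t]] += prop;
      }
      adapt(ls_u[i], acc, iter, adapting);
    }
    double mu_bar = 0.0;
    for (int i = 0; i < n_area; ++i) mu_bar += u[i];
    mu_bar /= n_area;
    for (int i = 0; i < n_area; ++i) u[i] -= mu_bar;
    for (int j = 0; j < n_j; ++j) aj[j] += mu_bar;
    // eta unchanged: the shift moved from u into every alpha_j

    // --- v sweep
    for (int i = 0; i < n_area; ++i) {
      double prop = std::exp(ls_v[i]) * R::norm_rand();
      double vi_new = v[i] + prop;
      double logr = -0.5 * tau_v * (vi_new * vi_new - v[i] * v[i]);
      for (size_t t = 0; t < cells_i[i].size(); ++t) {
        int c = cells_i[i][t];
        logr += cell_ll(d[c], y[c], dstar[c], eta[c] + prop)
              - cell_ll(d[c], y[c], dstar[c], eta[c]);
      }
      bool acc = std::log(R::unif_rand()) < logr;
      if (acc) {
        v[i] = vi_new;
        for (size_t t = 0; t < cells_i[i].size(); ++t) eta[cells_i[i][t]] += prop;
      }
      adapt(ls_v[i], acc, iter, adapting);
    }

    // --- precisions
    double quad_u = icar_quad(u, nb, nb_start, n_area);
    tau_u = update_tau(tau_u, tau_u_kind, tau_u_p1, tau_u_p2, quad_u,
                       (double)(n_area - n_components), ls_tu, iter, adapting);
    double quad_v = 0.0;
    for (int i = 0; i < n_area; ++i) quad_v += v[i] * v[i];
    tau_v = update_tau(tau_v, tau_v_kind, tau_v_p1, tau_v_p2, quad_v,
                       (double)n_area, ls_tv, iter, adapting);

    if (iter >= burn_in && ((iter - burn_in + 1) % thin == 0)) {
      for (int j = 0; j < n_j; ++j) out_aj(stored, j) = aj[j];
      for (int k = 0; k < n_k; ++k) out_bk(stored, k) = bk[k];
      for (int i = 0; i < n_area; ++i) {
        out_u(stored, i) = u[i];
        out_v(stored, i) = v[i];
      }
      out_tau_u[stored] = tau_u;
      out_tau_v[stored] = tau_v;
      ++stored;
    }
  }

  return List::create(
    _["alpha_j"] = out_aj, _["beta_k"] = out_bk,
    _["u"] = out_u, _["v"] = out_v,
    _["tau_u"] = out_tau_u, _["tau_v"] = out_tau_v);
}

// Gibbs sampler for an intrinsic CAR field at fixed precision: used by the
// synthetic-data generator to draw spatially structured effects.
// [[Rcpp::export]]
NumericVector icar_gibbs_cpp(IntegerVector nb, IntegerVector nb_start,
                             int n, double tau, int sweeps) {
  NumericVector u(n, 0.0);
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      int deg = nb_start[i + 1] - nb_start[i];
      if (deg == 0) continue;
      double m = 0.0;
      for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) m += u[nb[k]];
      m /= deg;
      u[i] = m + R::norm_rand() / std::sqrt(tau * deg);
    }
    double bar = 0.0;
    for (int i = 0; i < n; ++i) bar += u[i];
    bar /= n;
    for (int i = 0; i < n; ++i) u[i] -= bar;
  }
  return u;
}
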