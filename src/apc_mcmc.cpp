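// Metropolis-within-Gibbs kernel for the Poisson APC model.
//
// Single-site Gaussian random-walk Metropolis updates for the intercept,
// each effect level and each overdispersion cell, with conjugate Gamma
// updates for all precisions. Effect vectors are hard re-centred to
// sum-to-zero after every sweep, the subtracted mean being absorbed into
// the intercept (the likelihood and the intrinsic RW kernels are invariant
// to this shift). Proposal scales adapt toward 20-40% acceptance during
// burn-in only, so detailed balance holds for the retained draws.
//
// Uses R's RNG throughout: identical results under identical set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static double rw_q(const std::vector<double>& u, int ord) {
  double q = 0.0;
  int m = (int)u.size();
  if (ord == 1) {
    for (int t = 1; t < m; ++t) { double d = u[t] - u[t - 1]; q += d * d; }
  } else {
    for (int t = 2; t < m; ++t) { double d = u[t] - 2.0 * u[t - 1] + u[t - 2]; q += d * d; }
  }
  return q;
}

// [[Rcpp::export]]
List apc_mcmc_cpp(IntegerMatrix y, IntegerMatrix n, IntegerMatrix kidx,
                  bool has_beta, bool has_gamma, bool has_z,
                  int K,
                  int ord_a, int ord_b, int ord_g,
                  double eff_shape, double eff_rate,
                  double od_shape, double od_rate,
                  int n_iter, int burnin, int thin,
                  bool constrain_gamma_lin,
                  double mu0,
                  NumericVector alpha0, NumericVector beta0, NumericVector gamma0,
                  NumericVector scales0) {
  const int I = y.nrow(), J = y.ncol();
  const int nc = I * J;

  // flattened data, column-major: c = i + I*j
  std::vector<double> yv(nc), nv(nc), eta(nc);
  std::vector<int> kv(nc);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) {
      int c = i + I * j;
      yv[c] = y(i, j); nv[c] = n(i, j); kv[c] = has_gamma ? (kidx(i, j) - 1) : 0;
    }

  // cells per cohort diagonal
  std::vector<std::vector<int>> diag_cells(has_gamma ? K : 0);
  if (has_gamma) for (int c = 0; c < nc; ++c) diag_cells[kv[c]].push_back(c);

  // state
  double mu = mu0;
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> beta(has_beta ? beta0.size() : 0);
  if (has_beta) std::copy(beta0.begin(), beta0.end(), beta.begin());
  std::vector<double> gamma(has_gamma ? gamma0.size() : 0);
  if (has_gamma) std::copy(gamma0.begin(), gamma0.end(), gamma.begin());
  std::vector<double> z(nc, 0.0);
  double tau_a = 1.0, tau_b = 1.0, tau_g = 1.0, tau_z = 1.0;

  auto set_eta = [&]() {
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i) {
        int c = i + I * j;
        eta[c] = mu + alpha[i] + (has_beta ? beta[j] : 0.0) +
          (has_gamma ? gamma[kv[c]] : 0.0) + (has_z ? z[c] : 0.0);
      }
  };
  set_eta();

  // log-likelihood change when eta shifts by d on a set of cells
  auto ll_delta_cells = [&](const std::vector<int>& cells, double d) {
    double s = 0.0;
    for (int c : cells)
      if (nv[c] > 0) s += yv[c] * d - nv[c] * std::exp(eta[c]) * std::expm1(d);
    return s;
  };
  std::vector<int> all_cells(nc), row_cells(J), col_cells(I), one_cell(1);
  for (int c = 0; c < nc; ++c) all_cells[c] = c;

  // blocks: 0 mu, 1 alpha, 2 beta, 3 gamma, 4 z
  double sc[5];
  for (int b = 0; b < 5; ++b) sc[b] = scales0[b];
  long att[5] = {0, 0, 0, 0, 0}, acc[5] = {0, 0, 0, 0, 0};
  long att_keep[5] = {0, 0, 0, 0, 0}, acc_keep[5] = {0, 0, 0, 0, 0};

  const int n_keep = (n_iter - burnin) / thin;
  NumericVector mu_out(n_keep), loglik_out(n_keep);
  NumericMatrix alpha_out(n_keep, I);
  NumericMatrix beta_out(n_keep, has_beta ? J : 0);
  NumericMatrix gamma_out(n_keep, has_gamma ? K : 0);
  NumericMatrix z_out(n_keep, has_z ? nc : 0);
  NumericMatrix tau_out(n_keep, 4);

  int stored = 0;
  for (int it = 0; it < n_iter; ++it) {
    bool adapt = it < burnin;
    long* a_att = adapt ? att : att_keep;
    long* a_acc = adapt ? acc : acc_keep;

    // --- intercept ---
    {
      double d = R::rnorm(0.0, sc[0]);
      double dl = ll_delta_cells(all_cells, d);
      a_att[0]++;
      if (R_finite(dl) && std::log(R::runif(0.0, 1.0)) < dl) {
        mu += d; for (int c = 0; c < nc; ++c) eta[c] += d; a_acc[0]++;
      }
    }

    // --- effect vectors ---
    auto update_effect = [&](std::vector<double>& u, int ord, double tau, int block,
                             int which_dim) {
      int m = (int)u.size();
      for (int t = 0; t < m; ++t) {
        double d = R::rnorm(0.0, sc[block]);
        const std::vector<int>* cells;
        if (which_dim == 0) {            // age: row t
          for (int j = 0; j < J; ++j) row_cells[j] = t + I * j;
          cells = &row_cells;
        } else if (which_dim == 1) {     // period: column t
          for (int i = 0; i < I; ++i) col_cells[i] = i + I * t;
          cells = &col_cells;
        } else {                         // cohort: diagonal t
          cells = &diag_cells[t];
        }
        double q_old = rw_q(u, ord);
        double old = u[t];
        u[t] = old + d;
        double q_new = rw_q(u, ord);
        u[t] = old;
        double dl = ll_delta_cells(*cells, d) - 0.5 * tau * (q_new - q_old);
        a_att[block]++;
        if (R_finite(dl) && std::log(R::runif(0.0, 1.0)) < dl) {
          u[t] = old + d;
          for (int c : *cells) eta[c] += d;
          a_acc[block]++;
        }
      }
      // re-centre: absorb the mean into the intercept (eta unchanged)
      double mn = 0.0;
      for (double v : u) mn += v;
      mn /= m;
      for (double& v : u) v -= mn;
      mu += mn;
    };

    update_effect(alpha, ord_a, tau_a, 1, 0);
    if (has_beta) update_effect(beta, ord_b, tau_b, 2, 1);
    if (has_gamma) update_effect(gamma, ord_g, tau_g, 3, 2);

    // Full-APC identifiability: with RW2 kernels on all effects the
    // posterior is constant along the Lexis null-space direction (a linear
    // trend in gamma traded against linear trends in alpha and beta).
    // Select the representative with zero linear trend in gamma by
    // projecting it out and folding it into alpha and beta; eta and every
    // RW2 quadratic form are unchanged, so this is a pure
    // reparameterisation of the flat direction.
    if (constrain_gamma_lin && has_beta && has_gamma && I > 1 && K > 1) {
      double kbar = 0.5 * (K + 1.0), skk = 0.0, sky = 0.0;
      for (int k = 0; k < K; ++k) {
        double dk = (k + 1.0) - kbar;
        skk += dk * dk; sky += dk * gamma[k];
      }
      double c = sky / skk;
      if (c != 0.0) {
        for (int k = 0; k < K; ++k) gamma[k] -= c * ((k + 1.0) - kbar);
        // c*k = c*M*(I-i) + c*j: centred adjustments, constants cancel
        int M = (K - J) / (I - 1);
        double abar = 0.0, bbar = 0.0;
        for (int i = 0; i < I; ++i) abar += c * M * (I - (i + 1.0));
        abar /= I;
        for (int j = 0; j < J; ++j) bbar += c * (j + 1.0);
        bbar /= J;
        for (int i = 0; i < I; ++i) alpha[i] += c * M * (I - (i + 1.0)) - abar;
        for (int j = 0; j < J; ++j) beta[j] += c * (j + 1.0) - bbar;
        mu += abar + bbar - c * kbar; // zero in exact arithmetic
      }
    }

    // periodically rebuild eta from the state to stop round-off drift
    if ((it + 1) % 1000 == 0) set_eta();

    // --- overdispersion cells ---
    if (has_z) {
      for (int c = 0; c < nc; ++c) {
        double d = R::rnorm(0.0, sc[4]);
        one_cell[0] = c;
        double dl = ll_delta_cells(one_cell, d) -
          0.5 * tau_z * ((z[c] + d) * (z[c] + d) - z[c] * z[c]);
        a_att[4]++;
        if (R_finite(dl) && std::log(R::runif(0.0, 1.0)) < dl) {
          z[c] += d; eta[c] += d; a_acc[4]++;
        }
      }
    }

    // --- precisions: conjugate Gamma updates ---
    tau_a = R::rgamma(eff_shape + 0.5 * (alpha.size() - ord_a),
                      1.0 / (eff_rate + 0.5 * rw_q(alpha, ord_a)));
    if (has_beta)
      tau_b = R::rgamma(eff_shape + 0.5 * (beta.size() - ord_b),
                        1.0 / (eff_rate + 0.5 * rw_q(beta, ord_b)));
    if (has_gamma)
      tau_g = R::rgamma(eff_shape + 0.5 * (gamma.size() - ord_g),
                        1.0 / (eff_rate + 0.5 * rw_q(gamma, ord_g)));
    if (has_z) {
      double ss = 0.0;
      for (int c = 0; c < nc; ++c) ss += z[c] * z[c];
      tau_z = R::rgamma(od_shape + 0.5 * nc, 1.0 / (od_rate + 0.5 * ss));
    }

    // --- adapt proposal scales (burn-in only) ---
    if (adapt && (it + 1) % 100 == 0) {
      for (int b = 0; b < 5; ++b) {
        if (att[b] == 0) continue;
        double rate = (double)acc[b] / (double)att[b];
        if (rate > 0.40) sc[b] *= 1.25;
        else if (rate < 0.20) sc[b] *= 0.80;
        sc[b] = std::min(std::max(sc[b], 1e-6), 10.0);
        att[b] = 0; acc[b] = 0;
      }
    }

    // --- store ---
    if (it >= burnin && (it - burnin) % thin == 0 && stored < n_keep) {
      mu_out[stored] = mu;
      for (int i = 0; i < I; ++i) alpha_out(stored, i) = alpha[i];
      if (has_beta) for (int j = 0; j < J; ++j) beta_out(stored, j) = beta[j];
      if (has_gamma) for (int k = 0; k < K; ++k) gamma_out(stored, k) = gamma[k];
      if (has_z) for (int c = 0; c < nc; ++c) z_out(stored, c) = z[c];
      tau_out(stored, 0) = tau_a; tau_out(stored, 1) = tau_b;
      tau_out(stored, 2) = tau_g; tau_out(stored, 3) = tau_z;
      double ll = 0.0;
      for (int c = 0; c < nc; ++c)
        if (nv[c] > 0) {
          double m_c = nv[c] * std::exp(eta[c]);
          ll += yv[c] * std::log(m_c) - m_c - R::lgammafn(yv[c] + 1.0);
        }
      loglik_out[stored] = ll;
      ++stored;
    }
  }

  NumericVector acc_rates(5), att_out(5), scales_out(5);
  for (int b = 0; b < 5; ++b) {
    acc_rates[b] = att_keep[b] > 0 ? (double)acc_keep[b] / (double)att_keep[b] : NA_REAL;
    att_out[b] = (double)att_keep[b];
    scales_out[b] = sc[b];
  }

  return List::create(
    _["mu"] = mu_out, _["alpha"] = alpha_out, _["beta"] = beta_out,
    _["gamma"] = gamma_out, _["z"] = z_out, _["tau"] = tau_out,
    _["loglik"] = loglik_out, _["acceptance"] = acc_rates,
    _["attempts"] = att_out, _["scales"] = scales_out
  );
}
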