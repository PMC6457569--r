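#include <Rcpp.h>
#include <cmath>
#include <vector>

double pg_draw1(double c); // polyagamma.cpp

// Gibbs sampler for the three-level occupancy model
//   z_i   ~ Bernoulli(logit^-1(x_i' beta))                      site occupancy
//   a_ij  | z_i = 1 ~ Bernoulli(logit^-1(w_ij' alpha))          sample occurrence
//   y_ijk | a_ij = 1 ~ Bernoulli(logit^-1(v_ijk' delta))        replicate detection
// with independent Normal(0, prior_sd^2) priors on all coefficients.
// Coefficient updates are conjugate logistic updates via Polya-Gamma
// augmentation (sampler = 0) or adaptive random-walk Metropolis (sampler = 1).
//
// Update order per iteration: a | z, then z | a, then delta, alpha, beta.

static const int MAXP = 12;

static inline double clipv(double x, double clip) {
  if (x > clip) return clip;
  if (x < -clip) return -clip;
  return x;
}

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Cholesky of p x p SPD matrix A (row-major), in place lower triangle
static void chol_small(double* A, int p) {
  for (int j = 0; j < p; ++j) {
    double d = A[j * p + j];
    for (int k = 0; k < j; ++k) d -= A[j * p + k] * A[j * p + k];
    d = std::sqrt(d > 0 ? d : 1e-300);
    A[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[i * p + j];
      for (int k = 0; k < j; ++k) s -= A[i * p + k] * A[j * p + k];
      A[i * p + j] = s / d;
    }
  }
}

// draw coef ~ N(M^-1 b, M^-1) where M = Xact' Omega Xact + I/prior_sd^2
static void draw_mvn_from_precision(const double* M_in, const double* b,
                                    double* coef, int p) {
  double L[MAXP * MAXP];
  for (int i = 0; i < p * p; ++i) L[i] = M_in[i];
  chol_small(L, p);
  double u[MAXP], m[MAXP];
  // forward solve L u = b
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * p + k] * u[k];
    u[i] = s / L[i * p + i];
  }
  // back solve L' m = u  -> m = M^-1 b
  for (int i = p - 1; i >= 0; --i) {
    double s = u[i];
    for (int k = i + 1; k < p; ++k) s -= L[k * p + i] * m[k];
    m[i] = s / L[i * p + i];
  }
  // noise: solve L' e = eps
  double eps[MAXP], e[MAXP];
  for (int i = 0; i < p; ++i) eps[i] = R::norm_rand();
  for (int i = p - 1; i >= 0; --i) {
    double s = eps[i];
    for (int k = i + 1; k < p; ++k) s -= L[k * p + i] * e[k];
    e[i] = s / L[i * p + i];
  }
  for (int i = 0; i < p; ++i) coef[i] = m[i] + e[i];
}

// one Polya-Gamma conjugate update of a logistic coefficient block
static void update_coef_pg(double* coef, int p, const double* Xmat, int nrow,
                           const std::vector<int>& active, const int* u,
                           double prior_prec, double clip) {
  (void)nrow;
  double M[MAXP * MAXP] = {0.0};
  double b[MAXP] = {0.0};
  for (size_t idx = 0; idx < active.size(); ++idx) {
    int n = active[idx];
    const double* x = Xmat + (size_t)n * p;
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += x[j] * coef[j];
    eta = clipv(eta, clip);
    double om = pg_draw1(eta);
    double kap = u[n] - 0.5;
    for (int j = 0; j < p; ++j) {
      b[j] += kap * x[j];
      for (int k = 0; k <= j; ++k) M[j * p + k] += om * x[j] * x[k];
    }
  }
  for (int j = 0; j < p; ++j) {
    M[j * p + j] += prior_prec;
    for (int k = j + 1; k < p; ++k) M[j * p + k] = M[k * p + j];
  }
  draw_mvn_from_precision(M, b, coef, p);
}

// Bernoulli-logit log posterior of a coefficient block over active units
static double coef_logpost(const double* coef, int p, const double* Xmat,
                           const std::vector<int>& active, const int* u,
                           double prior_prec, double clip) {
  double lp = 0.0;
  for (size_t idx = 0; idx < active.size(); ++idx) {
    int n = active[idx];
    const double* x = Xmat + (size_t)n * p;
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += x[j] * coef[j];
    eta = clipv(eta, clip);
    // u*eta - log(1 + exp(eta)), stable form
    lp += u[n] * eta - (eta > 0 ? eta + std::log1p(std::exp(-eta))
                                : std::log1p(std::exp(eta)));
  }
  for (int j = 0; j < p; ++j) lp -= 0.5 * prior_prec * coef[j] * coef[j];
  return lp;
}

// componentwise adaptive random-walk Metropolis update
static void update_coef_rw(double* coef, int p, const double* Xmat,
                           const std::vector<int>& active, const int* u,
                           double prior_prec, double clip, double* log_step,
                           int* acc, int* tries) {
  for (int j = 0; j < p; ++j) {
    double old = coef[j];
    double lp0 = coef_logpost(coef, p, Xmat, active, u, prior_prec, clip);
    coef[j] = old + std::exp(log_step[j]) * R::norm_rand();
    double lp1 = coef_logpost(coef, p, Xmat, active, u, prior_prec, clip);
    ++tries[j];
    if (std::log(R::unif_rand()) < lp1 - lp0) {
      ++acc[j];
    } else {
      coef[j] = old;
    }
  }
}

// [[Rcpp::export(name = ".occu_gibbs_cpp")]]
Rcpp::List occu_gibbs_cpp(Rcpp::IntegerVector y,
                          Rcpp::IntegerVector site_of_sample,
                          Rcpp::IntegerVector sample_of_rep,
                          Rcpp::NumericMatrix X, Rcpp::NumericMatrix W,
                          Rcpp::NumericMatrix V, Rcpp::NumericMatrix Xtype,
                          int n_iter, int burn_in, double prior_sd,
                          int sampler, bool store_latent, double clip) {
  const int nsite = X.nrow(), nsamp = W.nrow(), nrep = V.nrow();
  const int pb = X.ncol(), pa = W.ncol(), pd = V.ncol();
  const int ntype = Xtype.nrow();
  if (pb > MAXP || pa > MAXP || pd > MAXP)
    Rcpp::stop("too many covariates in one level (max %d)", MAXP);
  const double prior_prec = 1.0 / (prior_sd * prior_sd);
  const int n_keep = n_iter - burn_in;

  // row-major copies of the design matrices for cache-friendly access
  std::vector<double> Xr((size_t)nsite * pb), Wr((size_t)nsamp * pa),
      Vr((size_t)nrep * pd), Xt((size_t)ntype * pb);
  for (int i = 0; i < nsite; ++i)
    for (int j = 0; j < pb; ++j) Xr[(size_t)i * pb + j] = X(i, j);
  for (int i = 0; i < nsamp; ++i)
    for (int j = 0; j < pa; ++j) Wr[(size_t)i * pa + j] = W(i, j);
  for (int i = 0; i < nrep; ++i)
    for (int j = 0; j < pd; ++j) Vr[(size_t)i * pd + j] = V(i, j);
  for (int i = 0; i < ntype; ++i)
    for (int j = 0; j < pb; ++j) Xt[(size_t)i * pb + j] = Xtype(i, j);

  // data-constant: does any replicate / sample carry a detection
  std::vector<int> any_y_samp(nsamp, 0), any_y_site(nsite, 0);
  for (int r = 0; r < nrep; ++r)
    if (y[r]) any_y_samp[sample_of_rep[r]] = 1;
  for (int s = 0; s < nsamp; ++s)
    if (any_y_samp[s]) any_y_site[site_of_sample[s]] = 1;

  // latent states, initialized at the observed minimum
  std::vector<int> z(any_y_site), a(any_y_samp);

  std::vector<double> beta(pb, 0.0), alpha(pa, 0.0), delta(pd, 0.0);
  std::vector<double> theta(nsamp), prep(nrep), psi(nsite);
  std::vector<double> qsamp(nsamp), rsite(nsite);

  // adaptive RW state
  double ls_b[MAXP] = {0}, ls_a[MAXP] = {0}, ls_d[MAXP] = {0};
  int acc_b[MAXP] = {0}, try_b[MAXP] = {0}, acc_a[MAXP] = {0},
      try_a[MAXP] = {0}, acc_d[MAXP] = {0}, try_d[MAXP] = {0};
  int batch = 0;

  std::vector<int> act_sites(nsite), act_samps, act_reps;
  for (int i = 0; i < nsite; ++i) act_sites[i] = i;

  Rcpp::NumericMatrix beta_out(n_keep, pb), alpha_out(n_keep, pa),
      delta_out(n_keep, pd), psi_out(n_keep, ntype);
  Rcpp::NumericVector theta_bar_out(n_keep), p_bar_out(n_keep);
  Rcpp::IntegerMatrix z_out(store_latent ? n_keep : 0, nsite),
      a_out(store_latent ? n_keep : 0, nsamp);

  for (int it = 0; it < n_iter; ++it) {
    // linear predictors -> probabilities
    for (int i = 0; i < nsite; ++i) {
      double e = 0.0;
      for (int j = 0; j < pb; ++j) e += Xr[(size_t)i * pb + j] * beta[j];
      psi[i] = inv_logit(clipv(e, clip));
    }
    for (int s = 0; s < nsamp; ++s) {
      double e = 0.0;
      for (int j = 0; j < pa; ++j) e += Wr[(size_t)s * pa + j] * alpha[j];
      theta[s] = inv_logit(clipv(e, clip));
    }
    for (int r = 0; r < nrep; ++r) {
      double e = 0.0;
      for (int j = 0; j < pd; ++j) e += Vr[(size_t)r * pd + j] * delta[j];
      prep[r] = inv_logit(clipv(e, clip));
    }

    // q_ij = P(all replicates of sample negative | a = 1)
    for (int s = 0; s < nsamp; ++s) qsamp[s] = 1.0;
    for (int r = 0; r < nrep; ++r) qsamp[sample_of_rep[r]] *= 1.0 - prep[r];

    // (1) a | z, y
    for (int s = 0; s < nsamp; ++s) {
      if (!z[site_of_sample[s]]) {
        a[s] = 0;
      } else if (any_y_samp[s]) {
        a[s] = 1;
      } else {
        double num = theta[s] * qsamp[s];
        a[s] = (R::unif_rand() < num / (num + 1.0 - theta[s])) ? 1 : 0;
      }
    }
    // (2) z | a
    std::vector<int> any_a_site(nsite, 0);
    for (int i = 0; i < nsite; ++i) rsite[i] = 1.0;
    for (int s = 0; s < nsamp; ++s) {
      if (a[s]) any_a_site[site_of_sample[s]] = 1;
      rsite[site_of_sample[s]] *= 1.0 - theta[s];
    }
    for (int i = 0; i < nsite; ++i) {
      if (any_a_site[i]) {
        z[i] = 1;
      } else {
        double num = psi[i] * rsite[i];
        z[i] = (R::unif_rand() < num / (num + 1.0 - psi[i])) ? 1 : 0;
      }
    }

    // active units: delta on replicates of a = 1 samples, alpha on samples
    // within z = 1 sites, beta on all sites
    act_reps.clear();
    for (int r = 0; r < nrep; ++r)
      if (a[sample_of_rep[r]]) act_reps.push_back(r);
    act_samps.clear();
    for (int s = 0; s < nsamp; ++s)
      if (z[site_of_sample[s]]) act_samps.push_back(s);

    if (sampler == 0) {
      update_coef_pg(delta.data(), pd, Vr.data(), nrep, act_reps, y.begin(),
                     prior_prec, clip);
      update_coef_pg(alpha.data(), pa, Wr.data(), nsamp, act_samps, a.data(),
                     prior_prec, clip);
      update_coef_pg(beta.data(), pb, Xr.data(), nsite, act_sites, z.data(),
                     prior_prec, clip);
    } else {
      update_coef_rw(delta.data(), pd, Vr.data(), act_reps, y.begin(), prior_prec,
                     clip, ls_d, acc_d, try_d);
      update_coef_rw(alpha.data(), pa, Wr.data(), act_samps, a.data(),
                     prior_prec, clip, ls_a, acc_a, try_a);
      update_coef_rw(beta.data(), pb, Xr.data(), act_sites, z.data(),
                     prior_prec, clip, ls_b, acc_b, try_b);
      if (it < burn_in && (it + 1) % 50 == 0) { // adapt toward 0.44 acceptance
        ++batch;
        double step = std::min(0.05, 1.0 / std::sqrt((double)batch));
        for (int j = 0; j < pd; ++j) {
          ls_d[j] += (acc_d[j] > 0.44 * try_d[j]) ? step : -step;
          acc_d[j] = try_d[j] = 0;
        }
        for (int j = 0; j < pa; ++j) {
          ls_a[j] += (acc_a[j] > 0.44 * try_a[j]) ? step : -step;
          acc_a[j] = try_a[j] = 0;
        }
        for (int j = 0; j < pb; ++j) {
          ls_b[j] += (acc_b[j] > 0.44 * try_b[j]) ? step : -step;
          acc_b[j] = try_b[j] = 0;
        }
      }
    }

    if (it >= burn_in) {
      int k = it - burn_in;
      for (int j = 0; j < pb; ++j) beta_out(k, j) = beta[j];
      for (int j = 0; j < pa; ++j) alpha_out(k, j) = alpha[j];
      for (int j = 0; j < pd; ++j) delta_out(k, j) = delta[j];
      for (int t = 0; t < ntype; ++t) {
        double e = 0.0;
        for (int j = 0; j < pb; ++j) e += Xt[(size_t)t * pb + j] * beta[j];
        psi_out(k, t) = inv_logit(clipv(e, clip));
      }
      double tb = 0.0, pb_ = 0.0;
      for (int s = 0; s < nsamp; ++s) {
        double e = 0.0;
        for (int j = 0; j < pa; ++j) e += Wr[(size_t)s * pa + j] * alpha[j];
        tb += inv_logit(clipv(e, clip));
      }
      for (int r = 0; r < nrep; ++r) {
        double e = 0.0;
        for (int j = 0; j < pd; ++j) e += Vr[(size_t)r * pd + j] * delta[j];
        pb_ += inv_logit(clipv(e, clip));
      }
      theta_bar_out[k] = nsamp > 0 ? tb / nsamp : NA_REAL;
      p_bar_out[k] = nrep > 0 ? pb_ / nrep : NA_REAL;
      if (store_latent) {
        for (int i = 0; i < nsite; ++i) z_out(k, i) = z[i];
        for (int s = 0; s < nsamp; ++s) a_out(k, s) = a[s];
      }
    }
    if (it % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta_out, Rcpp::Named("alpha") = alpha_out,
      Rcpp::Named("delta") = delta_out, Rcpp::Named("psi") = psi_out,
      Rcpp::Named("theta_bar") = theta_bar_out,
      Rcpp::Named("p_bar") = p_bar_out, Rcpp::Named("z") = z_out,
      Rcpp::Named("a") = a_out);
}
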