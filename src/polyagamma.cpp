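#include <Rcpp.h>
#include <cmath>
#include <cfloat>

// Exact sampler for the Polya-Gamma distribution PG(1, z), built from the
// alternating-series rejection sampler for the Jacobi-type density J*(1, z/2)
// (Devroye 2009; Polson, Scott & Windle 2013).  PG(1, z) = J*(1, z/2) / 4.
//
// Uses R's RNG so that set.seed() on the R side makes draws reproducible.

static const double PG_T = 2.0 / M_PI; // truncation point of the mixture

// n-th term of the alternating series for the J* density at x
static inline double pg_aterm(int n, double x, double t) {
  double h = n + 0.5;
  double lf;
  if (x <= t) {
    lf = std::log(M_PI) + std::log(h) +
      1.5 * (std::log(2.0 / M_PI) - std::log(x)) - 2.0 * h * h / x;
  } else {
    lf = std::log(M_PI) + std::log(h) - 0.5 * x * M_PI * M_PI * h * h;
  }
  return std::exp(lf);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t); valid for z >= 0
static double pg_rtigauss(double z, double t) {
  double x;
  if (z * t < 1.0) { // mu > t (includes z == 0): rejection from scaled chi
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  } else {
    double mu = 1.0 / z;
    for (;;) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (x <= 0.0) x = DBL_MIN; // guard against cancellation
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
      if (x < t) return x;
    }
  }
}

double pg_draw1(double c) {
  double z = 0.5 * std::fabs(c);
  const double t = PG_T;
  double K = 0.5 * z * z + 0.125 * M_PI * M_PI;
  // mixing probability of the truncated-exponential component:
  // p = (pi / (2K)) exp(-K t);  q = 2 exp(-z) P(IG(1/z, 1) <= t)
  double logA = std::log(4.0) - std::log(M_PI) - z;
  double logK = std::log(K);
  double Kt = K * t;
  double w = std::sqrt(0.5 * M_PI);
  double logf1 = logA + R::pnorm(w * (t * z - 1.0), 0.0, 1.0, 1, 1) + logK + Kt;
  double logf2 = logA + 2.0 * z + R::pnorm(-w * (t * z + 1.0), 0.0, 1.0, 1, 1) +
    logK + Kt;
  double q_over_p = std::exp(logf1) + std::exp(logf2);
  double ratio = 1.0 / (1.0 + q_over_p);

  for (;;) {
    double x;
    if (R::unif_rand() < ratio) {
      x = t + R::exp_rand() / K;
    } else {
      x = pg_rtigauss(z, t);
    }
    // squeeze via the alternating series
    double s = pg_aterm(0, x, t);
    double u = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_aterm(n, x, t);
        if (u <= s) return 0.25 * x;
      } else {
        s += pg_aterm(n, x, t);
        if (u > s) break;
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_cpp")]]
Rcpp::NumericVector rpg_cpp(int n, Rcpp::NumericVector z) {
  Rcpp::NumericVector out(n);
  int nz = z.size();
  for (int i = 0; i < n; ++i) out[i] = pg_draw1(z[i % nz]);
  return out;
}
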