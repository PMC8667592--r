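// Adaptive random-walk Metropolis sampler for the concentration-manifold
// model: data (u_i = fold change at the steric +1 reference, y_i = fold
// change at the query position), parameters theta = (fc_max, K, sigma) with
// independent uniform priors on [lower_j, upper_j].  Mean function:
//   mu_i = (1 + fc_max * K * t_i) / (1 + K * t_i),  t_i = (1 - u_i)/u_i,
// with the u = 0 endpoint handled as the analytic saturation limit
// mu = fc_max.  Likelihood: y_i ~ Normal(mu_i, sigma).
//
// Warmup: component-wise random walk with Robbins-Monro scale adaptation
// (target acceptance 0.44); the second half of warmup feeds an empirical
// covariance used for blocked proposals (scaled 2.38^2/d) in the sampling
// phase, which matters because fc_max and K are strongly correlated in the
// posterior.  Uses R's RNG so chains are reproducible via set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static inline double loglik(const std::vector<double>& t,
                            const NumericVector& y,
                            double fcmax, double K, double sigma) {
  const int n = y.size();
  double ll = -n * std::log(sigma);
  for (int i = 0; i < n; ++i) {
    double mu;
    if (!R_finite(t[i])) {
      mu = fcmax;
    } else {
      double kt = K * t[i];
      mu = (1.0 + fcmax * kt) / (1.0 + kt);
    }
    double r = (y[i] - mu) / sigma;
    ll -= 0.5 * r * r;
  }
  return ll;
}

static inline bool in_bounds(const double* th, const NumericVector& lo,
                             const NumericVector& hi) {
  for (int j = 0; j < 3; ++j) {
    if (th[j] < lo[j] || th[j] > hi[j]) return false;
  }
  return true;
}

// Cholesky of a 3x3 SPD matrix (lower triangular); returns false if it fails.
static bool chol3(const double S[3][3], double L[3][3]) {
  double a = S[0][0];
  if (a <= 0) return false;
  L[0][0] = std::sqrt(a);
  L[1][0] = S[1][0] / L[0][0];
  L[2][0] = S[2][0] / L[0][0];
  double b = S[1][1] - L[1][0] * L[1][0];
  if (b <= 0) return false;
  L[1][1] = std::sqrt(b);
  L[2][1] = (S[2][1] - L[2][0] * L[1][0]) / L[1][1];
  double c = S[2][2] - L[2][0] * L[2][0] - L[2][1] * L[2][1];
  if (c <= 0) return false;
  L[2][2] = std::sqrt(c);
  L[0][1] = L[0][2] = L[1][2] = 0.0;
  return true;
}

// [[Rcpp::export]]
NumericMatrix manifold_rw_chain(NumericVector u, NumericVector y,
                                int n_draws, int n_warmup,
                                NumericVector lower, NumericVector upper,
                                NumericVector init) {
  const int n = u.size();
  std::vector<double> t(n);
  for (int i = 0; i < n; ++i) {
    t[i] = (u[i] > 0.0) ? (1.0 - u[i]) / u[i] : R_PosInf;
  }

  double th[3] = {init[0], init[1], init[2]};
  if (!in_bounds(th, lower, upper)) stop("initial values outside prior bounds");
  double ll = loglik(t, y, th[0], th[1], th[2]);

  // per-component proposal scales, adapted during warmup
  double scale[3];
  for (int j = 0; j < 3; ++j) {
    double range = upper[j] - lower[j];
    scale[j] = std::min(0.1 * range, std::max(0.25 * std::fabs(th[j]), 1e-3));
  }
  int acc[3] = {0, 0, 0};
  const int batch = 50;

  // warmup draws kept for the covariance estimate
  const int keep_from = n_warmup / 2;
  const int n_keep = n_warmup - keep_from;
  std::vector<double> kept(3 * std::max(n_keep, 1));

  RNGScope rng;

  for (int it = 0; it < n_warmup; ++it) {
    for (int j = 0; j < 3; ++j) {
      double prop[3] = {th[0], th[1], th[2]};
      prop[j] += R::rnorm(0.0, scale[j]);
      if (in_bounds(prop, lower, upper)) {
        double llp = loglik(t, y, prop[0], prop[1], prop[2]);
        if (std::log(R::runif(0.0, 1.0)) < llp - ll) {
          th[j] = prop[j];
          ll = llp;
          acc[j]++;
        }
      }
    }
    if ((it + 1) % batch == 0) {
      for (int j = 0; j < 3; ++j) {
        double rate = (double)acc[j] / batch;
        double delta = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
        scale[j] *= std::exp(rate > 0.44 ? delta : -delta);
        // keep proposals inside a sane window of the prior range
        scale[j] = std::min(scale[j], upper[j] - lower[j]);
        scale[j] = std::max(scale[j], 1e-8);
        acc[j] = 0;
      }
    }
    if (it >= keep_from) {
      int k = it - keep_from;
      kept[3 * k] = th[0];
      kept[3 * k + 1] = th[1];
      kept[3 * k + 2] = th[2];
    }
  }

  // empirical covariance of the late-warmup draws for blocked proposals
  double mean[3] = {0, 0, 0};
  for (int k = 0; k < n_keep; ++k) {
    for (int j = 0; j < 3; ++j) mean[j] += kept[3 * k + j];
  }
  for (int j = 0; j < 3; ++j) mean[j] /= std::max(n_keep, 1);
  double S[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int k = 0; k < n_keep; ++k) {
    for (int a = 0; a < 3; ++a) {
      for (int b = 0; b < 3; ++b) {
        S[a][b] += (kept[3 * k + a] - mean[a]) * (kept[3 * k + b] - mean[b]);
      }
    }
  }
  const double sc = 2.38 * 2.38 / 3.0;
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) {
      S[a][b] = sc * S[a][b] / std::max(n_keep - 1, 1);
    }
    S[a][a] += 1e-10 + 1e-4 * sc * scale[a] * scale[a]; // nugget
  }
  double L[3][3];
  bool use_block = chol3(S, L);

  NumericMatrix out(n_draws, 3);
  for (int it = 0; it < n_draws; ++it) {
    if (use_block) {
      double z[3] = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
      double prop[3];
      for (int a = 0; a < 3; ++a) {
        prop[a] = th[a];
        for (int b = 0; b <= a; ++b) prop[a] += L[a][b] * z[b];
      }
      if (in_bounds(prop, lower, upper)) {
        double llp = loglik(t, y, prop[0], prop[1], prop[2]);
        if (std::log(R::runif(0.0, 1.0)) < llp - ll) {
          th[0] = prop[0]; th[1] = prop[1]; th[2] = prop[2];
          ll = llp;
        }
      }
    } else {
      for (int j = 0; j < 3; ++j) {
        double prop[3] = {th[0], th[1], th[2]};
        prop[j] += R::rnorm(0.0, scale[j]);
        if (in_bounds(prop, lower, upper)) {
          double llp = loglik(t, y, prop[0], prop[1], prop[2]);
          if (std::log(R::runif(0.0, 1.0)) < llp - ll) {
            th[j] = prop[j];
            ll = llp;
          }
        }
      }
    }
    out(it, 0) = th[0];
    out(it, 1) = th[1];
    out(it, 2) = th[2];
  }
  colnames(out) = CharacterVector::create("fc_max", "k_factor", "sigma");
  return out;
}
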