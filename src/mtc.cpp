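// Metropolis-within-Gibbs sampler for the binomial-logit random-effects
// mixed-treatment-comparison (consistency) model:
//
//   r_ik ~ Binomial(n_ik, p_ik),  logit(p_ik) = mu_i + delta_ik,
//   delta = 0 for the trial's baseline arm; the non-baseline delta vector of
//   trial i is MVN with mean (d[t_ik] - d[t_base]), variance sigma^2 and
//   pairwise covariance sigma^2/2 (homogeneous-variance multi-arm model).
//
// Sampled in the non-centered parameterization delta = mean + sigma * z,
// z ~ MVN(0, C) with C = (I + J)/2, so the basic parameters d mix at the
// data-informed scale even when the heterogeneity posterior sits near zero
// (the regime null simulations live in).  C^{-1} = 2(I - J/m) for a trial
// with m arms, so the z log-density needs only sums and sums of squares.
//
// Priors: mu_i ~ N(0, prior_sd^2), d_t ~ N(0, prior_sd^2),
//         sigma ~ Uniform(0, sigma_max); sigma may be fixed (oracle checks).
//
// Random-walk proposals with per-parameter log step sizes adapted by
// Robbins-Monro during burn-in toward 35% acceptance.  Uses R's RNG, so the
// chain is reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -20.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".mtc_run_chain")]]
List mtc_run_chain(IntegerVector arm_trial, IntegerVector arm_treat,
                   IntegerVector arm_r, IntegerVector arm_n,
                   IntegerVector trial_first, IntegerVector trial_size,
                   int k, double prior_sd, double sigma_max,
                   bool fix_sigma, double sigma_value,
                   int n_adapt, int n_iter, int thin) {
  const int A = arm_trial.size();
  const int T = trial_first.size();

  // baseline treatment of each trial; z index per non-baseline arm
  std::vector<int> base_treat(T);
  std::vector<int> z_idx(A, -1);
  int nz = 0;
  for (int i = 0; i < T; ++i) base_treat[i] = arm_treat[trial_first[i]];
  for (int a = 0; a < A; ++a) {
    int i = arm_trial[a];
    if (a != trial_first[i]) z_idx[a] = nz++;
  }
  // non-baseline arms per trial, and per treatment t >= 1 the non-baseline
  // arms whose delta mean involves d[t] (as the arm's own treatment or as
  // the trial's baseline)
  std::vector< std::vector<int> > trial_nb(T);
  for (int a = 0; a < A; ++a)
    if (z_idx[a] >= 0) trial_nb[arm_trial[a]].push_back(a);
  std::vector< std::vector<int> > affected(k);
  for (int a = 0; a < A; ++a) {
    if (z_idx[a] < 0) continue;
    int t_own = arm_treat[a], t_base = base_treat[arm_trial[a]];
    if (t_own >= 1) affected[t_own].push_back(a);
    if (t_base >= 1) affected[t_base].push_back(a);
  }

  std::vector<double> mu(T), z(nz, 0.0), d(k, 0.0);
  double sigma = fix_sigma ? sigma_value : 0.0;

  RNGScope scope;
  // overdispersed but data-anchored initial values
  for (int i = 0; i < T; ++i) {
    int a = trial_first[i];
    double p = (arm_r[a] + 0.5) / (arm_n[a] + 1.0);
    mu[i] = std::log(p / (1.0 - p)) + R::rnorm(0.0, 0.2);
  }
  for (int t = 1; t < k; ++t) d[t] = R::rnorm(0.0, 0.2);
  if (!fix_sigma) sigma = R::runif(0.02, 0.5 * std::min(1.0, sigma_max));

  // arm linear predictor and its binomial log-likelihood
  auto eta = [&](int a) -> double {
    int i = arm_trial[a];
    if (z_idx[a] < 0) return mu[i];
    double mean = d[arm_treat[a]] - d[base_treat[i]];
    return mu[i] + mean + sigma * z[z_idx[a]];
  };
  auto arm_ll = [&](int a) -> double {
    double e = eta(a);
    return arm_r[a] * e - arm_n[a] * log1pexp_(e);
  };
  auto trial_ll = [&](int i) -> double {
    double s = 0.0;
    for (int a = trial_first[i]; a < trial_first[i] + trial_size[i]; ++a)
      s += arm_ll(a);
    return s;
  };
  // z log-prior of trial i: -0.5 z' C^{-1} z with C^{-1} = 2(I - J/m)
  auto z_lp = [&](int i) -> double {
    double ss = 0.0, s = 0.0;
    for (int a : trial_nb[i]) { double v = z[z_idx[a]]; ss += v * v; s += v; }
    return -(ss - s * s / trial_size[i]);
  };

  // per-parameter adaptive log step sizes
  std::vector<double> ls_mu(T, std::log(0.2)), ls_z(nz, std::log(0.5)),
      ls_d(k, std::log(0.1));
  double ls_sigma = std::log(0.1), ls_shift = std::log(0.1);
  const double target = 0.35;

  const int n_save = n_iter / thin;
  NumericMatrix draws(n_save, k);  // cols: d[2..k] then sigma
  double acc_mu = 0.0, acc_z = 0.0, acc_d = 0.0, acc_sigma = 0.0;
  long n_mu = 0, n_z = 0, n_d = 0, n_sigma = 0;

  int save_row = 0;
  for (int sweep = 0; sweep < n_adapt + n_iter; ++sweep) {
    bool adapting = sweep < n_adapt;
    double gamma = adapting ? 1.0 / std::sqrt(1.0 + sweep) : 0.0;

    for (int i = 0; i < T; ++i) {
      double cur = mu[i];
      double lp0 = trial_ll(i) - 0.5 * cur * cur / (prior_sd * prior_sd);
      mu[i] = cur + std::exp(ls_mu[i]) * R::norm_rand();
      double lp1 = trial_ll(i) - 0.5 * mu[i] * mu[i] / (prior_sd * prior_sd);
      bool acc = std::log(R::unif_rand()) < lp1 - lp0;
      if (!acc) mu[i] = cur; else if (!adapting) acc_mu += 1.0;
      if (!adapting) ++n_mu;
      if (adapting) ls_mu[i] += gamma * ((acc ? 1.0 : 0.0) - target);
    }

    if (!fix_sigma || sigma_value > 0.0) {
      for (int i = 0; i < T; ++i) {
        for (int a : trial_nb[i]) {
          int j = z_idx[a];
          double cur = z[j];
          double lp0 = arm_ll(a) + z_lp(i);
          z[j] = cur + std::exp(ls_z[j]) * R::norm_rand();
          double lp1 = arm_ll(a) + z_lp(i);
          bool acc = std::log(R::unif_rand()) < lp1 - lp0;
          if (!acc) z[j] = cur; else if (!adapting) acc_z += 1.0;
          if (!adapting) ++n_z;
          if (adapting) ls_z[j] += gamma * ((acc ? 1.0 : 0.0) - target);
        }
      }
    }

    for (int pass = 0; pass < 2; ++pass) {
      for (int t = 1; t < k; ++t) {
        double cur = d[t];
        double lp0 = -0.5 * cur * cur / (prior_sd * prior_sd);
        for (int a : affected[t]) lp0 += arm_ll(a);
        d[t] = cur + std::exp(ls_d[t]) * R::norm_rand();
        double lp1 = -0.5 * d[t] * d[t] / (prior_sd * prior_sd);
        for (int a : affected[t]) lp1 += arm_ll(a);
        bool acc = std::log(R::unif_rand()) < lp1 - lp0;
        if (!acc) d[t] = cur; else if (!adapting) acc_d += 1.0;
        if (!adapting) ++n_d;
        if (adapting) ls_d[t] += gamma * ((acc ? 1.0 : 0.0) - target);
      }
    }

    // joint translation of all basic parameters: the posterior correlates
    // the d_t through the reference treatment's arms, so a move along the
    // ones-vector decorrelates far faster than single-site updates alone
    {
      double cur_lp = 0.0, prop_lp = 0.0;
      for (int t = 1; t < k; ++t)
        cur_lp += -0.5 * d[t] * d[t] / (prior_sd * prior_sd);
      for (int a = 0; a < A; ++a)
        if (z_idx[a] >= 0) cur_lp += arm_ll(a);
      double shift = std::exp(ls_shift) * R::norm_rand();
      for (int t = 1; t < k; ++t) d[t] += shift;
      for (int t = 1; t < k; ++t)
        prop_lp += -0.5 * d[t] * d[t] / (prior_sd * prior_sd);
      for (int a = 0; a < A; ++a)
        if (z_idx[a] >= 0) prop_lp += arm_ll(a);
      bool acc = std::log(R::unif_rand()) < prop_lp - cur_lp;
      if (!acc) { for (int t = 1; t < k; ++t) d[t] -= shift; }
      if (adapting) ls_shift += gamma * ((acc ? 1.0 : 0.0) - target);
    }

    if (!fix_sigma) {
      double cur = sigma;
      double lp0 = 0.0;
      for (int i = 0; i < T; ++i)
        for (int a : trial_nb[i]) lp0 += arm_ll(a);
      double prop = cur + std::exp(ls_sigma) * R::norm_rand();
      // reflect at the prior bounds to keep the kernel symmetric
      for (int guard = 0; guard < 64 && (prop < 0.0 || prop > sigma_max); ++guard) {
        if (prop < 0.0) prop = -prop;
        if (prop > sigma_max) prop = 2.0 * sigma_max - prop;
      }
      sigma = prop;
      double lp1 = 0.0;
      for (int i = 0; i < T; ++i)
        for (int a : trial_nb[i]) lp1 += arm_ll(a);
      bool acc = std::log(R::unif_rand()) < lp1 - lp0;
      if (!acc) sigma = cur; else if (!adapting) acc_sigma += 1.0;
      if (!adapting) ++n_sigma;
      if (adapting) ls_sigma += gamma * ((acc ? 1.0 : 0.0) - target);
    }

    if (!adapting) {
      int it = sweep - n_adapt;
      if ((it + 1) % thin == 0 && save_row < n_save) {
        for (int t = 1; t < k; ++t) draws(save_row, t - 1) = d[t];
        draws(save_row, k - 1) = sigma;
        ++save_row;
      }
    }
  }

  return List::create(
    _["draws"] = draws,
    _["accept"] = NumericVector::create(
      _["mu"] = n_mu ? acc_mu / n_mu : NA_REAL,
      _["z"] = n_z ? acc_z / n_z : NA_REAL,
      _["d"] = n_d ? acc_d / n_d : NA_REAL,
      _["sigma"] = n_sigma ? acc_sigma / n_sigma : NA_REAL));
}
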