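#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Besag-York-Mollie model
//   O_i ~ Poisson(E_i * exp(alpha + u_i + v_i))
//   u ~ ICAR(tau_u) with sum-to-zero constraint (recentred every sweep,
//       the mean being transferred into alpha, a likelihood-preserving move
//       valid under the flat prior on alpha)
//   v_i ~ N(0, 1/tau_v)
//   tau_u ~ Gamma(a_u, b_u), tau_v ~ Gamma(a_v, b_v)  (shape/rate)
// Optional zero-inflation: O_i ~ pi * delta_0 + (1 - pi) * Poisson(mu_i),
// with a global pi ~ Beta(a_z, b_z) updated by conjugate data augmentation.
//
// Single-site adaptive random-walk Metropolis on u_i, v_i and alpha;
// conjugate Gamma updates for the precisions. Uses R's RNG so seeding via
// set.seed() in the caller makes runs reproducible.

static inline double sqr(double x) { return x * x; }

// [[Rcpp::export]]
List bym_mcmc_cpp(IntegerVector O, NumericVector E, List nb,
                  double a_u, double b_u, double a_v, double b_v,
                  int n_iter, int burn_in, int thin,
                  bool zip, double a_z, double b_z,
                  IntegerVector pinned, NumericMatrix X) {
  const int n = O.size();
  const int p = X.ncol();  // fixed-effect covariates (N(0, 10^2) priors)
  std::vector<std::vector<int>> adj(n);
  int n_free_u = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nb[i];
    adj[i] = std::vector<int>(v.begin(), v.end());  // 0-based indices
    if (!pinned[i]) ++n_free_u;
  }
  // rank deficiency of the ICAR precision: one per connected component of
  // the non-pinned graph; caller guarantees a single component.
  const double icar_df = (n_free_u > 1) ? (n_free_u - 1) : 0.0;

  std::vector<double> u(n, 0.0), v(n, 0.0);
  double alpha = 0.0;
  {
    double so = 0, se = 0;
    for (int i = 0; i < n; ++i) { so += O[i]; se += E[i]; }
    if (so > 0 && se > 0) alpha = std::log(so / se);
  }
  double tau_u = 10.0, tau_v = 10.0, pi = zip ? 0.1 : 0.0;
  std::vector<int> z(n, 0);  // structural-zero indicators (ZIP only)
  std::vector<double> beta(p, 0.0), xb(n, 0.0);

  // adaptive RW scales
  std::vector<double> s_u(n, 0.3), s_v(n, 0.3), s_b(p > 0 ? p : 1, 0.1);
  double s_a = 0.1;
  std::vector<int> acc_u(n, 0), acc_v(n, 0), acc_b(p > 0 ? p : 1, 0);
  int acc_a = 0, adapt_window = 50;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix keep_u(n_keep, n), keep_v(n_keep, n);
  NumericMatrix keep_beta(n_keep, p > 0 ? p : 1);
  NumericVector keep_alpha(n_keep), keep_tau_u(n_keep), keep_tau_v(n_keep),
      keep_pi(n_keep), keep_dev(n_keep);
  int stored = 0;
  long long tot_acc_u = 0, tot_prop_u = 0, tot_acc_v = 0, tot_prop_v = 0;
  long long tot_acc_a = 0, tot_prop_a = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- ZIP data augmentation ---
    if (zip) {
      int nz = 0;
      for (int i = 0; i < n; ++i) {
        if (O[i] == 0) {
          double mu = E[i] * std::exp(alpha + xb[i] + u[i] + v[i]);
          double p1 = pi, p0 = (1.0 - pi) * std::exp(-mu);
          z[i] = (R::unif_rand() < p1 / (p1 + p0)) ? 1 : 0;
        } else z[i] = 0;
        nz += z[i];
      }
      pi = R::rbeta(a_z + nz, b_z + n - nz);
    }

    // --- u: single-site RW Metropolis ---
    for (int i = 0; i < n; ++i) {
      if (pinned[i]) { u[i] = 0.0; continue; }
      ++tot_prop_u;
      const double cur = u[i];
      const double prop = cur + R::norm_rand() * s_u[i];
      double nb_sum = 0; int d = 0;
      for (int j : adj[i]) { nb_sum += u[j]; ++d; }
      double dlp = -0.5 * tau_u * (d * sqr(prop) - 2.0 * prop * nb_sum
                                   - d * sqr(cur) + 2.0 * cur * nb_sum);
      if (!(zip && z[i])) {
        const double lam = E[i] * std::exp(alpha + xb[i] + v[i]);
        dlp += O[i] * (prop - cur) - lam * (std::exp(prop) - std::exp(cur));
      }
      if (std::log(R::unif_rand()) < dlp) {
        u[i] = prop; ++acc_u[i]; ++tot_acc_u;
      }
    }
    // global rescale move u -> c*u (c = e^z): decorrelates the field
    // amplitude from tau_u, which single-site updates mix slowly
    if (n_free_u > 2) {
      const double zstep = R::norm_rand() * 0.2;
      const double c = std::exp(zstep);
      double ssq = 0, dll = 0;
      for (int i = 0; i < n; ++i) {
        if (pinned[i]) continue;
        for (int j : adj[i]) if (j > i && !pinned[j]) ssq += sqr(u[i] - u[j]);
        if (!(zip && z[i])) {
          const double lam = E[i] * std::exp(alpha + xb[i] + v[i]);
          dll += O[i] * (c - 1.0) * u[i] -
                 lam * (std::exp(c * u[i]) - std::exp(u[i]));
        }
      }
      const double dlp = dll - 0.5 * tau_u * (c * c - 1.0) * ssq +
                         (n_free_u - 1) * zstep;
      if (std::log(R::unif_rand()) < dlp) {
        for (int i = 0; i < n; ++i) if (!pinned[i]) u[i] *= c;
      }
    }

    // recentre: transfer the mean of the free u into alpha
    if (n_free_u > 0) {
      double m = 0;
      for (int i = 0; i < n; ++i) if (!pinned[i]) m += u[i];
      m /= n_free_u;
      for (int i = 0; i < n; ++i) if (!pinned[i]) u[i] -= m;
      alpha += m;
    }

    // --- v: single-site RW Metropolis ---
    for (int i = 0; i < n; ++i) {
      ++tot_prop_v;
      const double cur = v[i];
      const double prop = cur + R::norm_rand() * s_v[i];
      double dlp = -0.5 * tau_v * (sqr(prop) - sqr(cur));
      if (!(zip && z[i])) {
        const double lam = E[i] * std::exp(alpha + xb[i] + u[i]);
        dlp += O[i] * (prop - cur) - lam * (std::exp(prop) - std::exp(cur));
      }
      if (std::log(R::unif_rand()) < dlp) {
        v[i] = prop; ++acc_v[i]; ++tot_acc_v;
      }
    }

    // --- alpha: RW Metropolis (flat prior) ---
    {
      ++tot_prop_a;
      const double prop = alpha + R::norm_rand() * s_a;
      double dlp = 0;
      for (int i = 0; i < n; ++i) {
        if (zip && z[i]) continue;
        const double lam = E[i] * std::exp(xb[i] + u[i] + v[i]);
        dlp += O[i] * (prop - alpha) - lam * (std::exp(prop) - std::exp(alpha));
      }
      if (std::log(R::unif_rand()) < dlp) { alpha = prop; ++acc_a; ++tot_acc_a; }
    }

    // --- beta: RW Metropolis per coefficient, N(0, 100) prior ---
    for (int j = 0; j < p; ++j) {
      const double cur = beta[j];
      const double prop = cur + R::norm_rand() * s_b[j];
      double dlp = -0.5 * (sqr(prop) - sqr(cur)) / 100.0;
      for (int i = 0; i < n; ++i) {
        const double x = X(i, j);
        if (x == 0.0 || (zip && z[i])) continue;
        const double base = alpha + xb[i] - x * cur + u[i] + v[i];
        dlp += O[i] * x * (prop - cur) -
               E[i] * (std::exp(base + x * prop) - std::exp(base + x * cur));
      }
      if (std::log(R::unif_rand()) < dlp) {
        for (int i = 0; i < n; ++i) xb[i] += X(i, j) * (prop - cur);
        beta[j] = prop; ++acc_b[j];
      }
    }

    // --- precisions: conjugate Gamma updates ---
    {
      double ssq = 0;
      for (int i = 0; i < n; ++i) {
        if (pinned[i]) continue;
        for (int j : adj[i]) if (j > i && !pinned[j]) ssq += sqr(u[i] - u[j]);
      }
      tau_u = R::rgamma(a_u + 0.5 * icar_df, 1.0 / (b_u + 0.5 * ssq));
      double ssv = 0;
      for (int i = 0; i < n; ++i) ssv += sqr(v[i]);
      tau_v = R::rgamma(a_v + 0.5 * n, 1.0 / (b_v + 0.5 * ssv));
    }

    // --- adapt proposal scales during burn-in ---
    if (it < burn_in && (it + 1) % adapt_window == 0) {
      for (int i = 0; i < n; ++i) {
        double r = (double)acc_u[i] / adapt_window;
        s_u[i] *= std::exp(0.6 * (r - 0.44));
        acc_u[i] = 0;
        r = (double)acc_v[i] / adapt_window;
        s_v[i] *= std::exp(0.6 * (r - 0.44));
        acc_v[i] = 0;
      }
      double r = (double)acc_a / adapt_window;
      s_a *= std::exp(0.6 * (r - 0.3));
      acc_a = 0;
      for (int j = 0; j < p; ++j) {
        r = (double)acc_b[j] / adapt_window;
        s_b[j] *= std::exp(0.6 * (r - 0.3));
        acc_b[j] = 0;
      }
    }

    // --- store ---
    if (it >= burn_in && (it - burn_in) % thin == 0 && stored < n_keep) {
      double dev = 0;
      for (int i = 0; i < n; ++i) {
        const double mu = E[i] * std::exp(alpha + xb[i] + u[i] + v[i]);
        if (zip) {
          double lik = (O[i] == 0 ? pi : 0.0) +
                       (1.0 - pi) * R::dpois(O[i], mu, 0);
          dev += -2.0 * std::log(std::max(lik, 1e-300));
        } else {
          dev += -2.0 * R::dpois(O[i], mu, 1);
        }
      }
      for (int i = 0; i < n; ++i) { keep_u(stored, i) = u[i]; keep_v(stored, i) = v[i]; }
      for (int j = 0; j < p; ++j) keep_beta(stored, j) = beta[j];
      keep_alpha[stored] = alpha;
      keep_tau_u[stored] = tau_u;
      keep_tau_v[stored] = tau_v;
      keep_pi[stored] = pi;
      keep_dev[stored] = dev;
      ++stored;
    }
  }

  return List::create(
    _["alpha"] = keep_alpha, _["u"] = keep_u, _["v"] = keep_v,
    _["beta"] = keep_beta,
    _["tau_u"] = keep_tau_u, _["tau_v"] = keep_tau_v,
    _["pi"] = keep_pi, _["deviance"] = keep_dev,
    _["accept"] = NumericVector::create(
        _["u"] = tot_prop_u ? (double)tot_acc_u / tot_prop_u : NA_REAL,
        _["v"] = tot_prop_v ? (double)tot_acc_v / tot_prop_v : NA_REAL,
        _["alpha"] = tot_prop_a ? (double)tot_acc_a / tot_prop_a : NA_REAL));
}
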