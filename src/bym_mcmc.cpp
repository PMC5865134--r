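// Metropolis-within-Gibbs sampler for the BYM Poisson disease-mapping model:
//   O_i ~ Poisson(mu_i),  log mu_i = log E_i + alpha + x_i' beta + u_i + v_i
// u has an intrinsic CAR prior (precision tau_u, equal weights, re-centred to
// zero mean per connected component every sweep -- the classic resolution of
// the ICAR impropriety); v_i ~ N(0, 1/tau_v); Gamma priors on precisions are
// conjugate and sampled by Gibbs; alpha, beta, u_i, v_i move by random-walk
// Metropolis with step sizes adapted during burn-in only (target acceptance
// 0.2-0.5), frozen afterwards so detailed balance holds post burn-in.
//
// Fitted means mu are cached and updated multiplicatively on acceptance, with
// a periodic full recomputation to stop floating-point drift.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void adapt_step(double &s, int acc, int window) {
  double rate = (double)acc / window;
  if (rate > 0.5) s *= 1.3;
  else if (rate < 0.2) s /= 1.3;
  if (s < 1e-6) s = 1e-6;
  if (s > 10.0) s = 10.0;
}

// [[Rcpp::export]]
List bym_chain_cpp(IntegerVector O, NumericVector E, NumericMatrix X,
                   IntegerVector adj, IntegerVector adj_ptr,
                   IntegerVector comp, double icar_rank,
                   double a_u, double b_u, double a_v, double b_v,
                   double prec_alpha, double prec_beta,
                   int burn_in, int n_iter, int thin) {
  const int n = O.size();
  const int p = X.ncol();
  if (E.size() != n || X.nrow() != n)
    stop("dimension mismatch between cases and design");

  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = adj_ptr[i + 1] - adj_ptr[i];
  int ncomp = 0;
  for (int i = 0; i < n; ++i) if (comp[i] + 1 > ncomp) ncomp = comp[i] + 1;
  std::vector<int> comp_size(ncomp, 0);
  for (int i = 0; i < n; ++i) comp_size[comp[i]]++;

  double sumO = 0.0, sumE = 0.0;
  for (int i = 0; i < n; ++i) { sumO += O[i]; sumE += E[i]; }

  // state
  double alpha = std::log((sumO > 0 ? sumO : 1.0) / sumE);
  std::vector<double> beta(p, 0.0), u(n, 0.0), v(n, 0.0), xb(n, 0.0);
  double tau_u = 10.0, tau_v = 10.0;
  std::vector<double> lam(n);
  auto recompute_lam = [&]() {
    for (int i = 0; i < n; ++i) {
      double eta = alpha + xb[i] + u[i] + v[i];
      lam[i] = E[i] * std::exp(eta);
      if (!std::isfinite(lam[i]))
        stop("non-finite fitted mean (region %d, eta = %g); model diverged",
             i + 1, eta);
    }
  };
  recompute_lam();

  // Adaptive random-walk step multipliers. Proposal SDs are the multiplier
  // over the square root of an approximate conditional precision
  // (prior precision + observed count), so the proposal scale tracks the
  // current tau draws even after the multipliers freeze at end of burn-in;
  // the precisions entering a proposal never depend on the coordinate being
  // moved, keeping the kernel symmetric.
  std::vector<double> s_u(n, 1.0), s_v(n, 1.0), s_b(p, 1.0);
  double s_a = 1.0;
  double prec_a_like = sumO + prec_alpha + 1.0;
  std::vector<double> prec_b_like(p, prec_beta);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      prec_b_like[j] += O[i] * X(i, j) * X(i, j);
  std::vector<int> acc_u(n, 0), acc_v(n, 0), acc_b(p, 0);
  int acc_a = 0;
  double s_scale_u = 0.5, s_scale_v = 0.5;
  int acc_scale_u = 0, acc_scale_v = 0;
  const int window = 100;

  const int nkeep = n_iter / thin;
  NumericVector alpha_s(nkeep), tau_u_s(nkeep), tau_v_s(nkeep);
  NumericMatrix beta_s(nkeep, p), u_s(nkeep, n), v_s(nkeep, n);

  RNGScope scope;
  std::vector<double> cmean(ncomp);
  const int total = burn_in + n_iter;

  for (int t = 1; t <= total; ++t) {
    // --- intercept ---
    {
      double d = R::norm_rand() * s_a / std::sqrt(prec_a_like);
      double slam = 0.0;
      for (int i = 0; i < n; ++i) slam += lam[i];
      double f = std::exp(d);
      double logr = d * sumO - slam * (f - 1.0)
        - 0.5 * prec_alpha * ((alpha + d) * (alpha + d) - alpha * alpha);
      if (std::isfinite(f) && std::log(R::unif_rand()) < logr) {
        alpha += d;
        for (int i = 0; i < n; ++i) lam[i] *= f;
        ++acc_a;
      }
    }
    // --- covariate coefficients ---
    for (int j = 0; j < p; ++j) {
      double d = R::norm_rand() * s_b[j] / std::sqrt(prec_b_like[j]);
      double bn = beta[j] + d;
      double logr = -0.5 * prec_beta * (bn * bn - beta[j] * beta[j]);
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        double xij = X(i, j);
        if (xij == 0.0) continue;
        double f = std::exp(d * xij);
        if (!std::isfinite(f)) { ok = false; break; }
        logr += d * xij * O[i] - lam[i] * (f - 1.0);
      }
      if (ok && std::log(R::unif_rand()) < logr) {
        beta[j] = bn;
        for (int i = 0; i < n; ++i) {
          double xij = X(i, j);
          if (xij != 0.0) { xb[i] += d * xij; lam[i] *= std::exp(d * xij); }
        }
        ++acc_b[j];
      }
    }
    // --- spatial effects u (islands stay at 0) ---
    for (int i = 0; i < n; ++i) {
      if (deg[i] == 0) continue;
      double m = 0.0;
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) m += u[adj[k]];
      m /= deg[i];
      double d = R::norm_rand() * s_u[i] / std::sqrt(tau_u * deg[i] + O[i] + 1.0);
      double un = u[i] + d;
      double f = std::exp(d);
      double logr = d * O[i] - lam[i] * (f - 1.0)
        - 0.5 * tau_u * deg[i] * ((un - m) * (un - m) - (u[i] - m) * (u[i] - m));
      if (std::isfinite(lam[i] * f) && std::log(R::unif_rand()) < logr) {
        u[i] = un;
        lam[i] *= f;
        ++acc_u[i];
      }
    }
    // --- re-centre u within each connected component ---
    std::fill(cmean.begin(), cmean.end(), 0.0);
    for (int i = 0; i < n; ++i) cmean[comp[i]] += u[i];
    for (int c = 0; c < ncomp; ++c) cmean[c] /= comp_size[c];
    for (int i = 0; i < n; ++i) {
      double m = cmean[comp[i]];
      if (m != 0.0) { u[i] -= m; lam[i] *= std::exp(-m); }
    }
    // --- unstructured effects v ---
    for (int i = 0; i < n; ++i) {
      double d = R::norm_rand() * s_v[i] / std::sqrt(tau_v + O[i] + 1.0);
      double vn = v[i] + d;
      double f = std::exp(d);
      double logr = d * O[i] - lam[i] * (f - 1.0)
        - 0.5 * tau_v * (vn * vn - v[i] * v[i]);
      if (std::isfinite(lam[i] * f) && std::log(R::unif_rand()) < logr) {
        v[i] = vn;
        lam[i] *= f;
        ++acc_v[i];
      }
    }
    // --- precisions: conjugate Gamma updates ---
    {
      double q2 = 0.0;  // sum over ordered pairs (u_i - u_j)^2 = 2 * u'(D-W)u
      for (int i = 0; i < n; ++i)
        for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
          double dd = u[i] - u[adj[k]];
          q2 += dd * dd;
        }
      double quad = 0.5 * q2;
      tau_u = R::rgamma(a_u + 0.5 * icar_rank, 1.0 / (b_u + 0.5 * quad));
      double sv = 0.0;
      for (int i = 0; i < n; ++i) sv += v[i] * v[i];
      tau_v = R::rgamma(a_v + 0.5 * n, 1.0 / (b_v + 0.5 * sv));
    }
    // --- joint scale moves on (u, tau_u) and (v, tau_v) ---
    // Propose s = exp(eps), rescale the effect vector by s and the
    // precision by 1/s^2: the prior kernel tau * quadform is invariant and
    // the ICAR/normal rank terms cancel against the Jacobian, leaving
    //   log r = delta loglik - 2 a log s - b tau (1/s^2 - 1).
    // This decorrelates the precision from the slowly-mixing magnitude of
    // the effect vector, which single-site moves alone track poorly.
    {
      double eps = R::norm_rand() * s_scale_u;
      double s = std::exp(eps);
      double dll = 0.0;
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        if (u[i] == 0.0) continue;
        double f = std::exp((s - 1.0) * u[i]);
        if (!std::isfinite(f) || !std::isfinite(lam[i] * f)) { ok = false; break; }
        dll += (s - 1.0) * u[i] * O[i] - lam[i] * (f - 1.0);
      }
      double logr = dll - 2.0 * a_u * eps - b_u * tau_u * (1.0 / (s * s) - 1.0);
      if (ok && std::log(R::unif_rand()) < logr) {
        for (int i = 0; i < n; ++i) {
          if (u[i] != 0.0) lam[i] *= std::exp((s - 1.0) * u[i]);
          u[i] *= s;
        }
        tau_u /= s * s;
        ++acc_scale_u;
      }
    }
    {
      double eps = R::norm_rand() * s_scale_v;
      double s = std::exp(eps);
      double dll = 0.0;
      bool ok = true;
      for (int i = 0; i < n; ++i) {
        double f = std::exp((s - 1.0) * v[i]);
        if (!std::isfinite(f) || !std::isfinite(lam[i] * f)) { ok = false; break; }
        dll += (s - 1.0) * v[i] * O[i] - lam[i] * (f - 1.0);
      }
      double logr = dll - 2.0 * a_v * eps - b_v * tau_v * (1.0 / (s * s) - 1.0);
      if (ok && std::log(R::unif_rand()) < logr) {
        for (int i = 0; i < n; ++i) {
          lam[i] *= std::exp((s - 1.0) * v[i]);
          v[i] *= s;
        }
        tau_v /= s * s;
        ++acc_scale_v;
      }
    }
    // --- burn-in step adaptation ---
    if (t <= burn_in && t % window == 0) {
      adapt_step(s_a, acc_a, window); acc_a = 0;
      adapt_step(s_scale_u, acc_scale_u, window); acc_scale_u = 0;
      adapt_step(s_scale_v, acc_scale_v, window); acc_scale_v = 0;
      for (int j = 0; j < p; ++j) { adapt_step(s_b[j], acc_b[j], window); acc_b[j] = 0; }
      for (int i = 0; i < n; ++i) {
        adapt_step(s_u[i], acc_u[i], window); acc_u[i] = 0;
        adapt_step(s_v[i], acc_v[i], window); acc_v[i] = 0;
      }
    }
    if (t % 500 == 0) recompute_lam();
    // --- store thinned post burn-in draws ---
    if (t > burn_in && (t - burn_in) % thin == 0) {
      int s = (t - burn_in) / thin - 1;
      if (s < nkeep) {
        alpha_s[s] = alpha;
        tau_u_s[s] = tau_u;
        tau_v_s[s] = tau_v;
        for (int j = 0; j < p; ++j) beta_s(s, j) = beta[j];
        for (int i = 0; i < n; ++i) { u_s(s, i) = u[i]; v_s(s, i) = v[i]; }
      }
    }
    if (t % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["intercept"] = alpha_s, _["beta"] = beta_s,
    _["u"] = u_s, _["v"] = v_s,
    _["tau_u"] = tau_u_s, _["tau_v"] = tau_v_s);
}
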