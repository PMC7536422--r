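#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with correlated allele frequencies
// (F-model).  Cluster frequencies p_k at each locus are Dirichlet-distributed
// around ancestral frequencies p_A with concentration (1 - F_k) / F_k; each
// individual has an ancestry vector q_i ~ Dirichlet(alpha, ..., alpha); every
// gene copy carries a latent cluster-of-origin z updated by Gibbs.  alpha,
// F_k and p_A move by Metropolis steps.  Uses R's RNG for reproducibility.
//
// alleles: n x (2L) matrix of 1-based allele indices per locus (complete
// genotypes only); nall: number of distinct alleles per locus.

static double rgamma1(double shape) {
  // R::rgamma handles shape < 1 correctly
  return R::rgamma(shape, 1.0);
}

static void rdirichlet(const std::vector<double>& conc, std::vector<double>& out) {
  double s = 0.0;
  for (size_t j = 0; j < conc.size(); ++j) { out[j] = rgamma1(conc[j]); s += out[j]; }
  if (s <= 0.0) {
    for (size_t j = 0; j < conc.size(); ++j) out[j] = 1.0 / conc.size();
    return;
  }
  for (size_t j = 0; j < conc.size(); ++j) {
    out[j] /= s;
    if (out[j] < 1e-12) out[j] = 1e-12;
  }
}

// log Dirichlet density of x with concentration vector a
static double ldirichlet(const std::vector<double>& x, const std::vector<double>& a) {
  double s = 0.0, lg = 0.0, ll = 0.0;
  for (size_t j = 0; j < x.size(); ++j) {
    s += a[j]; lg += R::lgammafn(a[j]); ll += (a[j] - 1.0) * std::log(x[j]);
  }
  return R::lgammafn(s) - lg + ll;
}

// [[Rcpp::export]]
List cpp_admixture_gibbs(IntegerMatrix alleles, IntegerVector nall, int K,
                         int burnin, int niter, int thin,
                         double alpha_init, double alpha_step, double alpha_max,
                         bool update_alpha) {
  int n = alleles.nrow();
  int L = nall.size();
  if (alleles.ncol() != 2 * L) stop("alleles must have 2 columns per locus");

  // state
  std::vector< std::vector<double> > pa(L);            // ancestral freqs
  std::vector< std::vector< std::vector<double> > > p(K);  // p[k][l][j]
  NumericMatrix q(n, K);
  std::vector<double> F(K, 0.1);
  double alpha = alpha_init;
  IntegerMatrix z(n, 2 * L);

  // init: pa = overall observed frequencies (with pseudocount), p_k = pa
  for (int l = 0; l < L; ++l) {
    pa[l].assign(nall[l], 1.0);
    for (int i = 0; i < n; ++i) {
      pa[l][alleles(i, 2 * l) - 1] += 1.0;
      pa[l][alleles(i, 2 * l + 1) - 1] += 1.0;
    }
    double s = 0.0;
    for (int j = 0; j < nall[l]; ++j) s += pa[l][j];
    for (int j = 0; j < nall[l]; ++j) pa[l][j] /= s;
  }
  for (int k = 0; k < K; ++k) {
    p[k].resize(L);
    for (int l = 0; l < L; ++l) p[k][l] = pa[l];
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c) z(i, c) = (int)(R::unif_rand() * K) % K;

  int nstore = niter / thin;
  NumericMatrix qsamp(nstore, n * K);
  NumericMatrix qsum(n, K);
  NumericVector lnp_trace; // running accumulation
  double lnp_sum = 0.0, lnp_sumsq = 0.0;
  int lnp_n = 0;
  double alpha_sum = 0.0;
  std::vector<double> F_sum(K, 0.0);
  int stored = 0;

  std::vector<double> prob(K), conc, draw;
  std::vector< std::vector< std::vector<int> > > cnt(K); // cnt[k][l][j]
  for (int k = 0; k < K; ++k) {
    cnt[k].resize(L);
    for (int l = 0; l < L; ++l) cnt[k][l].assign(nall[l], 0);
  }

  int total = burnin + niter;
  for (int it = 0; it < total; ++it) {
    // --- z updates + allele-origin counts
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(cnt[k][l].begin(), cnt[k][l].end(), 0);
    std::vector< std::vector<int> > m(n, std::vector<int>(K, 0));
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = alleles(i, 2 * l + c) - 1;
          double s = 0.0;
          for (int k = 0; k < K; ++k) { prob[k] = q(i, k) * p[k][l][a]; s += prob[k]; }
          double u = R::unif_rand() * s, acc = 0.0;
          int zk = K - 1;
          for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { zk = k; break; } }
          z(i, 2 * l + c) = zk;
          cnt[zk][l][a] += 1;
          m[i][zk] += 1;
        }
      }
    }
    // --- q updates
    conc.resize(K); draw.resize(K);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) conc[k] = alpha + m[i][k];
      rdirichlet(conc, draw);
      for (int k = 0; k < K; ++k) q(i, k) = draw[k];
    }
    if (K == 1) for (int i = 0; i < n; ++i) q(i, 0) = 1.0;
    // --- p updates
    for (int k = 0; k < K; ++k) {
      double lam = (1.0 - F[k]) / F[k];
      for (int l = 0; l < L; ++l) {
        conc.resize(nall[l]); draw.resize(nall[l]);
        for (int j = 0; j < nall[l]; ++j) conc[j] = lam * pa[l][j] + cnt[k][l][j];
        rdirichlet(conc, draw);
        p[k][l] = draw;
      }
    }
    // --- F_k Metropolis (logit random walk, Beta(1,3) prior)
    for (int k = 0; k < K; ++k) {
      double f0 = F[k];
      double lf = std::log(f0 / (1.0 - f0)) + R::norm_rand() * 0.3;
      double f1 = 1.0 / (1.0 + std::exp(-lf));
      if (f1 < 1e-4) f1 = 1e-4;
      if (f1 > 0.999) f1 = 0.999;
      double ll = 0.0;
      double lam0 = (1.0 - f0) / f0, lam1 = (1.0 - f1) / f1;
      for (int l = 0; l < L; ++l) {
        std::vector<double> a0(nall[l]), a1(nall[l]);
        for (int j = 0; j < nall[l]; ++j) { a0[j] = lam0 * pa[l][j]; a1[j] = lam1 * pa[l][j]; }
        ll += ldirichlet(p[k][l], a1) - ldirichlet(p[k][l], a0);
      }
      // prior Beta(1,3) + logit-walk Jacobian
      ll += 2.0 * (std::log(1.0 - f1) - std::log(1.0 - f0));
      ll += std::log(f1 * (1.0 - f1)) - std::log(f0 * (1.0 - f0));
      if (std::log(R::unif_rand()) < ll) F[k] = f1;
    }
    // --- p_A Metropolis per locus (Dirichlet random-walk proposal)
    double cprop = 500.0;
    for (int l = 0; l < L; ++l) {
      std::vector<double> conc0(nall[l]), prop(nall[l]);
      for (int j = 0; j < nall[l]; ++j) conc0[j] = cprop * pa[l][j] + 0.5;
      rdirichlet(conc0, prop);
      double ll = 0.0;
      for (int k = 0; k < K; ++k) {
        double lam = (1.0 - F[k]) / F[k];
        std::vector<double> a0(nall[l]), a1(nall[l]);
        for (int j = 0; j < nall[l]; ++j) { a0[j] = lam * pa[l][j]; a1[j] = lam * prop[j]; }
        ll += ldirichlet(p[k][l], a1) - ldirichlet(p[k][l], a0);
      }
      // uniform (Dirichlet(1)) prior on p_A cancels; proposal asymmetry:
      std::vector<double> concp(nall[l]);
      for (int j = 0; j < nall[l]; ++j) concp[j] = cprop * prop[j] + 0.5;
      ll += ldirichlet(pa[l], concp) - ldirichlet(prop, conc0);
      if (std::log(R::unif_rand()) < ll) pa[l] = prop;
    }
    // --- alpha Metropolis
    if (update_alpha && K > 1) {
      double a1 = alpha + R::norm_rand() * alpha_step;
      if (a1 > 1e-3 && a1 < alpha_max) {
        double ll = 0.0;
        ll += n * (R::lgammafn(K * a1) - K * R::lgammafn(a1)
                   - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(q(i, k));
        ll += (a1 - alpha) * slq;
        if (std::log(R::unif_rand()) < ll) alpha = a1;
      }
    }
    // --- data log-likelihood given (q, p)
    double lnp = 0.0;
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = alleles(i, 2 * l + c) - 1;
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += q(i, k) * p[k][l][a];
          lnp += std::log(s);
        }
    if (it >= burnin) {
      lnp_sum += lnp; lnp_sumsq += lnp * lnp; ++lnp_n;
      alpha_sum += alpha;
      for (int k = 0; k < K; ++k) { F_sum[k] += F[k]; }
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += q(i, k);
      int post = it - burnin;
      if ((post + 1) % thin == 0 && stored < nstore) {
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) qsamp(stored, i * K + k) = q(i, k);
        ++stored;
      }
    }
  }

  double lmean = lnp_sum / lnp_n;
  double lvar = lnp_sumsq / lnp_n - lmean * lmean;
  if (lvar < 0) lvar = 0;
  NumericVector Fm(K);
  for (int k = 0; k < K; ++k) Fm[k] = F_sum[k] / lnp_n;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) qsum(i, k) /= lnp_n;

  return List::create(
    _["q_mean"] = qsum, _["q_samples"] = qsamp, _["n_stored"] = stored,
    _["ln_pd"] = lmean - lvar / 2.0, _["ln_lik_mean"] = lmean,
    _["ln_lik_var"] = lvar, _["alpha_mean"] = alpha_sum / lnp_n,
    _["F_mean"] = Fm);
}
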