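#include <Rcpp.h>
using namespace Rcpp;

// Weir & Cockerham (1984) variance components for one locus.
// alleles: n x 2 matrix of 1-based allele indices (0 = missing call);
// pop: 1-based population index per individual; npop populations.
// Returns (sum_a, sum_b, sum_c) over alleles; all-missing or monomorphic
// loci return zeros.
static void wc_locus(const int* a1, const int* a2, const int* pop,
                     int n, int npop, int nall,
                     double& A, double& B, double& C) {
  A = B = C = 0.0;
  std::vector<double> ni(npop, 0.0);
  std::vector< std::vector<double> > cnt(npop, std::vector<double>(nall, 0.0));
  std::vector< std::vector<double> > het(npop, std::vector<double>(nall, 0.0));
  for (int i = 0; i < n; ++i) {
    int x = a1[i], y = a2[i];
    if (x <= 0 || y <= 0) continue;
    int p = pop[i] - 1;
    if (p < 0 || p >= npop) continue;
    ni[p] += 1.0;
    cnt[p][x - 1] += 1.0;
    cnt[p][y - 1] += 1.0;
    if (x != y) { het[p][x - 1] += 1.0; het[p][y - 1] += 1.0; }
  }
  double nsum = 0.0, nsq = 0.0;
  int r = 0;
  for (int p = 0; p < npop; ++p) { nsum += ni[p]; nsq += ni[p] * ni[p]; if (ni[p] > 0) ++r; }
  if (r < 2 || nsum <= 0) return;
  double rr = (double)npop; // populations with data assumed == npop by caller
  double nbar = nsum / rr;
  if (nbar <= 1.0) return;
  double nc = (nsum - nsq / nsum) / (rr - 1.0);
  if (nc <= 0) return;
  for (int j = 0; j < nall; ++j) {
    double pbar = 0.0, hbar = 0.0;
    for (int p = 0; p < npop; ++p) {
      if (ni[p] == 0) continue;
      pbar += cnt[p][j] / 2.0;       // n_i * p_ij = count/2... (count is gene copies)
      hbar += het[p][j];
    }
    pbar /= (rr * nbar);             // sum n_i p_ij / (r nbar)
    hbar /= (rr * nbar);
    double s2 = 0.0;
    for (int p = 0; p < npop; ++p) {
      if (ni[p] == 0) continue;
      double pij = cnt[p][j] / (2.0 * ni[p]);
      s2 += ni[p] * (pij - pbar) * (pij - pbar);
    }
    s2 /= ((rr - 1.0) * nbar);
    double inner = pbar * (1.0 - pbar) - (rr - 1.0) / rr * s2 - hbar / 4.0;
    A += nbar / nc * (s2 - inner / (nbar - 1.0));
    B += nbar / (nbar - 1.0) *
         (pbar * (1.0 - pbar) - (rr - 1.0) / rr * s2 -
          (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
    C += hbar / 2.0;
  }
}

// Per-locus WC components for a multi-locus genotype table.
// alleles: n x 2L, nall: distinct alleles per locus, pop: 1-based labels.
// [[Rcpp::export]]
NumericMatrix cpp_wc_components(IntegerMatrix alleles, IntegerVector nall,
                                IntegerVector pop, int npop) {
  int n = alleles.nrow(), L = nall.size();
  NumericMatrix out(L, 3);
  std::vector<int> a1(n), a2(n), pp(n);
  for (int i = 0; i < n; ++i) pp[i] = pop[i];
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) { a1[i] = alleles(i, 2 * l); a2[i] = alleles(i, 2 * l + 1); }
    double A, B, C;
    wc_locus(a1.data(), a2.data(), pp.data(), n, npop, nall[l], A, B, C);
    out(l, 0) = A; out(l, 1) = B; out(l, 2) = C;
  }
  return out;
}

// Permutation null for pairwise theta: individuals shuffled between the two
// populations; returns n_perm permuted theta values.
// [[Rcpp::export]]
NumericVector cpp_wc_perm(IntegerMatrix alleles, IntegerVector nall,
                          IntegerVector pop, int npop, int n_perm) {
  int n = alleles.nrow(), L = nall.size();
  std::vector<int> pp(n);
  for (int i = 0; i < n; ++i) pp[i] = pop[i];
  NumericVector out(n_perm);
  std::vector<int> a1(n), a2(n);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle of labels
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(pp[i], pp[j]);
    }
    double num = 0.0, den = 0.0;
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < n; ++i) { a1[i] = alleles(i, 2 * l); a2[i] = alleles(i, 2 * l + 1); }
      double A, B, C;
      wc_locus(a1.data(), a2.data(), pp.data(), n, npop, nall[l], A, B, C);
      num += A; den += A + B + C;
    }
    out[b] = (den > 0.0) ? num / den : 0.0;
  }
  return out;
}

// Guo-Thompson Monte-Carlo exact HWE test statistic: conditional on allele
// counts, P(array) is proportional to 2^H / prod(n_ij!).  Shuffles the 2n
// gene copies and re-pairs consecutively.  Returns count of permuted arrays
// with log-probability <= observed (within tolerance), for the add-one rule.
// [[Rcpp::export]]
int cpp_hwe_mc(IntegerVector a1, IntegerVector a2, int nall, int n_mc) {
  int n = a1.size();
  std::vector<int> copies(2 * n);
  for (int i = 0; i < n; ++i) { copies[2 * i] = a1[i] - 1; copies[2 * i + 1] = a2[i] - 1; }
  std::vector<double> tab(nall * nall);

  auto stat = [&](const std::vector<int>& cp) {
    std::fill(tab.begin(), tab.end(), 0.0);
    int H = 0;
    for (int i = 0; i < n; ++i) {
      int x = cp[2 * i], y = cp[2 * i + 1];
      if (x > y) std::swap(x, y);
      if (x != y) ++H;
      tab[x * nall + y] += 1.0;
    }
    double s = H * M_LN2;
    for (int j = 0; j < nall * nall; ++j)
      if (tab[j] > 0) s -= R::lgammafn(tab[j] + 1.0);
    return s;
  };

  double obs = stat(copies);
  int cnt = 0;
  for (int b = 0; b < n_mc; ++b) {
    for (int i = 2 * n - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(copies[i], copies[j]);
    }
    if (stat(copies) <= obs + 1e-9) ++cnt;
  }
  return cnt;
}

// Permutation null for the standardized index of association r_bar_d.
// dists: list of n x n per-locus genetic distance matrices.  Variances of
// the lower-triangle entries are permutation-invariant, so only pairwise
// covariances are recomputed per permutation.
// [[Rcpp::export]]
NumericVector cpp_rbard_perm(List dists, int n_perm) {
  int L = dists.size();
  std::vector<NumericMatrix> D(L);
  for (int l = 0; l < L; ++l) D[l] = as<NumericMatrix>(dists[l]);
  int n = D[0].nrow();
  int npair = n * (n - 1) / 2;

  std::vector<double> mean(L), var(L);
  std::vector< std::vector<double> > v(L, std::vector<double>(npair));
  std::vector<int> perm(n);

  // invariant per-locus moments from the identity permutation
  for (int l = 0; l < L; ++l) {
    int idx = 0; double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d = D[l](i, j); v[l][idx++] = d; s += d; ss += d * d;
      }
    mean[l] = s / npair;
    var[l] = ss / npair - mean[l] * mean[l];
  }
  double denom = 0.0;
  for (int j = 0; j < L; ++j)
    for (int k = j + 1; k < L; ++k) denom += std::sqrt(var[j] * var[k]);

  NumericVector out(n_perm);
  for (int b = 0; b < n_perm; ++b) {
    // independent permutation of individuals at each locus
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(R::unif_rand() * (i + 1)); if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      int idx = 0;
      for (int i = 0; i < n; ++i)
        for (int jj = i + 1; jj < n; ++jj)
          v[l][idx++] = D[l](perm[i], perm[jj]);
    }
    double num = 0.0;
    for (int j = 0; j < L; ++j)
      for (int k = j + 1; k < L; ++k) {
        double s = 0.0;
        for (int i = 0; i < npair; ++i) s += v[j][i] * v[k][i];
        num += s / npair - mean[j] * mean[k];
      }
    out[b] = (denom > 0.0) ? num / denom : NA_REAL;
  }
  return out;
}

// Mean shared-allele distance between two populations at one locus:
// average over cross-population individual pairs of 1 - (shared alleles)/2.
// [[Rcpp::export]]
double cpp_das_locus(IntegerVector a1, IntegerVector a2, IntegerVector pop) {
  int n = a1.size();
  double s = 0.0; long cnt = 0;
  for (int i = 0; i < n; ++i) {
    if (pop[i] != 1 || a1[i] <= 0) continue;
    for (int j = 0; j < n; ++j) {
      if (pop[j] != 2 || a1[j] <= 0) continue;
      int sh = 0;
      int xi = a1[i], yi = a2[i], xj = a1[j], yj = a2[j];
      // count shared alleles with multiplicity
      if (xi == xj) { sh++; if (yi == yj) sh++; }
      else if (xi == yj) { sh++; if (yi == xj) sh++; }
      else if (yi == xj || yi == yj) sh++;
      s += 1.0 - sh / 2.0;
      ++cnt;
    }
  }
  return cnt > 0 ? s / cnt : NA_REAL;
}
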