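#include <Rcpp.h>
using namespace Rcpp;

// Structured-coalescent machinery shared by the microsatellite and mtDNA
// simulators.  Times are in generations; `popsize` is on the *gene copy*
// scale (2N for diploid autosomal loci, N_f for mtDNA), so the coalescence
// rate per lineage pair within population i is 1 / popsize[i].
//
// Demographic events, ordered by time into the past, one row each:
//   col 0: time
//   col 1: type (0 = join: lineages of pop a move to pop b;
//                1 = admixture: lineages of pop a move to pop b with
//                    probability r, else to pop c;
//                2 = size change: pop a's size (gene copies) becomes r)
//   col 2: a   col 3: b   col 4: c   col 5: r
// Population indices in `events` are 1-based (R convention).
//
// Uses R's RNG throughout so set.seed() in R gives bit-reproducible trees.

// [[Rcpp::export]]
List cpp_coal_tree(IntegerVector nsam, NumericVector popsize,
                   NumericMatrix events) {
  popsize = clone(popsize);  // size-change events must not touch the R copy
  int npop = popsize.size();
  int n = 0;
  for (int i = 0; i < nsam.size(); ++i) n += nsam[i];
  if (n < 2) stop("need at least two sampled gene copies");

  int nnodes = 2 * n - 1;
  IntegerVector parent(nnodes, -1);
  NumericVector ntime(nnodes, 0.0);

  // active lineage lists per population
  std::vector< std::vector<int> > act(npop);
  int tip = 0;
  for (int p = 0; p < nsam.size(); ++p)
    for (int j = 0; j < nsam[p]; ++j) act[p].push_back(tip++);

  double t = 0.0;
  int eidx = 0, nev = events.nrow();
  int nextnode = n;
  int nact = n;

  while (nact > 1) {
    double rate = 0.0;
    for (int p = 0; p < npop; ++p) {
      double k = (double)act[p].size();
      rate += k * (k - 1.0) / 2.0 / popsize[p];
    }
    double dt = (rate > 0.0) ? R::exp_rand() / rate : R_PosInf;
    if (eidx < nev && (rate == 0.0 || t + dt >= events(eidx, 0))) {
      t = events(eidx, 0);
      int type = (int)events(eidx, 1);
      int a = (int)events(eidx, 2) - 1;
      int b = (int)events(eidx, 3) - 1;
      if (type == 0) {                       // join: a -> b
        for (size_t j = 0; j < act[a].size(); ++j) act[b].push_back(act[a][j]);
        act[a].clear();
      } else if (type == 2) {                // size change
        popsize[a] = events(eidx, 5);
      } else {                             // admixture: a -> b w.p. r else c
        int c = (int)events(eidx, 4) - 1;
        double r = events(eidx, 5);
        for (size_t j = 0; j < act[a].size(); ++j) {
          if (R::unif_rand() < r) act[b].push_back(act[a][j]);
          else act[c].push_back(act[a][j]);
        }
        act[a].clear();
      }
      ++eidx;
      continue;
    }
    if (rate == 0.0)
      stop("coalescent stalled: multiple isolated lineages and no remaining events");
    t += dt;
    // choose population proportional to its pair rate
    double u = R::unif_rand() * rate, acc = 0.0;
    int p = 0;
    for (; p < npop; ++p) {
      double k = (double)act[p].size();
      acc += k * (k - 1.0) / 2.0 / popsize[p];
      if (u <= acc) break;
    }
    if (p == npop) p = npop - 1;
    int k = act[p].size();
    int i1 = (int)(R::unif_rand() * k); if (i1 == k) --i1;
    int i2 = (int)(R::unif_rand() * (k - 1)); if (i2 == k - 1) --i2;
    if (i2 >= i1) ++i2;
    int l1 = act[p][i1], l2 = act[p][i2];
    parent[l1] = nextnode;
    parent[l2] = nextnode;
    ntime[nextnode] = t;
    // replace the two children by the new node
    if (i1 > i2) std::swap(i1, i2);
    act[p][i1] = nextnode;
    act[p].erase(act[p].begin() + i2);
    ++nextnode;
    --nact;
  }

  return List::create(_["parent"] = parent, _["time"] = ntime,
                      _["n_tips"] = n, _["tmrca"] = ntime[nnodes - 1]);
}

// children-ordered traversal: nodes are created in increasing time order, so
// visiting nodes from the root (last) downwards never visits a child before
// its parent if we iterate indices descending.

// Generalised stepwise mutation on a coalescent tree: Poisson(mu * branch)
// mutations per branch; each step is +/- k with k ~ Geometric(1 - p_gsm)
// (k >= 1); allele state reflected into [0, range - 1].
// [[Rcpp::export]]
IntegerVector cpp_mutate_gsm(IntegerVector parent, NumericVector ntime,
                             int n_tips, double mu, double p_gsm, int range) {
  int nnodes = parent.size();
  IntegerVector state(nnodes);
  state[nnodes - 1] = range / 2;  // root at mid-range
  for (int v = nnodes - 2; v >= 0; --v) {
    int u = parent[v];
    double br = ntime[u] - ntime[v];
    int s = state[u];
    int nmut = (int)R::rpois(mu * br);
    for (int m = 0; m < nmut; ++m) {
      int k = 1 + (int)R::rgeom(1.0 - p_gsm);
      if (R::unif_rand() < 0.5) k = -k;
      s += k;
      while (s < 0 || s >= range) {
        if (s < 0) s = -s;
        if (s >= range) s = 2 * (range - 1) - s;
      }
    }
    state[v] = s;
  }
  return IntegerVector(state.begin(), state.begin() + n_tips);
}

// Jukes-Cantor sequence mutation on a coalescent tree.  Root sequence drawn
// uniformly over {0,1,2,3}; each mutation hits a uniform site and switches
// to one of the three other bases.  Returns tips x L integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_mutate_jc69(IntegerVector parent, NumericVector ntime,
                              int n_tips, double mu_site, int L) {
  int nnodes = parent.size();
  std::vector< std::vector<int> > seq(nnodes);
  seq[nnodes - 1].resize(L);
  for (int j = 0; j < L; ++j)
    seq[nnodes - 1][j] = (int)(R::unif_rand() * 4) % 4;
  for (int v = nnodes - 2; v >= 0; --v) {
    int u = parent[v];
    double br = ntime[u] - ntime[v];
    seq[v] = seq[u];
    int nmut = (int)R::rpois(mu_site * L * br);
    for (int m = 0; m < nmut; ++m) {
      int site = (int)(R::unif_rand() * L); if (site == L) --site;
      int shift = 1 + (int)(R::unif_rand() * 3); if (shift == 4) shift = 3;
      seq[v][site] = (seq[v][site] + shift) % 4;
    }
  }
  IntegerMatrix out(n_tips, L);
  for (int i = 0; i < n_tips; ++i)
    for (int j = 0; j < L; ++j) out(i, j) = seq[i][j];
  return out;
}
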