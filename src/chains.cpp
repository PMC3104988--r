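#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in [0, n) from R's RNG, so results follow set.seed().
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Markov chain over single-locus genotype tables with fixed allele counts.
//
// State: an arrangement of the 2n allele copies into n ordered pairs.
// A uniformly random transposition of two copy slots is a symmetric
// proposal whose stationary distribution is uniform over arrangements,
// which induces the Levene conditional distribution on genotype tables.
// Given fixed allele counts the Weir-Cockerham Fis is a strictly
// decreasing function of the heterozygote count H, so tail membership is
// tracked through H alone.
//
// alleles: integer codes, slot 2i and 2i+1 belong to individual i.
// Returns per-batch mid-p tail estimates: each iteration contributes 1
// when the current table is strictly more extreme than the observed one
// (H > obs for excess, H < obs for deficiency) and 1/2 when it ties
// (H == obs), the score-test tie convention that keeps the discrete
// test calibrated.
// [[Rcpp::export]]
NumericVector hwe_chain_cpp(IntegerVector alleles, int dememorization,
                            int batches, int iters_per_batch, bool excess) {
  int m = alleles.size();
  int n = m / 2;
  std::vector<int> g(alleles.begin(), alleles.end());
  int H = 0;
  for (int i = 0; i < n; ++i) if (g[2 * i] != g[2 * i + 1]) ++H;
  const int obsH = H;

  NumericVector batch_means(batches);
  long total = (long)dememorization + (long)batches * iters_per_batch;
  long it = 0;
  double hits = 0;
  int batch = -1;
  long batch_it = 0;

  for (it = 0; it < total; ++it) {
    int u = runif_int(m);
    int v = runif_int(m - 1);
    if (v >= u) ++v;                       // distinct slots
    if (g[u] != g[v]) {
      int iu = u / 2, iv = v / 2;
      if (iu != iv) {
        bool hu = g[2 * iu] != g[2 * iu + 1];
        bool hv = g[2 * iv] != g[2 * iv + 1];
        std::swap(g[u], g[v]);
        bool hu2 = g[2 * iu] != g[2 * iu + 1];
        bool hv2 = g[2 * iv] != g[2 * iv + 1];
        H += (int)hu2 - (int)hu + (int)hv2 - (int)hv;
      } else {
        std::swap(g[u], g[v]);             // same individual: H unchanged
      }
    }
    if (it >= dememorization) {
      if (H == obsH) hits += 0.5;
      else if (excess ? (H > obsH) : (H < obsH)) hits += 1.0;
      if (++batch_it == iters_per_batch) {
        ++batch;
        batch_means[batch] = hits / iters_per_batch;
        hits = 0;
        batch_it = 0;
      }
    }
  }
  return batch_means;
}

// Per-locus pairwise genotype distance: (2 - shared alleles)/2 where
// shared alleles are counted with multiplicity over the best pairing.
static inline double pair_dist(int x1, int x2, int y1, int y2) {
  int s1 = (x1 == y1) + (x2 == y2);
  int s2 = (x1 == y2) + (x2 == y1);
  int s = s1 > s2 ? s1 : s2;
  return (2.0 - s) / 2.0;
}

// rbar_d for the distance vectors currently in `d` (loci x npairs,
// flattened).  Loci whose distance variance is zero are skipped; fewer
// than 2 usable loci gives NA.
static double rbard_stat(const std::vector<double>& d, int L, int np) {
  std::vector<double> var(L), mean(L);
  std::vector<int> use;
  for (int l = 0; l < L; ++l) {
    double s = 0, ss = 0;
    const double* dl = &d[(size_t)l * np];
    for (int p = 0; p < np; ++p) { s += dl[p]; ss += dl[p] * dl[p]; }
    mean[l] = s / np;
    var[l] = ss / np - mean[l] * mean[l];
    if (var[l] > 0) use.push_back(l);
  }
  if ((int)use.size() < 2) return NA_REAL;
  double varD = 0, sumvar = 0, denom = 0;
  // Var(D) via per-pair totals over usable loci
  double s = 0, ss = 0;
  for (int p = 0; p < np; ++p) {
    double D = 0;
    for (size_t k = 0; k < use.size(); ++k) D += d[(size_t)use[k] * np + p];
    s += D; ss += D * D;
  }
  varD = ss / np - (s / np) * (s / np);
  for (size_t k = 0; k < use.size(); ++k) sumvar += var[use[k]];
  for (size_t k = 0; k < use.size(); ++k)
    for (size_t j = k + 1; j < use.size(); ++j)
      denom += std::sqrt(var[use[k]] * var[use[j]]);
  if (denom <= 0) return NA_REAL;
  return (varD - sumvar) / (2.0 * denom);
}

// Observed rbar_d plus its permutation null distribution.  Permutation
// model: within each locus independently, the 2n allele copies are
// shuffled among individuals (alleles move between individuals, which
// destroys both inter-locus association and within-locus pairing).
// [[Rcpp::export]]
List rbard_perm_cpp(IntegerMatrix a1, IntegerMatrix a2, int nperm) {
  int n = a1.nrow(), L = a1.ncol();
  int np = n * (n - 1) / 2;
  std::vector<double> d((size_t)L * np);
  std::vector<int> pi(np), pj(np);
  {
    int q = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) { pi[q] = i; pj[q] = j; ++q; }
  }
  for (int l = 0; l < L; ++l)
    for (int q = 0; q < np; ++q)
      d[(size_t)l * np + q] =
        pair_dist(a1(pi[q], l), a2(pi[q], l), a1(pj[q], l), a2(pj[q], l));
  double obs = rbard_stat(d, L, np);

  NumericVector perms(nperm);
  std::vector<int> copies(2 * n);
  std::vector<int> x1(n), x2(n);
  std::vector<double> dp((size_t)L * np);
  for (int r = 0; r < nperm; ++r) {
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < n; ++i) {
        copies[2 * i] = a1(i, l);
        copies[2 * i + 1] = a2(i, l);
      }
      // Fisher-Yates with R RNG
      for (int i = 2 * n - 1; i > 0; --i) {
        int j = runif_int(i + 1);
        std::swap(copies[i], copies[j]);
      }
      for (int i = 0; i < n; ++i) { x1[i] = copies[2 * i]; x2[i] = copies[2 * i + 1]; }
      for (int q = 0; q < np; ++q)
        dp[(size_t)l * np + q] =
          pair_dist(x1[pi[q]], x2[pi[q]], x1[pj[q]], x2[pj[q]]);
    }
    perms[r] = rbard_stat(dp, L, np);
  }
  return List::create(_["observed"] = obs, _["perms"] = perms);
}
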