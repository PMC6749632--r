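#include <Rcpp.h>
using namespace Rcpp;

// Gene dropping over a pedigree given in topological order.
// sire/dam: 0-based parent indices into the same vectors, -1 = unknown.
// Uses R's RNG (unif_rand) so set.seed() gives reproducible replicates.

// Contribution of ancestor `anc`: both of its alleles are labelled; every
// other founder (and every unknown-parent gamete) is unlabelled. Returns the
// per-individual mean and sample-sd-based standard error of the fraction of
// labelled alleles over `nreps` replicates.
// [[Rcpp::export(name = ".gene_drop_cpp")]]
List gene_drop_cpp(IntegerVector order, IntegerVector sire, IntegerVector dam,
                   int anc, int nreps) {
  int n = sire.size();
  std::vector<double> sum(n, 0.0), sumsq(n, 0.0);
  std::vector<unsigned char> a1(n), a2(n);
  for (int r = 0; r < nreps; ++r) {
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      if (i == anc) { a1[i] = 1; a2[i] = 1; continue; }
      int s = sire[i], d = dam[i];
      a1[i] = (s < 0) ? 0 : ((unif_rand() < 0.5) ? a1[s] : a2[s]);
      a2[i] = (d < 0) ? 0 : ((unif_rand() < 0.5) ? a1[d] : a2[d]);
    }
    for (int i = 0; i < n; ++i) {
      double x = (a1[i] + a2[i]) / 2.0;
      sum[i] += x;
      sumsq[i] += x * x;
    }
  }
  NumericVector cmean(n), se(n);
  for (int i = 0; i < n; ++i) {
    double m = sum[i] / nreps;
    cmean[i] = m;
    if (nreps > 1) {
      double var = (sumsq[i] - nreps * m * m) / (nreps - 1);
      if (var < 0) var = 0;
      se[i] = std::sqrt(var / nreps);
    } else {
      se[i] = 0.0;
    }
  }
  return List::create(_["c"] = cmean, _["se"] = se);
}

// Joint homozygosity by gene dropping: one of the ancestor's two alleles is
// the mutant; count replicates in which the proband carries two mutant
// copies. Direct Monte-Carlo check of the product formula c_s * c_d / 4.
// [[Rcpp::export(name = ".joint_homo_cpp")]]
List joint_homo_cpp(IntegerVector order, IntegerVector sire, IntegerVector dam,
                    int anc, int proband, int nreps) {
  int n = sire.size();
  std::vector<unsigned char> a1(n), a2(n);
  long hits = 0;
  for (int r = 0; r < nreps; ++r) {
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      if (i == anc) { a1[i] = 1; a2[i] = 0; continue; }
      int s = sire[i], d = dam[i];
      a1[i] = (s < 0) ? 0 : ((unif_rand() < 0.5) ? a1[s] : a2[s]);
      a2[i] = (d < 0) ? 0 : ((unif_rand() < 0.5) ? a1[d] : a2[d]);
    }
    if (a1[proband] == 1 && a2[proband] == 1) ++hits;
  }
  double p = (double)hits / nreps;
  double se = std::sqrt(p * (1.0 - p) / nreps);
  return List::create(_["p_hat"] = p, _["se"] = se, _["n_reps"] = nreps);
}

// Single Mendelian forward drop from a heterozygous carrier ancestor:
// returns the number of mutant copies (0/1/2) per individual.
// [[Rcpp::export(name = ".mendelian_drop_cpp")]]
IntegerVector mendelian_drop_cpp(IntegerVector order, IntegerVector sire,
                                 IntegerVector dam, int anc) {
  int n = sire.size();
  std::vector<unsigned char> a1(n), a2(n);
  for (int k = 0; k < n; ++k) {
    int i = order[k];
    if (i == anc) { a1[i] = 1; a2[i] = 0; continue; }
    int s = sire[i], d = dam[i];
    a1[i] = (s < 0) ? 0 : ((unif_rand() < 0.5) ? a1[s] : a2[s]);
    a2[i] = (d < 0) ? 0 : ((unif_rand() < 0.5) ? a1[d] : a2[d]);
  }
  IntegerVector g(n);
  for (int i = 0; i < n; ++i) g[i] = a1[i] + a2[i];
  return g;
}
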