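#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Meiosis over an ordered set of loci grouped by chromosome.
//
// Haplotypes are 0/1 integer vectors over all loci (markers + QTL) sorted by
// chromosome then map position (cM). Crossover counts per chromosome are
// Poisson with mean = map length in Morgans, crossover positions uniform,
// parental origin alternates at each crossover, and the starting strand is a
// fair coin. Recurrent mutation toggles the allele at each locus with the
// given per-locus probability. All randomness comes from R's RNG so results
// are reproducible under set.seed().

static int gamete_into(const int* h1, const int* h2,
                       const double* pos,
                       const IntegerVector& chr_first,
                       const IntegerVector& chr_last,
                       const NumericVector& chr_len,
                       double mut_rate,
                       int n_loci,
                       int* out) {
  int n_chr = chr_first.size();
  int xo_total = 0;
  std::vector<double> xo;
  for (int c = 0; c < n_chr; ++c) {
    double len_m = chr_len[c] / 100.0;  // cM -> Morgan
    int nxo = len_m > 0 ? (int) R::rpois(len_m) : 0;
    xo_total += nxo;
    xo.resize(nxo);
    for (int k = 0; k < nxo; ++k) xo[k] = unif_rand() * chr_len[c];
    std::sort(xo.begin(), xo.end());
    int phase = unif_rand() < 0.5 ? 0 : 1;
    int k = 0;
    for (int j = chr_first[c]; j <= chr_last[c]; ++j) {
      while (k < nxo && xo[k] <= pos[j]) { phase ^= 1; ++k; }
      out[j] = phase ? h2[j] : h1[j];
    }
  }
  if (mut_rate > 0) {
    for (int j = 0; j < n_loci; ++j)
      if (unif_rand() < mut_rate) out[j] = 1 - out[j];
  }
  return xo_total;
}

// Single gamete from one parent's haplotype pair; returns the gamete and the
// genome-wide crossover count.
// [[Rcpp::export]]
List cpp_sample_gamete(IntegerVector h1, IntegerVector h2,
                       NumericVector pos,
                       IntegerVector chr_first, IntegerVector chr_last,
                       NumericVector chr_len, double mut_rate) {
  int L = h1.size();
  IntegerVector g(L);
  int nxo = gamete_into(h1.begin(), h2.begin(), pos.begin(),
                        chr_first, chr_last, chr_len, mut_rate, L, g.begin());
  return List::create(_["gamete"] = g, _["crossovers"] = nxo);
}

// Batch reproduction: one offspring per (sire, dam) pair. H1/H2 hold the two
// haplotypes of every candidate parent (rows = parents, columns = loci);
// sire/dam are 1-based row indices. The sire gamete is drawn first, then the
// dam gamete, pair by pair.
// [[Rcpp::export]]
List cpp_drop_offspring(IntegerMatrix H1, IntegerMatrix H2,
                        IntegerVector sire, IntegerVector dam,
                        NumericVector pos,
                        IntegerVector chr_first, IntegerVector chr_last,
                        NumericVector chr_len, double mut_rate) {
  int n_off = sire.size(), L = pos.size();
  IntegerMatrix O1(n_off, L), O2(n_off, L);
  std::vector<int> p1(L), p2(L), g(L);
  for (int i = 0; i < n_off; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < L; ++j) { p1[j] = H1(s, j); p2[j] = H2(s, j); }
    gamete_into(p1.data(), p2.data(), pos.begin(),
                chr_first, chr_last, chr_len, mut_rate, L, g.data());
    for (int j = 0; j < L; ++j) O1(i, j) = g[j];
    for (int j = 0; j < L; ++j) { p1[j] = H1(d, j); p2[j] = H2(d, j); }
    gamete_into(p1.data(), p2.data(), pos.begin(),
                chr_first, chr_last, chr_len, mut_rate, L, g.data());
    for (int j = 0; j < L; ++j) O2(i, j) = g[j];
  }
  return List::create(_["H1"] = O1, _["H2"] = O2);
}
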