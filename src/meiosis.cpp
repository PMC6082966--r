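#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gene-drop machinery for the forward-in-time simulator.
//
// Haplotypes are stored as an integer matrix with one row per locus (loci
// sorted by chromosome then genetic position) and two columns per diploid
// individual (paternal, maternal). Markers carry alleles {0,1}; QTL carry
// 1-based allele ids. All randomness goes through R's RNG so set.seed()
// makes whole simulations reproducible.

// One meiosis under the Haldane map: crossover count per chromosome is
// Poisson(length in Morgans), crossover positions uniform, no interference.
static void make_gamete(const int* h1, const int* h2,
                        const double* pos,
                        const std::vector<int>& chr_first,
                        const std::vector<int>& chr_last,
                        const std::vector<double>& chr_len,
                        int* out) {
  const int n_chr = (int) chr_len.size();
  double xo[64];
  for (int c = 0; c < n_chr; ++c) {
    int nxo = (int) R::rpois(chr_len[c]);
    if (nxo > 64) nxo = 64;  // > 64 crossovers on one chromosome is unreachable in practice
    for (int k = 0; k < nxo; ++k) xo[k] = unif_rand() * chr_len[c];
    std::sort(xo, xo + nxo);
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int k = 0;
    for (int i = chr_first[c]; i <= chr_last[c]; ++i) {
      while (k < nxo && xo[k] < pos[i]) { cur = 1 - cur; ++k; }
      out[i] = cur ? h2[i] : h1[i];
    }
  }
}

// Recurrent mutation. Markers flip allele state; a QTL mutation creates a
// brand-new allele id (effects for new ids are drawn lazily on the R side).
static void mutate_gamete(int* g,
                          const std::vector<int>& marker_idx, double marker_mu,
                          const std::vector<int>& qtl_idx, double qtl_mu,
                          int* allele_count) {
  const int nm = (int) marker_idx.size();
  if (nm > 0 && marker_mu > 0) {
    int nmut = (int) R::rbinom((double) nm, marker_mu);
    for (int k = 0; k < nmut; ++k) {
      int j = marker_idx[(int) (unif_rand() * nm)];
      g[j] = 1 - g[j];
    }
  }
  const int nq = (int) qtl_idx.size();
  if (nq > 0 && qtl_mu > 0) {
    int nmut = (int) R::rbinom((double) nq, qtl_mu);
    for (int k = 0; k < nmut; ++k) {
      int j = qtl_idx[(int) (unif_rand() * nq)];
      g[j] = ++allele_count[j];
    }
  }
}

static std::vector<int> to_idx0(const IntegerVector& v) {
  std::vector<int> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;
  return out;
}

// Produce one offspring generation from explicit parent assignments.
// sire/dam are 1-based individual indices into parent_haplo (ind i owns
// columns 2i-1, 2i). Returns the offspring haplotype matrix and the updated
// per-locus QTL allele counters.
// [[Rcpp::export]]
List cpp_drop_generation(IntegerMatrix parent_haplo,
                         IntegerVector sire, IntegerVector dam,
                         NumericVector pos, IntegerVector chr_first1,
                         IntegerVector chr_last1, NumericVector chr_len,
                         IntegerVector marker_idx1, double marker_mu,
                         IntegerVector qtl_idx1, double qtl_mu,
                         IntegerVector allele_count_in) {
  const int L = parent_haplo.nrow();
  const int n_off = sire.size();
  if (dam.size() != n_off) stop("sire/dam length mismatch");
  IntegerMatrix off(L, 2 * n_off);
  IntegerVector allele_count = clone(allele_count_in);

  std::vector<int> chr_first = to_idx0(chr_first1);
  std::vector<int> chr_last  = to_idx0(chr_last1);
  std::vector<double> clen(chr_len.begin(), chr_len.end());
  std::vector<int> midx = to_idx0(marker_idx1);
  std::vector<int> qidx = to_idx0(qtl_idx1);

  for (int o = 0; o < n_off; ++o) {
    int s = sire[o] - 1, d = dam[o] - 1;
    if (s < 0 || d < 0 || 2 * s + 1 >= parent_haplo.ncol() ||
        2 * d + 1 >= parent_haplo.ncol())
      stop("parent index out of range");
    // paternal gamete
    make_gamete(&parent_haplo(0, 2 * s), &parent_haplo(0, 2 * s + 1),
                REAL(pos), chr_first, chr_last, clen, &off(0, 2 * o));
    mutate_gamete(&off(0, 2 * o), midx, marker_mu, qidx, qtl_mu,
                  INTEGER(allele_count));
    // maternal gamete
    make_gamete(&parent_haplo(0, 2 * d), &parent_haplo(0, 2 * d + 1),
                REAL(pos), chr_first, chr_last, clen, &off(0, 2 * o + 1));
    mutate_gamete(&off(0, 2 * o + 1), midx, marker_mu, qidx, qtl_mu,
                  INTEGER(allele_count));
  }
  return List::create(_["haplo"] = off, _["allele_count"] = allele_count);
}

// Run a whole random-mating phase (the historical population) inside C++.
// gen_size/gen_males give, for each generation to create, its total size and
// how many of its members are male; within every generation the first
// gen_males individuals are the males. Sires and dams are drawn uniformly
// from the previous generation's males and females. Only the final
// generation's haplotypes are returned.
// [[Rcpp::export]]
List cpp_random_mating(IntegerMatrix founder_haplo, int founder_males,
                       IntegerVector gen_size, IntegerVector gen_males,
                       NumericVector pos, IntegerVector chr_first1,
                       IntegerVector chr_last1, NumericVector chr_len,
                       IntegerVector marker_idx1, double marker_mu,
                       IntegerVector qtl_idx1, double qtl_mu,
                       IntegerVector allele_count_in) {
  const int L = founder_haplo.nrow();
  const int n_gen = gen_size.size();
  if (gen_males.size() != n_gen) stop("gen_size/gen_males length mismatch");
  IntegerVector allele_count = clone(allele_count_in);

  std::vector<int> chr_first = to_idx0(chr_first1);
  std::vector<int> chr_last  = to_idx0(chr_last1);
  std::vector<double> clen(chr_len.begin(), chr_len.end());
  std::vector<int> midx = to_idx0(marker_idx1);
  std::vector<int> qidx = to_idx0(qtl_idx1);

  IntegerMatrix prev = founder_haplo;
  int prev_males = founder_males;
  int prev_n = founder_haplo.ncol() / 2;
  if (prev_males <= 0 || prev_males >= prev_n)
    stop("founder generation needs at least one male and one female");

  for (int g = 0; g < n_gen; ++g) {
    int N = gen_size[g], M = gen_males[g];
    if (N <= 0) stop("generation size must be positive");
    if (M <= 0 || M >= N) stop("each generation needs both sexes");
    IntegerMatrix cur(L, 2 * N);
    int n_fem = prev_n - prev_males;
    for (int o = 0; o < N; ++o) {
      int s = (int) (unif_rand() * prev_males);              // male index
      int d = prev_males + (int) (unif_rand() * n_fem);      // female index
      make_gamete(&prev(0, 2 * s), &prev(0, 2 * s + 1), REAL(pos),
                  chr_first, chr_last, clen, &cur(0, 2 * o));
      mutate_gamete(&cur(0, 2 * o), midx, marker_mu, qidx, qtl_mu,
                    INTEGER(allele_count));
      make_gamete(&prev(0, 2 * d), &prev(0, 2 * d + 1), REAL(pos),
                  chr_first, chr_last, clen, &cur(0, 2 * o + 1));
      mutate_gamete(&cur(0, 2 * o + 1), midx, marker_mu, qidx, qtl_mu,
                    INTEGER(allele_count));
    }
    prev = cur;
    prev_males = M;
    prev_n = N;
  }
  return List::create(_["haplo"] = prev, _["n_males"] = prev_males,
                      _["allele_count"] = allele_count);
}
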