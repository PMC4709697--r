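#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Haplotypes are stored one LOCUS per row and one haplotype per column
// (loci-major), so a gamete copy is contiguous in memory. Entries are in
// {0,1}, counting copies of the alternate allele. Loci must be sorted by
// (chromosome, position); pos_m gives the genetic map position in Morgans,
// chrom_id the integer chromosome of each locus.

static void chrom_bounds(const IntegerVector& chrom_id,
                         std::vector<int>& lo, std::vector<int>& hi) {
  int L = chrom_id.size();
  lo.clear(); hi.clear();
  int start = 0;
  for (int j = 1; j <= L; ++j) {
    if (j == L || chrom_id[j] != chrom_id[start]) {
      lo.push_back(start);
      hi.push_back(j);
      start = j;
    }
  }
}

// Meiosis for one parent (columns h1, h2 of length L): mosaic of the two
// parental haplotypes with Poisson crossovers per chromosome (Haldane, no
// interference) and independent assortment across chromosomes; symmetric
// bi-allelic mutation at rate mu per locus.
static void meiosis(const int* h1, const int* h2, int L,
                    const NumericVector& pos_m,
                    const std::vector<int>& lo, const std::vector<int>& hi,
                    double mu, int* out) {
  std::vector<double> cx;
  for (size_t c = 0; c < lo.size(); ++c) {
    int a = lo[c], b = hi[c];
    double m0 = pos_m[a], len = pos_m[b - 1] - pos_m[a];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int ncx = (len > 0) ? (int) R::rpois(len) : 0;
    if (ncx == 0) {
      std::memcpy(out + a, (cur ? h2 : h1) + a, (b - a) * sizeof(int));
    } else {
      cx.resize(ncx);
      for (int k = 0; k < ncx; ++k) cx[k] = m0 + unif_rand() * len;
      std::sort(cx.begin(), cx.end());
      int k = 0;
      for (int j = a; j < b; ++j) {
        while (k < ncx && cx[k] <= pos_m[j]) { cur = 1 - cur; ++k; }
        out[j] = (cur ? h2 : h1)[j];
      }
    }
  }
  if (mu > 0) {
    int nmut = (int) R::rbinom((double) L, mu);
    for (int k = 0; k < nmut; ++k) {
      int j = (int) (unif_rand() * L);
      if (j >= L) j = L - 1;
      out[j] = 1 - out[j];
    }
  }
}

// Fisher-Wright burn-in: n_gen discrete generations of random mating with
// replacement at constant size N (columns of H1/H2).
// [[Rcpp::export]]
List wf_burnin_cpp(IntegerMatrix H1, IntegerMatrix H2, int n_gen,
                   double mu, NumericVector pos_m, IntegerVector chrom_id) {
  int L = H1.nrow(), N = H1.ncol();
  std::vector<int> lo, hi;
  chrom_bounds(chrom_id, lo, hi);
  IntegerMatrix A1(clone(H1)), A2(clone(H2));
  IntegerMatrix B1(L, N), B2(L, N);
  for (int g = 0; g < n_gen; ++g) {
    for (int i = 0; i < N; ++i) {
      int s = (int) (unif_rand() * N); if (s >= N) s = N - 1;
      int d = (int) (unif_rand() * N); if (d >= N) d = N - 1;
      meiosis(&A1(0, s), &A2(0, s), L, pos_m, lo, hi, mu, &B1(0, i));
      meiosis(&A1(0, d), &A2(0, d), L, pos_m, lo, hi, mu, &B2(0, i));
    }
    std::swap(A1, B1);
    std::swap(A2, B2);
  }
  return List::create(_["H1"] = A1, _["H2"] = A2);
}

// One gamete per entry of `parent` (1-based column indices into H1/H2);
// returns an L x length(parent) matrix.
// [[Rcpp::export]]
IntegerMatrix drop_gametes_cpp(IntegerMatrix H1, IntegerMatrix H2,
                               IntegerVector parent, double mu,
                               NumericVector pos_m, IntegerVector chrom_id) {
  int L = H1.nrow(), N = H1.ncol(), n = parent.size();
  std::vector<int> lo, hi;
  chrom_bounds(chrom_id, lo, hi);
  IntegerMatrix out(L, n);
  for (int i = 0; i < n; ++i) {
    int p = parent[i] - 1;
    if (p < 0 || p >= N) stop("parent index out of range");
    meiosis(&H1(0, p), &H2(0, p), L, pos_m, lo, hi, mu, &out(0, i));
  }
  return out;
}
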