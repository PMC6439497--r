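#include <Rcpp.h>
using namespace Rcpp;

// Mendelian offspring genotypes. The genotype pool is stored locus x
// individual (one contiguous column per fish) so parent reads and offspring
// writes are cache-local. Genotypes are per-locus counts of the wild allele
// (0, 1 or 2); each offspring receives one allele from each parent, drawn
// uniformly from the parent's two alleles, independently per locus
// (unlinked loci). Uses the R RNG so results are reproducible via
// set.seed(); heterozygous-parent transmissions need one fair bit each,
// taken 32 at a time from single unif_rand() draws.

struct BitPool {
  unsigned int pool;
  int have;
  BitPool() : pool(0u), have(0) {}
  inline int next() {
    if (have == 0) {
      pool = (unsigned int)(unif_rand() * 4294967296.0);
      have = 32;
    }
    int b = pool & 1u;
    pool >>= 1;
    --have;
    return b;
  }
};

static inline void cross_cols(const int *mum, const int *dad, int *kid,
                              int L, BitPool &bits) {
  for (int j = 0; j < L; ++j) {
    int a = 0;
    const int gm = mum[j];
    if (gm == 2) a += 1;
    else if (gm == 1 && bits.next()) a += 1;
    const int gf = dad[j];
    if (gf == 2) a += 1;
    else if (gf == 1 && bits.next()) a += 1;
    kid[j] = a;
  }
}

// [[Rcpp::export]]
IntegerMatrix cross_genotypes(IntegerMatrix geno, IntegerVector mothers,
                              IntegerVector fathers) {
  const int n = mothers.size();
  const int L = geno.nrow();
  const int np = geno.ncol();
  if (fathers.size() != n) stop("mothers and fathers must have equal length");
  IntegerMatrix out(L, n);
  const int *g = geno.begin();
  int *o = out.begin();
  BitPool bits;
  for (int i = 0; i < n; ++i) {
    const int mi = mothers[i] - 1;
    const int fi = fathers[i] - 1;
    if (mi < 0 || mi >= np || fi < 0 || fi >= np)
      stop("parent index out of range");
    cross_cols(g + (R_xlen_t)mi * L, g + (R_xlen_t)fi * L,
               o + (R_xlen_t)i * L, L, bits);
  }
  return out;
}

// In-place variant used by the simulator's hot path: writes offspring
// columns directly into the preallocated genotype pool at columns `dest`
// (1-based).

// [[Rcpp::export]]
void cross_genotypes_into(IntegerMatrix geno, IntegerVector mothers,
                          IntegerVector fathers, IntegerVector dest) {
  const int n = mothers.size();
  const int L = geno.nrow();
  const int np = geno.ncol();
  if (fathers.size() != n || dest.size() != n)
    stop("mothers, fathers and dest must have equal length");
  int *g = geno.begin();
  BitPool bits;
  for (int i = 0; i < n; ++i) {
    const int mi = mothers[i] - 1;
    const int fi = fathers[i] - 1;
    const int di = dest[i] - 1;
    if (mi < 0 || mi >= np || fi < 0 || fi >= np || di < 0 || di >= np)
      stop("column index out of range");
    cross_cols(g + (R_xlen_t)mi * L, g + (R_xlen_t)fi * L,
               g + (R_xlen_t)di * L, L, bits);
  }
}
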