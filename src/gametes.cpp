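#include <Rcpp.h>
using namespace Rcpp;

// Sequential-Markov gamete model, no crossover interference.
// rvec[j] is the recombination fraction between locus j-1 and j; rvec[0] and
// every chromosome-start entry must be 0.5 so the source haplotype starts at
// random and chromosomes assort independently. Uses R's RNG, so draws are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix gametes_cpp(const IntegerMatrix& hapA, const IntegerMatrix& hapB,
                          const NumericVector& rvec) {
  const int n = hapA.nrow(), L = hapA.ncol();
  if (hapB.nrow() != n || hapB.ncol() != L)
    stop("haplotype matrices differ in shape");
  if (rvec.size() != L)
    stop("recombination vector length must equal locus count");
  IntegerMatrix g(n, L);
  for (int i = 0; i < n; ++i) {
    bool useB = false;
    for (int j = 0; j < L; ++j) {
      if (unif_rand() < rvec[j]) useB = !useB;
      g(i, j) = useB ? hapB(i, j) : hapA(i, j);
    }
  }
  return g;
}
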