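#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

static const char BASES[5] = "ACGT";

// Sample a sequence from a fixed-order Markov chain.  trans has 4^order rows
// (contexts in base-4 encoding, A=0..T=3, leftmost base most significant) and
// 4 columns summing to 1.  The first `order` bases are drawn uniformly.
// Uses R's RNG: seed via set.seed().
// [[Rcpp::export(name = ".markov_gen_cpp")]]
String markov_gen_cpp(int order, NumericMatrix trans, int len) {
  if (order < 0 || order > 8) stop("order must be in 0..8");
  uint32_t nctx = 1u << (2 * order);
  if ((uint32_t) trans.nrow() != nctx || trans.ncol() != 4)
    stop("transition matrix must be 4^order x 4");
  if (len <= order) stop("length must exceed order");
  uint32_t mask = (order == 0) ? 0u : (nctx - 1u);
  std::string s(len, 'A');
  uint32_t ctx = 0;
  for (int i = 0; i < order; ++i) {
    int b = (int) (unif_rand() * 4);
    if (b > 3) b = 3;
    s[i] = BASES[b];
    ctx = ((ctx << 2) | (uint32_t) b) & mask;
  }
  for (int i = order; i < len; ++i) {
    double u = unif_rand();
    double cum = 0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      cum += trans(ctx, j);
      if (u < cum) { b = j; break; }
    }
    s[i] = BASES[b];
    ctx = ((ctx << 2) | (uint32_t) b) & mask;
  }
  return String(s);
}
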